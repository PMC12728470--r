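#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell to a common library size (default 10,000 counts) and
#' applies `log(1 + x)`.  Cells with zero total counts are dropped with a
#' warning.
#'
#' @param counts genes x cells matrix (dense or sparse; gene and cell names
#'   required for downstream scoring).
#' @param scale_factor common library size (default 1e4).
#' @return sparse dgCMatrix of normalized log expression, same genes,
#'   possibly fewer cells.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  libs <- Matrix::colSums(m)
  if (any(libs == 0)) {
    warning(sprintf("dropping %d zero-count cell(s)", sum(libs == 0)))
    m <- m[, libs > 0, drop = FALSE]
    libs <- libs[libs > 0]
  }
  ## scale each column: nonzero entries of column j are x / libs[j] * sf
  m@x <- m@x / rep.int(libs, diff(m@p)) * scale_factor
  m@x <- log1p(m@x)
  m
}

#' Per-cell module score for a signature gene set
#'
#' Signature enrichment score in the bin-matched control-gene style: the
#' mean normalized expression of the signature genes minus the mean of
#' control genes sampled from expression-matched bins.  Genes are ranked by
#' their average expression across all cells and split into `n_bins`
#' equal-frequency bins; for each signature gene, `n_ctrl` control genes are
#' drawn (seeded, without replacement, signature genes excluded) from the
#' same bin.  A cell's score is the mean expression of the signature genes
#' minus the mean over the pooled control draw.
#'
#' Scores are deterministic given `seed` and invariant to cell order (bins
#' depend only on per-gene averages).
#'
#' @param normalized genes x cells matrix from [normalize_log()].
#' @param gene_set character vector of signature genes; at least one must be
#'   present in the matrix (an error names the missing genes otherwise).
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl control genes sampled per signature gene (default 50;
#'   capped at the bin's available pool).
#' @param seed integer seed for control sampling (default 0).
#' @return named numeric vector of per-cell scores.
#' @export
score_signature <- function(normalized, gene_set, n_bins = 25L, n_ctrl = 50L,
                            seed = 0L) {
  genes <- rownames(normalized)
  if (is.null(genes)) stop_config("normalized matrix must have gene names")
  present <- intersect(gene_set, genes)
  if (!length(present))
    stop_data("no signature gene present in matrix; missing: %s",
              paste(utils::head(setdiff(gene_set, genes), 10), collapse = ", "))
  avg <- Matrix::rowMeans(normalized)
  ## equal-frequency bins over average expression; ties broken stably
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  ctrl_pool <- withr::with_seed(seed, {
    unlist(lapply(present, function(g) {
      cand <- genes[bin == bin[match(g, genes)]]
      cand <- setdiff(cand, gene_set)
      if (!length(cand)) return(character(0))
      cand[sample.int(length(cand), min(n_ctrl, length(cand)))]
    }))
  })
  sig_mean <- Matrix::colMeans(normalized[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl_pool))
    Matrix::colMeans(normalized[ctrl_pool, , drop = FALSE]) else 0
  score <- sig_mean - ctrl_mean
  setNames(as.numeric(score), colnames(normalized))
}

#' Score several signatures and assign a state label per cell
#'
#' Computes a module score per signature ([score_signature()]) and labels
#' each cell with the arg-max signature when the maximum score exceeds
#' `threshold`; cells with no score above the threshold are labelled
#' `undiff_label` ("the remaining cells").  Ties are broken by signature
#' order (first listed wins); the order is recorded in the result.
#'
#' @param normalized genes x cells matrix from [normalize_log()].
#' @param signatures named list of signature gene vectors (state
#'   signatures only, not cell-cycle lists).
#' @param threshold minimum winning score (default 0: any positive
#'   enrichment wins).
#' @param undiff_label label for unassigned cells (default `"undiff"`).
#' @param n_bins,n_ctrl,seed passed to [score_signature()].
#' @return data.frame of class `cell_state_assignment`: `cell`, one score
#'   column per signature, `state`.
#' @export
assign_states <- function(normalized, signatures, threshold = 0,
                          undiff_label = "undiff", n_bins = 25L,
                          n_ctrl = 50L, seed = 0L) {
  if (is.null(names(signatures)) || anyDuplicated(names(signatures)))
    stop_config("signatures must be a uniquely named list")
  scores <- sapply(names(signatures), function(nm)
    score_signature(normalized, signatures[[nm]], n_bins = n_bins,
                    n_ctrl = n_ctrl, seed = derive_seed(seed, nm)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, names(signatures)))
  best <- max.col(scores, ties.method = "first")
  state <- colnames(scores)[best]
  state[scores[cbind(seq_len(nrow(scores)), best)] <= threshold] <- undiff_label
  out <- data.frame(cell = colnames(normalized), scores, state = state,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("cell_state_assignment", "data.frame"),
            threshold = threshold, signature_order = names(signatures))
}

#' Cell-cycle phase per cell from S and G2M signatures
#'
#' Scores the S-phase and G2M gene lists with [score_signature()]; a cell's
#' phase is the arg-max of the two scores when either is positive, `"G1"`
#' otherwise; `cycling` flags phases other than G1.
#'
#' @param normalized genes x cells matrix from [normalize_log()].
#' @param s_genes,g2m_genes cell-cycle gene lists.
#' @param n_bins,n_ctrl,seed passed to [score_signature()].
#' @return data.frame: `cell`, `s_score`, `g2m_score`, `phase`, `cycling`.
#' @export
cycle_phase <- function(normalized, s_genes, g2m_genes, n_bins = 25L,
                        n_ctrl = 50L, seed = 0L) {
  s <- score_signature(normalized, s_genes, n_bins, n_ctrl,
                       seed = derive_seed(seed, "S"))
  g <- score_signature(normalized, g2m_genes, n_bins, n_ctrl,
                       seed = derive_seed(seed, "G2M"))
  phase <- ifelse(pmax(s, g) <= 0, "G1", ifelse(s >= g, "S", "G2M"))
  data.frame(cell = colnames(normalized), s_score = as.numeric(s),
             g2m_score = as.numeric(g), phase = phase,
             cycling = phase != "G1", stringsAsFactors = FALSE)
}

#' Per-condition cell-state proportions
#'
#' @param states character vector of per-cell state labels.
#' @param conditions character vector of per-cell condition labels (same
#'   length).  Conditions with no cells are excluded with a warning.
#' @return data.frame, one row per (condition, state), with `proportion`
#'   summing to 1 within each condition.
#' @export
state_proportions <- function(states, conditions) {
  if (length(states) != length(conditions))
    stop_data("states and conditions must have equal length")
  keep <- !is.na(states) & !is.na(conditions)
  if (!all(keep)) warning("dropping cells with missing labels")
  tab <- table(condition = conditions[keep], state = states[keep])
  empty <- rownames(tab)[rowSums(tab) == 0]
  if (length(empty)) {
    warning(sprintf("excluding empty condition(s): %s",
                    paste(empty, collapse = ", ")))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  }
  prop <- prop.table(tab, margin = 1)
  out <- as.data.frame(prop, responseName = "proportion",
                       stringsAsFactors = FALSE)
  out$n <- as.data.frame(tab, responseName = "n")$n
  out
}

#' Pseudobulk Pearson correlation between conditions
#'
#' Collapses the normalized matrix to one profile per condition (mean
#' normalized expression across that condition's cells) and returns the
#' Pearson correlation matrix across conditions over the selected genes.
#'
#' @param normalized genes x cells matrix from [normalize_log()].
#' @param conditions per-cell condition labels.
#' @param genes optional gene subset (default: all genes).
#' @param top_n optional: restrict to the `top_n` most variable genes
#'   (variance of the pseudobulk profiles across conditions).
#' @return list with `r` (condition x condition Pearson matrix) and
#'   `profiles` (genes x conditions pseudobulk matrix).
#' @export
pseudobulk_correlation <- function(normalized, conditions, genes = NULL,
                                   top_n = NULL) {
  if (ncol(normalized) != length(conditions))
    stop_data("conditions must label every cell")
  conds <- unique(conditions)
  prof <- sapply(conds, function(cc)
    Matrix::rowMeans(normalized[, conditions == cc, drop = FALSE]))
  rownames(prof) <- rownames(normalized)
  if (!is.null(genes)) {
    shared <- intersect(genes, rownames(prof))
    if (length(shared) < 2L) stop_data("need at least 2 shared genes")
    prof <- prof[shared, , drop = FALSE]
  }
  if (!is.null(top_n)) {
    v <- apply(prof, 1, var)
    prof <- prof[order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(prof)))], ,
                 drop = FALSE]
  }
  if (any(apply(prof, 2, function(p) var(p) == 0)))
    stop_data("zero-variance pseudobulk profile; cannot correlate")
  list(r = cor(prof, method = "pearson"), profiles = prof)
}

#' Per-gene differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on normalized expression for every
#' gene (vectorized normal approximation with tie and continuity
#' correction, appropriate at single-cell group sizes), log2 fold change of
#' group means on the de-logged normalized scale with a pseudocount, and
#' Benjamini-Hochberg adjustment across genes.  Genes that are all-zero in
#' both groups are excluded (their number is recorded in the
#' `n_excluded` attribute).
#'
#' @param normalized genes x cells matrix from [normalize_log()].
#' @param cells_a,cells_b cell id vectors (each n >= 3).
#' @param pseudocount added to de-logged group means before the log2 ratio
#'   (default 1e-9).
#' @return data.frame: `gene`, `log2_fc` (positive = up in group A),
#'   `p_value`, `p_adj`, sorted by `p_adj` then p; attribute `n_excluded`.
#' @export
differential_expression <- function(normalized, cells_a, cells_b,
                                    pseudocount = 1e-9) {
  ids <- colnames(normalized)
  a <- match(cells_a, ids); b <- match(cells_b, ids)
  if (anyNA(a) || anyNA(b)) stop_data("unknown cell ids in group definitions")
  if (length(a) < 3L || length(b) < 3L)
    stop_data("both groups need at least 3 cells")
  m <- as.matrix(normalized[, c(a, b), drop = FALSE])
  na <- length(a); nb <- length(b); n <- na + nb
  nz <- rowSums(m != 0) > 0
  n_excluded <- sum(!nz)
  m <- m[nz, , drop = FALSE]

  ## vectorized rank-sum with tie correction + continuity correction,
  ## matching wilcox.test(correct = TRUE)'s normal path
  rk <- t(apply(m, 1, rank))
  w <- rowSums(rk[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  tiecor <- apply(m, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  })
  sigma2 <- (na * nb / 12) * ((n + 1) - tiecor / (n * (n - 1)))
  z <- w - na * nb / 2
  z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  p <- pmin(p, 1)

  ma <- rowMeans(expm1(m[, seq_len(na), drop = FALSE]))
  mb <- rowMeans(expm1(m[, na + seq_len(nb), drop = FALSE]))
  lfc <- log2(ma + pseudocount) - log2(mb + pseudocount)

  out <- data.frame(gene = rownames(m), log2_fc = lfc, p_value = p,
                    p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_value), ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Detection fraction of a gene within (state, condition) cell subsets
#'
#' Fraction of cells expressing the gene above zero, per state-by-condition
#' subset — the check used to ask whether a differentiation marker is
#' present in one model's cells but absent from another's.  Empty subsets
#' are reported as `NA`.
#'
#' @param expr genes x cells matrix (counts or normalized; only the zero
#'   pattern matters).
#' @param gene gene name (must be present).
#' @param states,conditions per-cell labels.
#' @return data.frame: `state`, `condition`, `n_cells`, `fraction`.
#' @export
marker_presence <- function(expr, gene, states, conditions) {
  if (!gene %in% rownames(expr))
    stop_data("gene '%s' not present in matrix", gene)
  if (ncol(expr) != length(states) || ncol(expr) != length(conditions))
    stop_data("states and conditions must label every cell")
  v <- as.numeric(expr[gene, ])
  combos <- unique(data.frame(state = states, condition = conditions,
                              stringsAsFactors = FALSE))
  combos <- combos[order(combos$condition, combos$state), ]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- states == combos$state[i] & conditions == combos$condition[i]
    data.frame(state = combos$state[i], condition = combos$condition[i],
               n_cells = sum(sel),
               fraction = if (any(sel)) mean(v[sel] > 0) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read signature gene sets from GMT or two-column text
#'
#' GMT files (`.gmt`) are parsed with [fgsea::gmtPathways()]; any other
#' extension is read as two-column delimited text (`set`, `gene`).
#'
#' @param path file path.
#' @return named list of gene vectors.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop_data("signature file not found: %s", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE))
    return(fgsea::gmtPathways(path))
  tab <- read.csv(path, sep = "", header = FALSE, col.names = c("set", "gene"),
                  stringsAsFactors = FALSE)
  split(tab$gene, tab$set)
}
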