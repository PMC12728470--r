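#' Specification of a synthetic single-cell count matrix
#'
#' Defines conditions (e.g. primary tumor, tumor-forebrain-organoid,
#' tumorsphere), per-condition proportions of tumor cell states (RG-like,
#' NProg-like, Nb-like, undifferentiated), per-condition cycling fractions,
#' and negative-binomial count parameters.  Each state except `undiff` owns
#' a disjoint signature gene list whose expression is multiplied by
#' `signature_fold_change` in cells of that state; cycling cells
#' additionally up-regulate an S-phase or G2M gene list.  Per-gene baseline
#' abundances are log-normal (seeded), which gives the expression-bin
#' structure the module-score control sampling relies on.
#'
#' The default condition set and proportions emulate the qualitative
#' situation the fidelity analyses are built for: primary and TBO share a
#' balanced state distribution, tumorspheres are skewed toward the
#' NProg-like state (0.7) and accumulate cycling cells (0.6 vs 0.2).
#'
#' @param n_cells_per_condition cells per condition (default 1000).
#' @param conditions condition names.
#' @param states state names; the last one (default `"undiff"`) carries no
#'   signature.
#' @param state_proportions matrix (conditions x states), each row summing
#'   to 1.
#' @param cycling_fraction named numeric, fraction of cycling cells per
#'   condition.
#' @param n_signature_genes signature genes per non-undiff state (default 50).
#' @param n_cycle_genes genes in each of the S and G2M lists (default 40).
#' @param n_background_genes unregulated genes (default 2000).
#' @param signature_fold_change multiplicative up-regulation of a state's
#'   signature genes in that state (> 1; default 4).
#' @param cycling_fold_change up-regulation of S/G2M genes in cycling cells
#'   (default 10; cell-cycle markers are near-binary between cycling and
#'   non-cycling cells, a much stronger modulation than subtle state
#'   signatures).
#' @param baseline_sdlog log-normal sd of per-gene baseline abundances.
#' @param dispersion negative-binomial size parameter (default 2).
#' @param library_size_mean expected total counts per cell (default 5000).
#' @param library_size_sdlog log-normal sd of per-cell library-size factors
#'   (mean-one; default 0.15).
#' @param knockouts optional data.frame with columns `gene`, `state`,
#'   `condition`: those cells express that gene at (near) zero — emulating
#'   a differentiation marker absent from one model's cells.
#' @param seed integer master seed.
#' @return object of class `synthetic_cell_spec`, with `$signature_genes`
#'   (named list: one entry per non-undiff state, plus `S` and `G2M`).
#' @export
synthetic_cell_spec <- function(n_cells_per_condition = 1000L,
                                conditions = c("primary", "TBO", "spheres"),
                                states = c("RG-like", "NProg-like",
                                           "Nb-like", "undiff"),
                                state_proportions = NULL,
                                cycling_fraction = c(primary = 0.2,
                                                     TBO = 0.2,
                                                     spheres = 0.6),
                                n_signature_genes = 50L,
                                n_cycle_genes = 40L,
                                n_background_genes = 2000L,
                                signature_fold_change = 4,
                                cycling_fold_change = 10,
                                baseline_sdlog = 1,
                                dispersion = 2,
                                library_size_mean = 5000,
                                library_size_sdlog = 0.15,
                                knockouts = NULL,
                                seed = 1L) {
  if (is.null(state_proportions)) {
    state_proportions <- rbind(primary = c(0.25, 0.25, 0.25, 0.25),
                               TBO = c(0.25, 0.25, 0.25, 0.25),
                               spheres = c(0.1, 0.7, 0.1, 0.1))
    colnames(state_proportions) <- states
    state_proportions <- state_proportions[conditions, , drop = FALSE]
  }
  state_proportions <- as.matrix(state_proportions)
  if (!identical(rownames(state_proportions), as.character(conditions)) ||
      !identical(colnames(state_proportions), as.character(states)))
    stop_config("state_proportions must have conditions as rows and states as columns")
  if (any(abs(rowSums(state_proportions) - 1) > 1e-8))
    stop_data("each condition's state proportions must sum to 1")
  if (signature_fold_change < 1)
    stop_config("signature_fold_change must be >= 1 (1 = null model)")
  if (any(cycling_fraction < 0 | cycling_fraction > 1) ||
      !all(conditions %in% names(cycling_fraction)))
    stop_config("cycling_fraction must be named per condition, in [0, 1]")

  sig_states <- states[-length(states)]
  mk <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))
  signature_genes <- c(
    setNames(lapply(sig_states, function(s)
      mk(toupper(gsub("[^A-Za-z0-9]", "", s)), n_signature_genes)), sig_states),
    list(S = mk("S", n_cycle_genes), G2M = mk("G2M", n_cycle_genes)))
  if (anyDuplicated(unlist(signature_genes)))
    stop_config("signature gene lists must be pairwise disjoint")

  structure(list(n_cells_per_condition = as.integer(n_cells_per_condition),
                 conditions = as.character(conditions),
                 states = as.character(states),
                 state_proportions = state_proportions,
                 cycling_fraction = cycling_fraction,
                 signature_genes = signature_genes,
                 n_background_genes = as.integer(n_background_genes),
                 signature_fold_change = signature_fold_change,
                 cycling_fold_change = cycling_fold_change,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 knockouts = knockouts,
                 seed = as.integer(seed)),
            class = "synthetic_cell_spec")
}

#' Generate a synthetic gene-by-cell count matrix with known cell states
#'
#' Draws negative-binomial counts for every (condition, state) group:
#' per-gene log-normal baseline abundances, the state's signature genes
#' multiplied by `signature_fold_change`, S/G2M genes multiplied by
#' `cycling_fold_change` in cycling cells (phase S or G2M, alternating),
#' knockout genes zeroed for their (state, condition), and per-cell weights
#' rescaled so the expected library size equals `library_size_mean` times a
#' mean-one log-normal factor.  State and cycling assignments use
#' largest-remainder rounding, so the realized per-condition proportions
#' match the spec up to integer rounding.
#'
#' @param spec a [synthetic_cell_spec()].
#' @return list with `counts` (sparse dgCMatrix, genes x cells),
#'   `cell_info` (data.frame: `cell`, `condition`, `state`, `cycling`,
#'   `phase`), `gene_info` (data.frame: `gene`, `class`), and `signatures`
#'   (the spec's signature gene lists).
#' @export
generate_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  sig <- spec$signature_genes
  genes <- c(unlist(sig, use.names = FALSE),
             sprintf("BG_%04d", seq_len(spec$n_background_genes)))
  gene_class <- c(rep(names(sig), lengths(sig)),
                  rep("background", spec$n_background_genes))
  ng <- length(genes)

  withr::with_seed(spec$seed, {
    baseline <- rlnorm(ng, meanlog = 0, sdlog = spec$baseline_sdlog)

    infos <- list()
    for (cond in spec$conditions) {
      n <- spec$n_cells_per_condition
      n_state <- round_counts(spec$state_proportions[cond, ], n)
      state_vec <- rep(spec$states, n_state)
      ## cycling cells spread across states by a seeded permutation
      n_cyc <- round_counts(c(spec$cycling_fraction[[cond]],
                              1 - spec$cycling_fraction[[cond]]), n)[1]
      cyc <- rep(FALSE, n); cyc[sample.int(n, n_cyc)] <- TRUE
      phase <- rep("G1", n)
      phase[cyc] <- rep(c("S", "G2M"), length.out = n_cyc)
      infos[[cond]] <- data.frame(
        cell = sprintf("%s_c%04d", cond, seq_len(n)),
        condition = cond, state = state_vec, cycling = cyc, phase = phase,
        stringsAsFactors = FALSE)
    }
    info <- do.call(rbind, infos)
    rownames(info) <- NULL
    nc <- nrow(info)
    lib <- spec$library_size_mean *
      rlnorm(nc, meanlog = -spec$library_size_sdlog^2 / 2,
             sdlog = spec$library_size_sdlog)

    counts <- matrix(0, nrow = ng, ncol = nc)
    groups <- split(seq_len(nc),
                    interaction(info$condition, info$state, info$phase,
                                drop = TRUE))
    for (idx in groups) {
      st <- info$state[idx[1]]
      cond <- info$condition[idx[1]]
      ph <- info$phase[idx[1]]
      w <- baseline
      if (st %in% names(sig))
        w[gene_class == st] <- w[gene_class == st] * spec$signature_fold_change
      if (ph %in% c("S", "G2M"))
        w[gene_class == ph] <- w[gene_class == ph] * spec$cycling_fold_change
      if (!is.null(spec$knockouts)) {
        ko <- spec$knockouts
        hit <- ko$gene[ko$state == st & ko$condition == cond]
        if (length(hit)) w[genes %in% hit] <- 0
      }
      w <- w / sum(w)
      mu <- outer(w, lib[idx])
      counts[, idx] <- rnbinom(length(mu), size = spec$dispersion, mu = mu)
    }
  })

  dimnames(counts) <- list(genes, info$cell)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       cell_info = info,
       gene_info = data.frame(gene = genes, class = gene_class,
                              stringsAsFactors = FALSE),
       signatures = sig)
}
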