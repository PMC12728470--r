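#' Normalize a treated group to the control group
#'
#' Ratio of group means (treated / control), the normalization used for all
#' screen and dose-response effects ("relative to vehicle control").  The
#' reported SEM is the treated group's SEM divided by the control mean;
#' control uncertainty is not propagated (documented choice: the control is
#' the common reference for every drug, so its noise shifts all effects
#' identically and is not drug-specific dispersion).  Effects are floored at
#' 0 (a background-corrected sum can dip below zero under noise).
#'
#' @param treated,control numeric vectors of per-organoid measurements.
#' @return list with `effect`, `sem`, `n`.
#' @export
normalize_to_control <- function(treated, control) {
  tr <- aggregate_group(treated)
  ct <- aggregate_group(control)
  if (!is.finite(ct$mean) || ct$mean <= 0)
    stop_data("degenerate control group: mean %.4g (must be > 0)", ct$mean)
  list(effect = max(tr$mean / ct$mean, 0),
       sem = tr$sem / ct$mean,
       n = tr$n)
}

#' Two-sided Wilcoxon rank-sum test between two groups
#'
#' Exact distribution when the combined sample size is at most 20 and no
#' ties are present; otherwise the normal approximation with tie correction
#' and continuity correction.  When every value in both groups is identical
#' there is no evidence of a difference and p = 1 is returned.
#'
#' @param x,y numeric vectors (each n >= 1).
#' @return list with `p_value`, `statistic` (the rank-sum W of `x`),
#'   `method` (`"exact"`, `"normal-approx"` or `"degenerate"`).
#' @export
test_group_difference <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop_data("both groups must be non-empty")
  comb <- c(x, y)
  if (length(unique(comb)) == 1L)
    return(list(p_value = 1, statistic = NA_real_, method = "degenerate"))
  ties <- anyDuplicated(comb) > 0L
  use_exact <- (length(comb) <= 20L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = use_exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(p_value = min(p, 1), statistic = unname(wt$statistic),
       method = if (use_exact) "exact" else "normal-approx")
}

#' Score a drug screen: per-drug effects, significance, hits, ranking
#'
#' For every treated drug, computes the normalized tumor and TME effects
#' (group mean over control mean, per [normalize_to_control()]), two-sided
#' Wilcoxon rank-sum p-values against control ([test_group_difference()]),
#' Benjamini-Hochberg adjusted p-values across drugs (per compartment), a
#' hit flag (adjusted tumor p below `alpha` AND tumor effect below 1, i.e. a
#' significant tumor *reduction*) and the selectivity (TME effect minus
#' tumor effect; positive means the drug spares the microenvironment more
#' than the tumor).
#'
#' The default effect fields are the compartment areas (`tumor_area`,
#' `tme_area`); summed-brightness fields (`tumor_sum`, `neuronal_sum`) are
#' the appropriate choice when the drug effect manifests as an intensity
#' reduction rather than a shrinking footprint.
#'
#' @param measurements data.frame with columns `drug`, `role` and the chosen
#'   effect fields; one row per organoid.  Exactly one drug must have role
#'   `"control"`.
#' @param tumor_field,tme_field measurement columns for the two compartments.
#' @param alpha hit-calling significance level (default 0.05).
#' @param mt_method multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @param order `"figure"` (default; ascending anti-tumor strength, i.e.
#'   weakest drugs first and strongest last) or `"effect"` (ascending
#'   normalized tumor effect, strongest first).
#' @return data.frame of class `screen_result`, one row per treated drug,
#'   with attributes `alpha`, `mt_method`, `control_drug`, `n_hits`.
#' @export
score_screen <- function(measurements, tumor_field = "tumor_area",
                         tme_field = "tme_area", alpha = 0.05,
                         mt_method = "BH",
                         order = c("figure", "effect")) {
  order <- match.arg(order)
  req <- c("drug", "role", tumor_field, tme_field)
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop_config("measurements are missing columns: %s", paste(miss, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  ctrl_drugs <- unique(measurements$drug[measurements$role == "control"])
  if (length(ctrl_drugs) != 1L)
    stop_data("exactly one control drug is required (found %d)", length(ctrl_drugs))
  ctrl <- measurements[measurements$role == "control", ]
  drugs <- unique(measurements$drug[measurements$role != "control"])
  if (!length(drugs)) stop_data("no treated groups present")

  rows <- lapply(drugs, function(dg) {
    gr <- measurements[measurements$drug == dg & measurements$role != "control", ]
    eff_t <- normalize_to_control(gr[[tumor_field]], ctrl[[tumor_field]])
    eff_m <- normalize_to_control(gr[[tme_field]], ctrl[[tme_field]])
    p_t <- test_group_difference(gr[[tumor_field]], ctrl[[tumor_field]])
    p_m <- test_group_difference(gr[[tme_field]], ctrl[[tme_field]])
    data.frame(drug = dg, n = nrow(gr),
               normalized_tumor_effect = eff_t$effect,
               tumor_sem = eff_t$sem,
               normalized_tme_effect = eff_m$effect,
               tme_sem = eff_m$sem,
               p_tumor = p_t$p_value, p_tme = p_m$p_value,
               test_method = p_t$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_tumor_adj <- p.adjust(res$p_tumor, method = mt_method)
  res$p_tme_adj <- p.adjust(res$p_tme, method = mt_method)
  res$hit <- res$p_tumor_adj < alpha & res$normalized_tumor_effect < 1
  res$selectivity <- res$normalized_tme_effect - res$normalized_tumor_effect
  res <- res[order(res$normalized_tumor_effect,
                   decreasing = (order == "figure")), ]
  rownames(res) <- NULL
  structure(res, class = c("screen_result", "data.frame"),
            alpha = alpha, mt_method = mt_method,
            control_drug = ctrl_drugs, n_hits = sum(res$hit))
}
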