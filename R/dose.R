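#' Build per-compartment dose-response curves for one drug
#'
#' For each tested dose, normalizes the tumor (summed tumor-channel
#' brightness in tumor areas) and neuronal (summed neuronal-channel
#' brightness in the whole organoid) readouts to the vehicle control and
#' tests each dose group against control with the two-sided Wilcoxon
#' rank-sum test.  Dose 0 denotes the control and is normalized to 1 by
#' construction.
#'
#' @param measurements data.frame with columns `drug`, `dose`, `role` and
#'   the two compartment fields; control rows have role `"control"`.
#' @param drug drug to build the curve for (default: the single treated
#'   drug present).
#' @param tumor_field,tme_field measurement columns (defaults `tumor_sum`,
#'   `neuronal_sum`, the summed-brightness readouts).
#' @param mt_method optional within-curve multiplicity adjustment applied
#'   per compartment across doses (`"none"` by default, mirroring per-dose
#'   reporting; any [stats::p.adjust()] method accepted).
#' @return data.frame of class `dose_response_curve`, long format: `drug`,
#'   `dose`, `compartment` (`"tumor"` / `"neuronal"`), `n`, `mean`
#'   (normalized), `sem`, `p`.
#' @export
build_curve <- function(measurements, drug = NULL,
                        tumor_field = "tumor_sum",
                        tme_field = "neuronal_sum",
                        mt_method = "none") {
  req <- c("drug", "dose", "role", tumor_field, tme_field)
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop_config("measurements are missing columns: %s", paste(miss, collapse = ", "))
  ctrl <- measurements[measurements$role == "control", ]
  if (!nrow(ctrl)) stop_data("control group (role 'control') is required")
  treated <- measurements[measurements$role != "control", ]
  if (is.null(drug)) {
    drug <- unique(treated$drug)
    if (length(drug) != 1L)
      stop_config("multiple drugs present; specify `drug`")
  }
  treated <- treated[treated$drug == drug, ]
  doses <- sort(unique(treated$dose))
  if (length(doses) < 2L)
    stop_data("need at least 2 nonzero doses (found %d)", length(doses))
  if (anyDuplicated(doses) || any(doses <= 0) || anyNA(doses))
    stop_data("doses must be distinct, positive and non-missing")
  per_dose_n <- table(treated$dose)

  fields <- c(tumor = tumor_field, neuronal = tme_field)
  rows <- list()
  for (comp in names(fields)) {
    f <- fields[[comp]]
    ctrl_norm <- normalize_to_control(ctrl[[f]], ctrl[[f]])
    rows[[length(rows) + 1L]] <- data.frame(
      drug = drug, dose = 0, compartment = comp, n = nrow(ctrl),
      mean = 1, sem = ctrl_norm$sem, p = NA_real_)
    for (d in doses) {
      gr <- treated[treated$dose == d, ]
      eff <- normalize_to_control(gr[[f]], ctrl[[f]])
      tst <- test_group_difference(gr[[f]], ctrl[[f]])
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, dose = d, compartment = comp, n = nrow(gr),
        mean = eff$effect, sem = eff$sem, p = tst$p_value)
    }
  }
  curve <- do.call(rbind, rows)
  if (!identical(mt_method, "none")) {
    for (comp in names(fields)) {
      sel <- curve$compartment == comp & curve$dose > 0
      curve$p[sel] <- p.adjust(curve$p[sel], method = mt_method)
    }
  }
  structure(curve, class = c("dose_response_curve", "data.frame"),
            drug = drug, doses = doses, mt_method = mt_method)
}

#' Lowest dose with a significant reduction in a compartment
#'
#' The first (lowest) dose whose two-sided p-value against control is below
#' `alpha` AND whose normalized mean is below 1 — i.e. the first significant
#' *reduction*, matching the convention of marking the first significant
#' difference along a decreasing dose-response curve.
#'
#' @param curve a [build_curve()] result.
#' @param compartment `"tumor"` or `"neuronal"`.
#' @param alpha significance level (default 0.05).
#' @return the dose (numeric scalar), or `NA` if no dose qualifies.
#' @export
first_significant_dose <- function(curve, compartment = c("tumor", "neuronal"),
                                   alpha = 0.05) {
  compartment <- match.arg(compartment)
  cc <- curve[curve$compartment == compartment & curve$dose > 0, ]
  cc <- cc[order(cc$dose), ]
  sig <- !is.na(cc$p) & cc$p < alpha & cc$mean < 1
  if (!any(sig)) return(NA_real_)
  cc$dose[which(sig)[1]]
}

#' Therapeutic window from a dose-response curve
#'
#' The dose interval that is efficacious against the tumor compartment but
#' not yet toxic to the neuronal compartment: `lower` is the first
#' significant tumor-reduction dose; `upper` is the largest tested dose
#' strictly below the first significant neuronal-reduction dose (or the
#' maximum tested dose if the neuronal compartment is never significantly
#' reduced).  The window exists when `lower` is defined and
#' `lower <= upper`.
#'
#' @param curve a [build_curve()] result (must contain both compartments).
#' @param alpha significance level (default 0.05).
#' @return object of class `therapeutic_window`: list with `lower`, `upper`,
#'   `exists`, `alpha`, `first_neuronal` (the first significant neuronal
#'   dose, `NA` if none).
#' @export
therapeutic_window <- function(curve, alpha = 0.05) {
  if (!all(c("tumor", "neuronal") %in% curve$compartment))
    stop_data("curve must contain both tumor and neuronal compartments")
  doses <- sort(unique(curve$dose[curve$dose > 0]))
  lower <- first_significant_dose(curve, "tumor", alpha)
  fn <- first_significant_dose(curve, "neuronal", alpha)
  upper <- if (is.na(fn)) max(doses) else {
    below <- doses[doses < fn]
    if (length(below)) max(below) else NA_real_
  }
  exists <- !is.na(lower) && !is.na(upper) && lower <= upper
  structure(list(lower = lower, upper = upper, exists = exists,
                 alpha = alpha, first_neuronal = fn),
            class = "therapeutic_window")
}

#' @export
print.therapeutic_window <- function(x, ...) {
  if (x$exists)
    cat(sprintf("<therapeutic_window> [%g, %g] at alpha=%g\n",
                x$lower, x$upper, x$alpha))
  else
    cat(sprintf("<therapeutic_window> none at alpha=%g\n", x$alpha))
  invisible(x)
}

#' Optional Hill fit of a dose-response curve (EC50 reporting)
#'
#' Fits `mean(d) = 1 - max_kill * d^h / (ec50^h + d^h)` to one compartment
#' of a curve by least squares ([stats::nls()], port algorithm).  Reporting
#' aid only; the therapeutic-window logic never depends on this fit.
#'
#' @param curve a [build_curve()] result.
#' @param compartment `"tumor"` or `"neuronal"`.
#' @return list with `ec50`, `hill`, `max_kill`, and the `nls` fit (or
#'   `NULL` with a warning if the fit fails to converge).
#' @export
fit_hill <- function(curve, compartment = c("tumor", "neuronal")) {
  compartment <- match.arg(compartment)
  cc <- curve[curve$compartment == compartment & curve$dose > 0, ]
  fit <- tryCatch(
    stats::nls(mean ~ 1 - mk * dose^h / (e^h + dose^h), data = cc,
               start = list(mk = min(max(1 - min(cc$mean), 0.1), 1),
                            e = stats::median(cc$dose), h = 1),
               algorithm = "port",
               lower = c(mk = 0, e = min(cc$dose) / 100, h = 0.1),
               upper = c(mk = 1, e = max(cc$dose) * 100, h = 10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Hill fit did not converge")
    return(NULL)
  }
  cf <- stats::coef(fit)
  list(ec50 = unname(cf["e"]), hill = unname(cf["h"]),
       max_kill = unname(cf["mk"]), fit = fit)
}
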