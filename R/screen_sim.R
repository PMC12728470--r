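#' Ground-truth table for a synthetic drug screen
#'
#' One row per treatment group (drug, or drug x dose), holding the simulated
#' kill fractions and replicate count, plus exactly one control group
#' (DMSO-like, zero kill).  This is the ground truth against which the
#' screen and dose-response stages are validated by parameter recovery.
#'
#' @param drug character vector of drug names (the treated groups; one row
#'   per drug/dose combination when `dose` is given).
#' @param tumor_kill,neuronal_kill numeric vectors (recycled) of kill
#'   fractions in `[0, 1]` for the tumor and neuronal compartments.
#' @param dose optional numeric vector of doses (strictly positive);
#'   `NA` for single-dose screens.
#' @param n_per_group organoids per treated group (>= 1; the screening
#'   default is 4).
#' @param control_name name of the control condition (default `"DMSO"`).
#' @param n_control organoids in the control group (defaults to
#'   `n_per_group`).
#' @return data.frame with columns `drug`, `dose`, `tumor_kill`,
#'   `neuronal_kill`, `role`, `n`, of class `screen_truth`.
#' @export
screen_truth_table <- function(drug, tumor_kill = 0, neuronal_kill = 0,
                               dose = NA_real_, n_per_group = 4L,
                               control_name = "DMSO",
                               n_control = n_per_group) {
  k <- length(drug)
  tab <- data.frame(drug = as.character(drug),
                    dose = rep_len(as.numeric(dose), k),
                    tumor_kill = rep_len(tumor_kill, k),
                    neuronal_kill = rep_len(neuronal_kill, k),
                    role = "treated",
                    n = rep_len(as.integer(n_per_group), k),
                    stringsAsFactors = FALSE)
  tab <- rbind(tab,
               data.frame(drug = control_name, dose = 0, tumor_kill = 0,
                          neuronal_kill = 0, role = "control",
                          n = as.integer(n_control)))
  validate_screen_truth(tab)
  class(tab) <- c("screen_truth", "data.frame")
  tab
}

validate_screen_truth <- function(tab) {
  req <- c("drug", "dose", "tumor_kill", "neuronal_kill", "role", "n")
  if (!all(req %in% names(tab)))
    stop_config("truth table must have columns: %s", paste(req, collapse = ", "))
  if (sum(tab$role == "control") != 1L)
    stop_data("truth table must contain exactly one control row (found %d)",
              sum(tab$role == "control"))
  if (any(tab$n < 1L)) stop_data("n per group must be >= 1")
  if (any(tab$tumor_kill < 0 | tab$tumor_kill > 1 |
          tab$neuronal_kill < 0 | tab$neuronal_kill > 1))
    stop_data("kill fractions must lie in [0, 1]")
  key <- paste(tab$drug, tab$dose)
  if (anyDuplicated(key))
    stop_data("duplicate (drug, dose) groups in truth table")
  invisible(tab)
}

well_ids_for <- function(tab) {
  ids <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    tag <- if (is.na(tab$dose[i]) || tab$role[i] == "control")
      tab$drug[i] else sprintf("%s_d%g", tab$drug[i], tab$dose[i])
    sprintf("%s_r%02d", tag, seq_len(tab$n[i]))
  }))
  if (anyDuplicated(ids)) stop_data("duplicate well ids generated")
  ids
}

#' Generate a synthetic screening dataset (one phantom per organoid)
#'
#' For every row of the truth table, renders `n` organoid phantoms with the
#' row's kill fractions, using per-well seeds derived deterministically from
#' the master seed (`spec$seed`) and the well id, so generation is
#' order-independent and reproducible.
#'
#' @param truth a [screen_truth_table()].
#' @param spec a [phantom_spec()]; its `seed` acts as the master seed and
#'   its `tumor_kill`/`neuronal_kill` are overridden per group.
#' @return list with `stacks` (named list of [image_stack()]), `truths`
#'   (named list of voxel ground truth), and `layout` (data.frame with
#'   columns `well_id`, `drug`, `dose`, `role`, `replicate`).
#' @seealso [simulate_screen_measurements()] for the memory-light path that
#'   measures each phantom as it is generated.
#' @export
generate_screen_dataset <- function(truth, spec) {
  validate_screen_truth(truth)
  layout <- screen_layout(truth)
  stacks <- vector("list", nrow(layout))
  truths <- vector("list", nrow(layout))
  names(stacks) <- names(truths) <- layout$well_id
  for (i in seq_len(nrow(layout))) {
    res <- generate_well(layout[i, ], truth, spec)
    stacks[[i]] <- res$stack
    truths[[i]] <- res$truth
  }
  list(stacks = stacks, truths = truths, layout = layout)
}

screen_layout <- function(truth) {
  ids <- well_ids_for(truth)
  layout <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    data.frame(drug = truth$drug[i], dose = truth$dose[i],
               role = truth$role[i], replicate = seq_len(truth$n[i]),
               stringsAsFactors = FALSE)
  }))
  layout <- cbind(well_id = ids, layout)
  rownames(layout) <- NULL
  layout
}

generate_well <- function(well, truth, spec) {
  row <- truth[truth$drug == well$drug &
               (is.na(truth$dose) & is.na(well$dose) |
                !is.na(truth$dose) & !is.na(well$dose) &
                truth$dose == well$dose), , drop = FALSE]
  wspec <- spec
  wspec$tumor_kill <- row$tumor_kill[1]
  wspec$neuronal_kill <- row$neuronal_kill[1]
  wspec$seed <- derive_seed(spec$seed, well$well_id)
  class(wspec) <- class(spec)
  generate_organoid_stack(wspec)
}

#' Simulate a screen and measure it in one streaming pass
#'
#' Generates each phantom, runs organoid and tumor segmentation, measures
#' compartment-specific summed brightness and areas, and discards the stack
#' before the next one is rendered.  This is the workhorse for recovery and
#' calibration experiments, where thousands of organoids would not fit in
#' memory simultaneously.
#'
#' @inheritParams generate_screen_dataset
#' @param background background-correction method passed to
#'   [measure_organoid()] (`"compartment"`, `"outside"` or `"none"`).
#' @param segment_args optional list of extra arguments for
#'   [segment_organoid()].
#' @return measurements data.frame: layout columns plus `tumor_sum`,
#'   `neuronal_sum`, `tumor_area`, `tme_area`.
#' @export
simulate_screen_measurements <- function(truth, spec,
                                         background = "compartment",
                                         segment_args = list()) {
  validate_screen_truth(truth)
  layout <- screen_layout(truth)
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    res <- generate_well(layout[i, ], truth, spec)
    seg <- do.call(segment_stack, c(list(res$stack), segment_args))
    m <- measure_organoid(res$stack, seg, background = background)
    rows[[i]] <- data.frame(tumor_sum = m$tumor_sum,
                            neuronal_sum = m$neuronal_sum,
                            tumor_area = m$tumor_area,
                            tme_area = m$tme_area)
  }
  cbind(layout, do.call(rbind, rows))
}

#' Hill-type kill fraction as a function of dose
#'
#' Convenience parameterization for simulated dose-response experiments:
#' `kill(d) = max_kill * d^h / (ec50^h + d^h)`.
#'
#' @param dose numeric vector of doses (>= 0).
#' @param ec50 dose of half-maximal kill.
#' @param hill Hill coefficient (default 2).
#' @param max_kill plateau kill fraction in `[0, 1]` (default 1).
#' @return numeric vector of kill fractions.
#' @export
hill_kill <- function(dose, ec50, hill = 2, max_kill = 1) {
  stopifnot(ec50 > 0, max_kill >= 0, max_kill <= 1)
  max_kill * dose^hill / (ec50^hill + dose^hill)
}
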