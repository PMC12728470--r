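#' Read and validate a pipeline run configuration
#'
#' A single YAML (or JSON) file configures all pipeline stages.  Top-level
#' keys: `seed` (integer), `output_dir`, and per-stage blocks `simulate`,
#' `quantify`, `screen`, `dose`, `fidelity` (all optional; stages use
#' defaults for missing entries).
#'
#' @param path YAML or JSON config path.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.na(cfg$seed)) stop_config("seed must be an integer")
  cfg$output_dir <- cfg$output_dir %||% "tboscreen_out"
  alpha <- cfg$screen$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  structure(cfg, class = c("run_config", "list"))
}

ensure_outdir <- function(dir, force = FALSE, expect = character(0)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clash <- file.path(dir, expect)
  clash <- clash[file.exists(clash)]
  if (length(clash) && !force)
    stop_config("output file(s) already exist (use force = TRUE): %s",
                paste(clash, collapse = ", "))
  invisible(dir)
}

write_manifest <- function(dir, stage, cfg, files) {
  manifest <- list(stage = stage,
                   package_version = as.character(packageVersion("tboscreen")),
                   seed = cfg$seed,
                   config_hash = config_hash(unclass(cfg)),
                   files = as.list(setNames(unname(tools::md5sum(
                     file.path(dir, files))), files)))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

phantom_spec_from_config <- function(cfg) {
  p <- cfg$simulate$phantom %||% list()
  allowed <- names(formals(phantom_spec))
  bad <- setdiff(names(p), allowed)
  if (length(bad)) stop_config("unknown phantom option(s): %s",
                               paste(bad, collapse = ", "))
  p$seed <- cfg$seed
  do.call(phantom_spec, p)
}

truth_from_config <- function(cfg) {
  sim <- cfg$simulate %||% list()
  if (!is.null(sim$truth)) {
    tab <- as.data.frame(sim$truth, stringsAsFactors = FALSE)
    validate_screen_truth(tab)
    return(tab)
  }
  n_drugs <- sim$n_drugs %||% 3L
  if (n_drugs < 1L) stop_config("n_drugs must be >= 1")
  kills <- rep(c(0.75, 0.5, 0.25, 0), length.out = n_drugs)
  screen_truth_table(drug = sprintf("drug%03d", seq_len(n_drugs)),
                     tumor_kill = kills,
                     neuronal_kill = rep(c(0.1, 0), length.out = n_drugs),
                     n_per_group = sim$n_per_group %||% 4L)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes either an imaging screen (one TIFF stack + sidecar per organoid,
#' a plate-layout CSV and the ground-truth table) or a single-cell count
#' matrix (MTX + genes/cells/truth files), depending on
#' `config$simulate$mode` (`"screen"`, default, or `"counts"`).  A manifest
#' JSON records the seed, config hash and per-file checksums; reruns with
#' the same config are byte-identical.
#'
#' @param config a [read_run_config()] result (or its path).
#' @param force overwrite existing outputs (default `FALSE`).
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  mode <- cfg$simulate$mode %||% "screen"
  dir <- cfg$output_dir
  if (mode == "screen") {
    truth <- truth_from_config(cfg)
    spec <- phantom_spec_from_config(cfg)
    layout <- screen_layout(truth)
    files <- c("layout.csv", "truth.csv",
               paste0(layout$well_id, ".tif"))
    ensure_outdir(dir, force, files)
    for (i in seq_len(nrow(layout))) {
      res <- generate_well(layout[i, ], truth, spec)
      write_stack_tiff(res$stack, file.path(dir, paste0(layout$well_id[i], ".tif")))
    }
    write_layout_csv(layout, file.path(dir, "layout.csv"))
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    manifest <- write_manifest(dir, "simulate", cfg,
                               c("layout.csv", "truth.csv"))
  } else if (mode == "counts") {
    spec_args <- cfg$simulate$cells %||% list()
    spec_args$seed <- cfg$seed
    cspec <- do.call(synthetic_cell_spec, spec_args)
    files <- paste0("counts", c(".mtx", ".genes.txt", ".cells.txt",
                                ".cell_info.csv"))
    ensure_outdir(dir, force, files)
    gen <- generate_expression_matrix(cspec)
    write_counts_mtx(gen$counts, file.path(dir, "counts"),
                     cell_info = gen$cell_info)
    sigs <- gen$signatures
    gmt <- vapply(names(sigs), function(nm)
      paste(c(nm, nm, sigs[[nm]]), collapse = "\t"), character(1))
    writeLines(gmt, file.path(dir, "signatures.gmt"))
    manifest <- write_manifest(dir, "simulate", cfg, files)
  } else stop_config("unknown simulate mode '%s'", mode)
  invisible(manifest)
}

#' Quantify a directory of stacks into per-organoid measurements
#'
#' Reads the plate layout and each well's TIFF stack, segments organoid and
#' tumor areas, measures compartment sums and areas, and writes
#' `measurements.csv` (plus `measurements_per_plane.csv` when
#' `config$quantify$per_plane` is true).
#'
#' @inheritParams run_simulate
#' @return the measurements data.frame, invisibly.
#' @export
run_quantify <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  q <- cfg$quantify %||% list()
  stacks_dir <- q$stacks_dir %||% cfg$output_dir
  layout <- read_layout_csv(q$layout %||% file.path(stacks_dir, "layout.csv"))
  dir <- cfg$output_dir
  ensure_outdir(dir, force, "measurements.csv")
  background <- q$background %||% "compartment"
  per_plane <- isTRUE(q$per_plane)
  rows <- list(); pp <- list()
  for (i in seq_len(nrow(layout))) {
    stack <- read_stack_tiff(file.path(stacks_dir,
                                       paste0(layout$well_id[i], ".tif")))
    seg <- segment_stack(stack)
    m <- measure_organoid(stack, seg, background = background)
    rows[[i]] <- data.frame(tumor_sum = m$tumor_sum,
                            neuronal_sum = m$neuronal_sum,
                            tumor_area = m$tumor_area, tme_area = m$tme_area)
    if (per_plane)
      pp[[i]] <- cbind(well_id = layout$well_id[i], m$per_plane)
  }
  meas <- cbind(layout, do.call(rbind, rows))
  write_measurements_csv(meas, file.path(dir, "measurements.csv"))
  if (per_plane)
    write.csv(do.call(rbind, pp), file.path(dir, "measurements_per_plane.csv"),
              row.names = FALSE)
  write_manifest(dir, "quantify", cfg, "measurements.csv")
  invisible(meas)
}

#' Score a screen from measurements on disk
#'
#' Runs [score_screen()] on `measurements.csv` and writes the ranked
#' `screen_results.csv` plus a JSON summary (hit count, alpha, method
#' provenance).
#'
#' @inheritParams run_simulate
#' @return the screen_result data.frame, invisibly.
#' @export
run_screen <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  s <- cfg$screen %||% list()
  dir <- cfg$output_dir
  meas <- read_measurements_csv(s$measurements %||%
                                file.path(dir, "measurements.csv"))
  ensure_outdir(dir, force, c("screen_results.csv", "screen_summary.json"))
  res <- score_screen(meas,
                      tumor_field = s$tumor_field %||% "tumor_area",
                      tme_field = s$tme_field %||% "tme_area",
                      alpha = s$alpha %||% 0.05,
                      mt_method = s$mt_method %||% "BH")
  write.csv(res, file.path(dir, "screen_results.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_drugs = nrow(res), n_hits = attr(res, "n_hits"),
         alpha = attr(res, "alpha"), mt_method = attr(res, "mt_method"),
         control_drug = attr(res, "control_drug"),
         tumor_field = s$tumor_field %||% "tumor_area",
         tme_field = s$tme_field %||% "tme_area",
         seed = cfg$seed, config_hash = config_hash(unclass(cfg))),
    file.path(dir, "screen_summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(dir, "screen", cfg,
                 c("screen_results.csv", "screen_summary.json"))
  invisible(res)
}

#' Dose-response curves and therapeutic window from measurements on disk
#'
#' Builds the per-compartment dose-response curve for each treated drug in
#' `measurements.csv` and writes `dose_curves.csv` (long format) and
#' `therapeutic_windows.json`.
#'
#' @inheritParams run_simulate
#' @return named list of `therapeutic_window` objects, invisibly.
#' @export
run_dose <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  d <- cfg$dose %||% list()
  dir <- cfg$output_dir
  meas <- read_measurements_csv(d$measurements %||%
                                file.path(dir, "measurements.csv"))
  ensure_outdir(dir, force, c("dose_curves.csv", "therapeutic_windows.json"))
  alpha <- d$alpha %||% 0.05
  drugs <- unique(meas$drug[meas$role != "control"])
  curves <- list(); windows <- list()
  for (dg in drugs) {
    cur <- build_curve(meas[meas$role == "control" | meas$drug == dg, ],
                       drug = dg,
                       tumor_field = d$tumor_field %||% "tumor_sum",
                       tme_field = d$tme_field %||% "neuronal_sum",
                       mt_method = d$mt_method %||% "none")
    curves[[dg]] <- cur
    w <- therapeutic_window(cur, alpha = alpha)
    windows[[dg]] <- list(lower = w$lower, upper = w$upper,
                          exists = w$exists, alpha = w$alpha)
  }
  write.csv(do.call(rbind, curves), file.path(dir, "dose_curves.csv"),
            row.names = FALSE)
  jsonlite::write_json(windows, file.path(dir, "therapeutic_windows.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(dir, "dose", cfg,
                 c("dose_curves.csv", "therapeutic_windows.json"))
  invisible(lapply(curves, therapeutic_window, alpha = alpha))
}

#' Cell-state fidelity report from a count matrix on disk
#'
#' Reads counts (MTX prefix), per-cell condition labels and signature gene
#' sets, classifies cells ([assign_states()], [cycle_phase()]), and writes
#' `assignment.csv`, `proportions.csv`, `correlation.csv` and — when two
#' conditions are named in `config$fidelity$de_conditions` — `de_table.csv`.
#'
#' @inheritParams run_simulate
#' @return list with `assignment`, `proportions`, `correlation` (and `de`),
#'   invisibly.
#' @export
run_fidelity <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  f <- cfg$fidelity %||% list()
  dir <- cfg$output_dir
  prefix <- f$counts %||% file.path(dir, "counts")
  sig_path <- f$signatures %||% file.path(dir, "signatures.gmt")
  if (!file.exists(sig_path))
    stop_data("signature file not found: %s", sig_path)
  counts <- read_counts_mtx(prefix)
  info_path <- f$cell_info %||% paste0(prefix, ".cell_info.csv")
  if (!file.exists(info_path))
    stop_data("cell metadata not found: %s", info_path)
  info <- read.csv(info_path, stringsAsFactors = FALSE)
  sigs <- read_signatures(sig_path)
  cycle <- list(S = sigs$S, G2M = sigs$G2M)
  state_sigs <- sigs[setdiff(names(sigs), c("S", "G2M"))]
  ensure_outdir(dir, force, c("assignment.csv", "proportions.csv",
                              "correlation.csv"))

  norm <- normalize_log(counts)
  info <- info[match(colnames(norm), info$cell), ]
  asg <- assign_states(norm, state_sigs,
                       threshold = f$threshold %||% 0, seed = cfg$seed)
  if (!is.null(cycle$S) && !is.null(cycle$G2M)) {
    cyc <- cycle_phase(norm, cycle$S, cycle$G2M, seed = cfg$seed)
    asg$phase <- cyc$phase
    asg$cycling <- cyc$cycling
  }
  asg$condition <- info$condition
  props <- state_proportions(asg$state, asg$condition)
  pc <- pseudobulk_correlation(norm, asg$condition)

  write.csv(asg, file.path(dir, "assignment.csv"), row.names = FALSE)
  write.csv(props, file.path(dir, "proportions.csv"), row.names = FALSE)
  write.csv(as.data.frame(pc$r), file.path(dir, "correlation.csv"))
  out <- list(assignment = asg, proportions = props, correlation = pc$r)
  if (!is.null(f$de_conditions)) {
    dc <- f$de_conditions
    de <- differential_expression(norm,
                                  asg$cell[asg$condition == dc[1]],
                                  asg$cell[asg$condition == dc[2]])
    write.csv(de, file.path(dir, "de_table.csv"), row.names = FALSE)
    out$de <- de
  }
  write_manifest(dir, "fidelity", cfg,
                 c("assignment.csv", "proportions.csv", "correlation.csv"))
  invisible(out)
}
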