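#' Write / read a plate-layout table
#'
#' Layout CSV columns: `well_id`, `drug`, `dose`, `role` (control|treated),
#' `replicate`.
#'
#' @param layout data.frame as produced by [generate_screen_dataset()].
#' @param path CSV path.
#' @return `path` (write) or the layout data.frame (read).
#' @export
write_layout_csv <- function(layout, path) {
  req <- c("well_id", "drug", "dose", "role", "replicate")
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stop_config("layout is missing columns: %s", paste(miss, collapse = ", "))
  write.csv(layout[req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  if (!file.exists(path)) stop_data("layout file not found: %s", path)
  layout <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("well_id", "drug", "dose", "role", "replicate")
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stop_data("layout file %s is missing columns: %s", path,
              paste(miss, collapse = ", "))
  if (anyDuplicated(layout$well_id))
    stop_data("duplicate well ids in layout %s", path)
  layout
}

#' Write / read per-organoid measurements
#'
#' One row per organoid: layout columns plus `tumor_sum`, `neuronal_sum`,
#' `tumor_area`, `tme_area`.  An optional long-format per-plane table can be
#' written alongside.
#'
#' @param measurements measurements data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_measurements_csv <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) stop_data("measurements file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a count matrix as MTX with genes/cells sidecar files
#'
#' Writes `<prefix>.mtx` (MatrixMarket, via [Matrix::writeMM()]),
#' `<prefix>.genes.txt` and `<prefix>.cells.txt` (one name per line), and —
#' when cell metadata is supplied — `<prefix>.cell_info.csv`.
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param prefix output path prefix.
#' @param cell_info optional per-cell data.frame (truth labels etc.).
#' @return the `.mtx` path, invisibly.
#' @export
write_counts_mtx <- function(counts, prefix, cell_info = NULL) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".genes.txt"))
  writeLines(colnames(m), paste0(prefix, ".cells.txt"))
  if (!is.null(cell_info))
    write.csv(cell_info, paste0(prefix, ".cell_info.csv"), row.names = FALSE)
  invisible(paste0(prefix, ".mtx"))
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param prefix path prefix used at write time.
#' @return sparse dgCMatrix with gene and cell names.
#' @export
read_counts_mtx <- function(prefix) {
  mtx <- paste0(prefix, ".mtx")
  if (!file.exists(mtx)) stop_data("count matrix not found: %s", mtx)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  rownames(m) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".cells.txt"))
  m
}
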