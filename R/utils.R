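`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a configuration error
#'
#' Configuration errors (bad arguments, missing channels, malformed configs)
#' carry the condition class `tboscreen_config_error` so that callers (and the
#' command-line wrapper) can map them to a distinct exit code.
#'
#' @param fmt,... passed to [sprintf()].
#' @keywords internal
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tboscreen_config_error", "tboscreen_error")))
}

#' Signal a data error
#'
#' Data errors (degenerate inputs, missing controls, shape mismatches) carry
#' the condition class `tboscreen_data_error`.
#'
#' @param fmt,... passed to [sprintf()].
#' @keywords internal
stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tboscreen_data_error", "tboscreen_error")))
}

#' Stable 31-bit hash of a character identifier
#'
#' Polynomial rolling hash modulo the Mersenne prime 2^31 - 1, computed in
#' exact double arithmetic (all intermediates stay below 2^53).  Used to
#' derive per-object random seeds from a master seed and an identifier, so
#' that generation order does not matter and every seed fits in a 32-bit
#' integer.
#'
#' @param id character scalar.
#' @return integer in `[0, 2^31 - 2]`.
#' @keywords internal
hash_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Derive a per-object seed from a master seed and an identifier
#'
#' @param master integer master seed.
#' @param id character identifier (e.g. a well id).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "A01") != derive_seed(1L, "A02")
derive_seed <- function(master, id) {
  m <- 2147483647
  h <- hash_id(as.character(id))
  as.integer((h * 1000003 + as.double(master) %% m) %% m)
}

## largest-remainder rounding of n * proportions to integers summing to n
round_counts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

## md5 of an in-memory object via its canonical JSON form (provenance hashing)
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
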