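#' Read and write wormkin CSV tables
#'
#' One row per entity, UTF-8, header row, dot decimal separator. The
#' `scenarios` table stores the sampling-day grid as a semicolon-separated
#' list in the `times` column (e.g. `"1;2;4;7;14;21"`); it is parsed into a
#' list-column on read and serialized back on write. All readers validate.
#'
#' @param path File path.
#' @param ... Passed to the matching validator (e.g. `fractions_to_percent`).
#' @return A validated tibble.
#' @seealso [validate_chemicals()]
#' @name wormkin_io
NULL

read_wormkin_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname wormkin_io
#' @export
read_chemicals <- function(path, ...) validate_chemicals(read_wormkin_csv(path), ...)

#' @rdname wormkin_io
#' @export
read_soils <- function(path, ...) validate_soils(read_wormkin_csv(path), ...)

#' @rdname wormkin_io
#' @export
read_worms <- function(path, ...) validate_worms(read_wormkin_csv(path), ...)

#' @rdname wormkin_io
#' @export
read_scenarios <- function(path) validate_scenarios(read_wormkin_csv(path))

#' @rdname wormkin_io
#' @param scenarios A validated scenarios tibble.
#' @export
write_scenarios <- function(scenarios, path) {
  scenarios <- validate_scenarios(scenarios)
  out <- scenarios
  out$times <- vapply(out$times, paste, character(1), collapse = ";")
  readr::write_csv(out, path)
  invisible(path)
}
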