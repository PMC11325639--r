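#' Input validation for chemicals, soils, earthworms and exposure scenarios
#'
#' `wormkin` works on four plain tables (one row per entity). The validators
#' check the schema and the scientific invariants, and return the data
#' unchanged as a tibble; they never convert units. The unit contract is:
#' OM, clay and lipid in percent (e.g. `om = 39.9`, never `0.399`), CEC in
#' cmol+/kg, TPSA in Angstrom^2, SSA in m^2/kg, concentrations in mg/L
#' (porewater) or mg/kg dry weight (soil), times in days.
#'
#' * `chemicals`: `name`, `log_kow`, `pka` (may be `NA` for neutral
#'   compounds), `charge_type` (`"neutral"`, `"monovalent_acid"` or
#'   `"monovalent_base"`), `tpsa`, `kd_measured` (L/kg, `NA` when
#'   unmeasured).
#' * `soils`: `name`, `om`, `clay`, `cec`, `ph`.
#' * `worms`: `species`, `lipid` (% wet weight), `ssa` (m^2/kg); a
#'   `ssalipid` column is added (or checked) as `ssa * lipid`.
#' * `scenarios`: `route` (`"porewater"` or `"soil"`), `c0`, `k0` (1/d,
#'   first-order exposure decay, 0 for constant exposure), `times` (a
#'   list-column of strictly increasing day vectors).
#'
#' Violations raise a condition of class `wormkin_validation_error` whose
#' message names the offending field. Validation is idempotent.
#'
#' @param chemicals,soils,worms,scenarios Data frames as described above.
#' @param fractions_to_percent If `TRUE`, OM, clay and lipid supplied as
#'   fractions (all values <= 1) are multiplied by 100 on ingest. Off by
#'   default: units are a contract, not a guess.
#' @return The validated tibble (or, for [validate_inputs()], a named list
#'   of the four validated tibbles).
#' @examples
#' validate_chemicals(data.frame(
#'   name = "hexachlorobenzene", log_kow = 5.73, pka = NA,
#'   charge_type = "neutral", tpsa = 0, kd_measured = NA
#' ))
#' @name validate
NULL

abort_validation <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg),
        class = "wormkin_validation_error", field = field)
}

check_numeric <- function(df, field, min = -Inf, max = Inf,
                          strict_min = FALSE, allow_na = FALSE) {
  x <- df[[field]]
  if (is.null(x)) abort_validation(field, "column is missing")
  if (!is.numeric(x)) abort_validation(field, "must be numeric")
  bad_na <- is.na(x)
  if (!allow_na && any(bad_na)) abort_validation(field, "contains missing values")
  x <- x[!bad_na]
  if (strict_min && any(x <= min))
    abort_validation(field, sprintf("must be > %g", min))
  if (!strict_min && any(x < min))
    abort_validation(field, sprintf("must be >= %g", min))
  if (any(x > max)) abort_validation(field, sprintf("must be <= %g", max))
  invisible(TRUE)
}

maybe_percent <- function(df, fields, convert) {
  if (!convert) return(df)
  for (f in fields) {
    if (!is.null(df[[f]]) && all(df[[f]] <= 1, na.rm = TRUE))
      df[[f]] <- 100 * df[[f]]
  }
  df
}

charge_types <- c("neutral", "monovalent_acid", "monovalent_base")

#' @rdname validate
#' @export
validate_chemicals <- function(chemicals) {
  df <- tibble::as_tibble(chemicals)
  for (f in c("name", "log_kow", "charge_type", "tpsa"))
    if (is.null(df[[f]])) abort_validation(f, "column is missing")
  if (is.null(df[["pka"]])) df$pka <- NA_real_
  if (is.null(df[["kd_measured"]])) df$kd_measured <- NA_real_
  # all-NA columns arrive as logical from CSV readers
  for (f in c("pka", "kd_measured"))
    if (is.logical(df[[f]]) && all(is.na(df[[f]]))) df[[f]] <- as.numeric(df[[f]])
  if (!all(df$charge_type %in% charge_types))
    abort_validation("charge_type",
                     paste("must be one of", paste(charge_types, collapse = ", ")))
  check_numeric(df, "log_kow")
  check_numeric(df, "tpsa", min = 0)
  check_numeric(df, "pka", allow_na = TRUE)
  check_numeric(df, "kd_measured", min = 0, strict_min = TRUE, allow_na = TRUE)
  ionizable <- df$charge_type != "neutral"
  if (any(ionizable & is.na(df$pka)))
    abort_validation("pka", "required for ionizable compounds (charge_type != neutral)")
  df
}

#' @rdname validate
#' @export
validate_soils <- function(soils, fractions_to_percent = FALSE) {
  df <- tibble::as_tibble(soils)
  for (f in c("name", "om", "clay", "cec", "ph"))
    if (is.null(df[[f]])) abort_validation(f, "column is missing")
  df <- maybe_percent(df, c("om", "clay"), fractions_to_percent)
  check_numeric(df, "om", min = 0, strict_min = TRUE, max = 100)
  check_numeric(df, "clay", min = 0)
  check_numeric(df, "cec", min = 0)
  check_numeric(df, "ph", min = 0, max = 14)
  df
}

#' @rdname validate
#' @export
validate_worms <- function(worms, fractions_to_percent = FALSE) {
  df <- tibble::as_tibble(worms)
  for (f in c("species", "lipid", "ssa"))
    if (is.null(df[[f]])) abort_validation(f, "column is missing")
  df <- maybe_percent(df, "lipid", fractions_to_percent)
  check_numeric(df, "lipid", min = 0, strict_min = TRUE, max = 100)
  check_numeric(df, "ssa", min = 0, strict_min = TRUE)
  expected <- df$ssa * df$lipid
  if (is.null(df[["ssalipid"]])) {
    df$ssalipid <- expected
  } else if (!isTRUE(all.equal(df$ssalipid, expected))) {
    abort_validation("ssalipid", "must equal ssa * lipid exactly")
  }
  df
}

#' @rdname validate
#' @export
validate_scenarios <- function(scenarios) {
  df <- tibble::as_tibble(scenarios)
  for (f in c("route", "c0", "k0", "times"))
    if (is.null(df[[f]])) abort_validation(f, "column is missing")
  if (!all(df$route %in% c("porewater", "soil")))
    abort_validation("route", "must be 'porewater' or 'soil'")
  check_numeric(df, "c0", min = 0)
  check_numeric(df, "k0", min = 0)
  if (is.character(df$times)) df$times <- parse_times(df$times)
  if (!is.list(df$times)) df$times <- as.list(df$times)
  ok <- vapply(df$times, function(t) {
    is.numeric(t) && length(t) >= 1 && !anyNA(t) && all(t >= 0) &&
      (length(t) == 1 || all(diff(t) > 0))
  }, logical(1))
  if (!all(ok))
    abort_validation("times", "must be non-negative and strictly increasing")
  df
}

#' @rdname validate
#' @export
validate_inputs <- function(chemicals, soils, worms, scenarios,
                            fractions_to_percent = FALSE) {
  list(
    chemicals = validate_chemicals(chemicals),
    soils = validate_soils(soils, fractions_to_percent),
    worms = validate_worms(worms, fractions_to_percent),
    scenarios = validate_scenarios(scenarios)
  )
}

parse_times <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(s) as.numeric(trimws(s)))
}
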