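#' Rate-constant regression models
#'
#' A `rate_model` is a linear regression on a (possibly log10-transformed)
#' response with named coefficients, validation statistics and a
#' per-descriptor applicability domain. The package ships five of them (see
#' [wormkin_models()]): uptake (`kin`) and elimination (`kout`) rate
#' constants for the porewater and bulk-soil exposure routes, plus the
#' sorption model for `log_kd`.
#'
#' @param response `"kin"`, `"kout"` or `"log_kd"`.
#' @param route `"porewater"`, `"soil"` or `"none"`.
#' @param coefficients Named numeric vector: `intercept` plus one slope per
#'   descriptor (on the transformed response scale).
#' @param response_transform `"log10"` (predictions are back-transformed with
#'   `10^`) or `"identity"`.
#' @param stats Named list of fit statistics (`n`, `r_squared`,
#'   `adj_r_squared`, `rmse`, `q2_loo`, `ccc_loo`).
#' @param domain Named list of `c(low, high)` applicability ranges; must
#'   cover every descriptor.
#' @param provenance Free-text note on where the coefficients come from.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(response, route, coefficients,
                       response_transform = c("log10", "identity"),
                       stats = list(), domain = list(), provenance = "") {
  response_transform <- match.arg(response_transform)
  stopifnot(is.numeric(coefficients), "intercept" %in% names(coefficients))
  descriptors <- setdiff(names(coefficients), "intercept")
  missing_dom <- setdiff(descriptors, names(domain))
  if (length(missing_dom) > 0)
    abort(paste("no applicability domain for descriptor(s):",
                paste(missing_dom, collapse = ", ")),
          class = "wormkin_validation_error")
  if (!is.null(stats$n) && stats$n <= length(coefficients))
    abort("stats$n must exceed the number of coefficients",
          class = "wormkin_validation_error")
  structure(
    list(response = response, route = route, descriptors = descriptors,
         coefficients = coefficients, response_transform = response_transform,
         stats = stats, domain = domain, provenance = provenance),
    class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s (%s route), response scale: %s\n",
              x$response, x$route, x$response_transform))
  co <- x$coefficients
  eq <- paste0(sprintf("%.4g", co["intercept"]),
               paste(sprintf(" %+.4g*%s", co[x$descriptors], x$descriptors),
                     collapse = ""))
  lhs <- if (x$response_transform == "log10" && x$response != "log_kd")
    paste0("log10(", x$response, ")") else x$response
  cat(" ", lhs, "=", eq, "\n")
  if (length(x$stats) > 0)
    cat("  stats:", paste(names(x$stats), signif(unlist(x$stats), 3),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn rate_model Evaluate the model on new data; predictions on the
#'   transformed scale are back-transformed to natural units (so rate
#'   constants are strictly positive).
#' @param object,x A `rate_model`.
#' @param newdata Data frame containing the model's descriptor columns.
#' @param transformed Return the linear predictor (log10 scale) instead of
#'   the back-transformed value.
#' @param ... Unused.
#' @export
predict.rate_model <- function(object, newdata, transformed = FALSE, ...) {
  miss <- setdiff(object$descriptors, names(newdata))
  if (length(miss) > 0)
    abort(paste("newdata lacks descriptor(s):", paste(miss, collapse = ", ")),
          class = "wormkin_validation_error")
  X <- as.matrix(as.data.frame(newdata)[, object$descriptors, drop = FALSE])
  eta <- drop(X %*% object$coefficients[object$descriptors]) +
    object$coefficients[["intercept"]]
  if (!transformed && object$response_transform == "log10" &&
      object$response != "log_kd") 10^eta else eta
}

#' @describeIn rate_model Coefficient table (`term`, `estimate`).
#' @export
tidy.rate_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @describeIn rate_model One-row tibble of the stored fit statistics.
#' @export
glance.rate_model <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    response = x$response, route = x$route,
    n = s$n %||% NA_integer_,
    r_squared = s$r_squared %||% NA_real_,
    adj_r_squared = s$adj_r_squared %||% NA_real_,
    rmse = s$rmse %||% NA_real_,
    q2_loo = s$q2_loo %||% NA_real_,
    ccc_loo = s$ccc_loo %||% NA_real_
  )
}

#' Load the packaged reference rate-constant models
#'
#' Returns the five packaged `rate_model`s: `kin_porewater`, `kout_porewater`,
#' `kin_soil`, `kout_soil` and `kd_porewater` (the sorption model). The
#' coefficient file is a SYNTHETIC reference calibration: it reproduces the
#' documented structure of OECD-317-derived earthworm toxicokinetic
#' regressions (descriptor sets, coefficient signs, applicability domains,
#' realistic rate-constant ranges) with validation statistics computed from
#' the packaged synthetic calibration table
#' (`inst/extdata/reference_calibration_synthetic.csv`), not transcribed
#' published coefficients. See `vignette("wormkin-methods")`.
#'
#' The file carries an md5 checksum which is verified on first load; a
#' mismatch (a silently edited coefficient file) is an error.
#'
#' @param path Optional path to an alternative model JSON (checksum then
#'   skipped unless a sibling `.md5` file exists).
#' @return Named list of `rate_model` objects.
#' @examples
#' glance(wormkin_models()$kin_porewater)
#' @export
wormkin_models <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$models)) return(the$models)
    path <- system.file("extdata", "reference_models_synthetic.json",
                        package = "wormkin", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  md5_path <- paste0(path, ".md5")
  if (file.exists(md5_path)) {
    want <- trimws(strsplit(readLines(md5_path, warn = FALSE)[1], "\\s+")[[1]][1])
    got <- unname(tools::md5sum(path))
    if (!identical(want, got))
      abort(sprintf("checksum mismatch for model file %s (want %s, got %s)",
                    path, want, got),
            class = "wormkin_checksum_error")
  }
  models <- read_rate_models(path)
  if (cache) the$models <- models
  models
}

#' Serialize rate models to / from JSON
#'
#' @param models Named list of `rate_model`s (or a single one).
#' @param path JSON file path.
#' @return `read_rate_models()` returns the named list; `write_rate_models()`
#'   returns `path` invisibly.
#' @export
write_rate_models <- function(models, path) {
  if (inherits(models, "rate_model")) models <- list(model = models)
  payload <- purrr::map(models, function(m) {
    list(response = m$response, route = m$route,
         descriptors = as.list(m$descriptors),
         coefficients = as.list(m$coefficients),
         response_transform = m$response_transform,
         stats = m$stats, domain = m$domain, provenance = m$provenance)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rate_models
#' @export
read_rate_models <- function(path) {
  payload <- jsonlite::read_json(path)
  purrr::map(payload, function(p) {
    rate_model(
      response = p$response, route = p$route,
      coefficients = unlist(p$coefficients),
      response_transform = p$response_transform,
      stats = p$stats,
      domain = purrr::map(p$domain, ~ as.numeric(unlist(.x))),
      provenance = p$provenance %||% ""
    )
  })
}

#' Predict uptake and elimination rate constants
#'
#' Evaluates the packaged route-specific regressions. Uptake (`kin`) uses
#' log K_om, soil OM and SSAlipid for both routes. Elimination (`kout`) uses
#' TPSA and OM for the porewater route (interspecies differences are
#' negligible there, so `ssalipid` is ignored) and additionally SSAlipid for
#' the bulk-soil route. Out-of-domain inputs warn and proceed.
#'
#' @param route `"porewater"` or `"soil"`.
#' @param log_kom OM-normalized sorption coefficient, log10.
#' @param om Soil organic matter, percent.
#' @param ssalipid Earthworm SSA (m^2/kg) times lipid content (% wet weight).
#' @param tpsa Topological polar surface area, Angstrom^2.
#' @param models Packaged models, see [wormkin_models()].
#' @param quiet Suppress domain warnings.
#' @return `kin` (L/kg/d or kg/kg/d) or `kout` (1/d); strictly positive.
#' @examples
#' predict_uptake_rate("porewater", log_kom = 3, om = 10, ssalipid = 2)
#' predict_elimination_rate("porewater", tpsa = 25, om = 10)
#' @export
predict_uptake_rate <- function(route = c("porewater", "soil"),
                                log_kom, om, ssalipid,
                                models = wormkin_models(), quiet = FALSE) {
  route <- match.arg(route)
  m <- models[[paste0("kin_", route)]]
  newdata <- tibble::tibble(log_kom = log_kom, om = om, ssalipid = ssalipid)
  stopifnot(all(is.finite(as.matrix(newdata))))
  if (!quiet) warn_if_outside(newdata, m, paste(route, "kin"))
  predict(m, newdata)
}

#' @rdname predict_uptake_rate
#' @export
predict_elimination_rate <- function(route = c("porewater", "soil"),
                                     tpsa, om, ssalipid = NULL,
                                     models = wormkin_models(), quiet = FALSE) {
  route <- match.arg(route)
  m <- models[[paste0("kout_", route)]]
  if (route == "soil" && is.null(ssalipid))
    abort_validation("ssalipid", "required for the soil-route kout model")
  newdata <- tibble::tibble(tpsa = tpsa, om = om)
  if ("ssalipid" %in% m$descriptors) newdata$ssalipid <- ssalipid
  stopifnot(all(is.finite(as.matrix(newdata))))
  if (!quiet) warn_if_outside(newdata, m, paste(route, "kout"))
  predict(m, newdata)
}
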