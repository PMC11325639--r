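#' pH-adjusted octanol-water partition coefficient (log D_ow)
#'
#' For monovalent ionizable organic compounds the effective hydrophobicity at
#' soil pH is the octanol-water partition coefficient of the neutral species
#' weighted by the neutral fraction (Henderson-Hasselbalch):
#' acids `log_dow = log_kow - log10(1 + 10^(ph - pka))`, bases
#' `log_dow = log_kow - log10(1 + 10^(pka - ph))`. Neutral compounds are
#' returned unchanged (`log_dow == log_kow`).
#'
#' @param log_kow Octanol-water partition coefficient, log10.
#' @param ph Soil pH (0-14); taken as the porewater pH.
#' @param charge_type `"neutral"`, `"monovalent_acid"` or
#'   `"monovalent_base"`; multivalent and zwitterionic species are out of
#'   scope and rejected.
#' @param pka Acid dissociation constant; required unless neutral.
#' @return `log_dow`, dimensionless, same length as the inputs.
#' @examples
#' log_dow_adjust(3.0, ph = 5, charge_type = "monovalent_acid", pka = 5)
#' @export
log_dow_adjust <- function(log_kow, ph, charge_type = "neutral", pka = NULL) {
  if (!all(charge_type %in% charge_types))
    abort_validation("charge_type",
                     "only neutral and monovalent ionizable compounds are supported")
  if (any(ph < 0 | ph > 14)) abort_validation("ph", "must be within 0-14")
  n <- max(length(log_kow), length(ph), length(charge_type))
  log_kow <- rep_len(log_kow, n); ph <- rep_len(ph, n)
  charge_type <- rep_len(charge_type, n)
  pka <- rep_len(if (is.null(pka)) NA_real_ else pka, n)
  ionizable <- charge_type != "neutral"
  if (any(ionizable & is.na(pka)))
    abort_validation("pka", "required for ionizable compounds")
  shift <- numeric(n)
  acid <- charge_type == "monovalent_acid"
  base <- charge_type == "monovalent_base"
  shift[acid] <- log10(1 + 10^(ph[acid] - pka[acid]))
  shift[base] <- log10(1 + 10^(pka[base] - ph[base]))
  log_kow - shift
}

#' Organic-matter-normalized sorption coefficient (log K_om)
#'
#' K_om is the soil-porewater sorption coefficient K_d (L/kg) divided by the
#' organic-matter fraction of the soil: `log_kom = log10(kd / (om / 100))`.
#' OM is supplied in percent dry weight.
#'
#' @param kd Sorption coefficient, L/kg, > 0.
#' @param om Soil organic matter, percent (0, 100].
#' @return `log_kom`, dimensionless.
#' @examples
#' compute_log_kom(kd = 100, om = 10) # 3
#' @export
compute_log_kom <- function(kd, om) {
  if (any(kd <= 0)) abort_validation("kd", "must be > 0")
  if (any(om <= 0 | om > 100)) abort_validation("om", "must be in (0, 100]")
  log10(kd / (om / 100))
}

#' Predict the soil-porewater sorption coefficient from log D_ow and OM
#'
#' Linear regression on the chemical's pH-adjusted hydrophobicity and the
#' soil organic-matter content, `log_kd = b0 + b1 * log_dow + b2 * om`,
#' using the packaged reference sorption model (see [wormkin_models()]).
#' Inputs outside the model's applicability domain (log D_ow 1.69-6.63,
#' OM 0.97-39.9 %) produce a warning, never an error: the prediction is an
#' extrapolation, not a failure.
#'
#' @param log_dow pH-adjusted log K_ow (see [log_dow_adjust()]).
#' @param om Soil organic matter, percent.
#' @param model A `rate_model` with `response = "log_kd"`; defaults to the
#'   packaged reference model.
#' @param quiet Suppress the out-of-domain warning.
#' @return Predicted `log_kd` (log10 of K_d in L/kg).
#' @export
predict_log_kd <- function(log_dow, om, model = wormkin_models()$kd_porewater,
                           quiet = FALSE) {
  stopifnot(is.finite(log_dow), is.finite(om))
  newdata <- tibble::tibble(log_dow = log_dow, om = om)
  if (!quiet) warn_if_outside(newdata, model)
  predict(model, newdata)
}

#' Porewater concentration from a bulk-soil concentration
#'
#' Equilibrium partitioning: `c_porewater = c_soil / kd`.
#'
#' @param c_soil Concentration in bulk soil, mg/kg dry weight, >= 0.
#' @param kd Sorption coefficient, L/kg, > 0 (measured if available,
#'   otherwise from [predict_log_kd()]).
#' @return Porewater concentration, mg/L.
#' @examples
#' soil_to_porewater(2, kd = 20) # 0.1
#' @export
soil_to_porewater <- function(c_soil, kd) {
  if (any(kd <= 0)) abort_validation("kd", "must be > 0")
  if (any(c_soil < 0)) abort_validation("c_soil", "must be >= 0")
  c_soil / kd
}

#' Applicability-domain check
#'
#' Compares descriptor values against a model's training ranges (closed
#' intervals: a boundary value is inside). Reporting only - out-of-domain
#' values are flagged, never rejected, because predictions outside the
#' domain are extrapolations that may still be useful.
#'
#' @param values Named list or one-row data frame of descriptor values
#'   (e.g. `list(log_kom = 3, om = 10, ssa = 1, lipid = 2)`).
#' @param model A `rate_model`; its `domain` field holds the per-descriptor
#'   `[low, high]` ranges. Descriptors absent from `values` are skipped.
#' @return A `domain_report` tibble with columns `descriptor`, `value`,
#'   `low`, `high`, `status` (`"inside"`, `"below"` or `"above"`).
#' @examples
#' m <- wormkin_models()$kin_porewater
#' domain_check(list(log_kom = 3, om = 45, ssa = 1, lipid = 2), m)
#' @export
domain_check <- function(values, model) {
  values <- as.list(values)
  dom <- model$domain
  keep <- intersect(names(dom), names(values))
  rows <- purrr::map(keep, function(d) {
    v <- as.numeric(values[[d]])
    lo <- dom[[d]][1]; hi <- dom[[d]][2]
    tibble::tibble(
      descriptor = d, value = v, low = lo, high = hi,
      status = dplyr::case_when(v < lo ~ "below", v > hi ~ "above",
                                .default = "inside")
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("domain_report", class(out))
  out
}

warn_if_outside <- function(newdata, model, context = model$response) {
  flags <- purrr::map(seq_len(nrow(newdata)),
                      function(i) domain_check(newdata[i, ], model))
  bad <- dplyr::filter(dplyr::bind_rows(flags), .data$status != "inside")
  if (nrow(bad) > 0) {
    u <- dplyr::distinct(bad, .data$descriptor, .data$status)
    warn(sprintf(
      "%d value(s) outside the applicability domain of the %s model (%s); predictions are extrapolations",
      nrow(bad), context,
      paste(u$descriptor, u$status, collapse = ", ")),
      class = "wormkin_domain_warning")
  }
  invisible(bad)
}

#' Soil-porewater partitioning summary for one chemical-soil pair
#'
#' Convenience wrapper combining [log_dow_adjust()], measured-vs-predicted
#' K_d resolution and [compute_log_kom()].
#'
#' @param chemical,soil One-row validated tibbles (see [validate_chemicals()]).
#' @param kd_policy `"measured_first"` (use `kd_measured` when present) or
#'   `"always_predict"`.
#' @param models Packaged models list, see [wormkin_models()].
#' @param quiet Suppress domain warnings.
#' @return A one-row tibble: `log_dow`, `log_kd`, `log_kom`, `kd_source`.
#' @export
partition_chemical <- function(chemical, soil,
                               kd_policy = c("measured_first", "always_predict"),
                               models = wormkin_models(), quiet = FALSE) {
  kd_policy <- match.arg(kd_policy)
  log_dow <- log_dow_adjust(chemical$log_kow, soil$ph,
                            chemical$charge_type, chemical$pka)
  use_measured <- kd_policy == "measured_first" && !is.na(chemical$kd_measured)
  if (use_measured) {
    log_kd <- log10(chemical$kd_measured)
    kd_source <- "measured"
  } else {
    log_kd <- predict_log_kd(log_dow, soil$om, models$kd_porewater, quiet = quiet)
    kd_source <- "predicted"
  }
  tibble::tibble(log_dow = log_dow, log_kd = log_kd,
                 log_kom = compute_log_kom(10^log_kd, soil$om),
                 kd_source = kd_source)
}
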