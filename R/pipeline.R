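#' End-to-end body-residue prediction
#'
#' For every chemical x soil x earthworm x scenario combination: compute the
#' pH-adjusted log D_ow, resolve K_d (measured or predicted from the
#' sorption model), convert between soil and porewater concentrations,
#' derive log K_om, predict the route-specific rate constants, and evaluate
#' the closed-form body residue on the scenario's time grid together with
#' the steady-state BCF and per-combination applicability-domain flags.
#' Deterministic: the same inputs always give the same output.
#'
#' @param chemicals,soils,worms,scenarios Input tables (validated on entry,
#'   see [validate_inputs()]).
#' @param route Rate-model route to use: `"porewater"`, `"soil"` or
#'   `"both"`.
#' @param kd_policy `"measured_first"` (default: use a measured K_d when the
#'   chemical record has one, otherwise predict) or `"always_predict"`.
#' @param domain_policy `"warn"` (default: flag out-of-domain descriptors
#'   and proceed) or `"strict"` (abort on any violation).
#' @param models Packaged models, see [wormkin_models()].
#' @return A tibble with one row per combination and time point: identifier
#'   columns (`chemical`, `soil`, `species`, `scenario`, `route`), the
#'   partitioning intermediates (`log_dow`, `log_kd`, `log_kom`,
#'   `kd_source`), rate constants and `bcf`, `time` (d), `c_earthworm`
#'   (mg/kg ww) and `domain_flags` (semicolon-joined `descriptor:status`
#'   pairs, empty when fully inside).
#' @examples
#' chem <- data.frame(name = "dieldrin", log_kow = 5.2, pka = NA,
#'                    charge_type = "neutral", tpsa = 12.5, kd_measured = NA)
#' soil <- data.frame(name = "loam", om = 8.2, clay = 20, cec = 15, ph = 6.1)
#' worm <- data.frame(species = "E. fetida", lipid = 2.64, ssa = 1.45)
#' scen <- data.frame(route = "soil", c0 = 1, k0 = 0.02,
#'                    times = "1;2;4;7;14;21")
#' predict_residues(chem, soil, worm, scen, route = "porewater")
#' @export
predict_residues <- function(chemicals, soils, worms, scenarios,
                             route = c("porewater", "soil", "both"),
                             kd_policy = c("measured_first", "always_predict"),
                             domain_policy = c("warn", "strict"),
                             models = wormkin_models()) {
  route <- match.arg(route)
  kd_policy <- match.arg(kd_policy)
  domain_policy <- match.arg(domain_policy)
  inp <- validate_inputs(chemicals, soils, worms, scenarios)
  routes <- if (route == "both") c("porewater", "soil") else route

  empty <- tibble::tibble(
    chemical = character(), soil = character(), species = character(),
    scenario = integer(), route = character(), kd_source = character(),
    log_dow = numeric(), log_kd = numeric(), log_kom = numeric(),
    kin = numeric(), kout = numeric(), bcf = numeric(),
    time = numeric(), c_earthworm = numeric(), domain_flags = character())
  if (nrow(inp$scenarios) == 0 || nrow(inp$chemicals) == 0 ||
      nrow(inp$soils) == 0 || nrow(inp$worms) == 0) return(empty)

  combos <- tidyr::expand_grid(
    ci = seq_len(nrow(inp$chemicals)), si = seq_len(nrow(inp$soils)),
    wi = seq_len(nrow(inp$worms)), zi = seq_len(nrow(inp$scenarios)),
    route = routes)

  rows <- purrr::pmap(combos, function(ci, si, wi, zi, route) {
    chem <- inp$chemicals[ci, ]; soil <- inp$soils[si, ]
    worm <- inp$worms[wi, ]; scen <- inp$scenarios[zi, ]
    part <- partition_chemical(chem, soil, kd_policy, models, quiet = TRUE)
    kd <- 10^part$log_kd

    kin_m <- models[[paste0("kin_", route)]]
    kout_m <- models[[paste0("kout_", route)]]
    vals <- list(log_kom = part$log_kom, om = soil$om, ssa = worm$ssa,
                 lipid = worm$lipid, ssalipid = worm$ssalipid,
                 tpsa = chem$tpsa, log_dow = part$log_dow)
    flags <- dplyr::bind_rows(
      domain_check(vals, kin_m), domain_check(vals, kout_m),
      if (part$kd_source == "predicted") domain_check(vals, models$kd_porewater))
    flags <- dplyr::distinct(
      dplyr::filter(flags, .data$status != "inside"),
      .data$descriptor, .data$status)
    flag_str <- paste(flags$descriptor, flags$status, sep = ":", collapse = ";")
    if (domain_policy == "strict" && nrow(flags) > 0)
      abort(sprintf(
        "out-of-domain descriptors for %s / %s / %s under strict domain policy: %s",
        chem$name, soil$name, worm$species, flag_str),
        class = "wormkin_domain_error")

    kin <- predict_uptake_rate(route, part$log_kom, soil$om, worm$ssalipid,
                               models, quiet = TRUE)
    kout <- predict_elimination_rate(route, chem$tpsa, soil$om,
                                     worm$ssalipid, models, quiet = TRUE)
    c0 <- if (route == scen$route) scen$c0
          else if (route == "porewater") scen$c0 / kd else scen$c0 * kd
    times <- scen$times[[1]]
    cw <- closed_form_cw(kin, kout, c0, scen$k0, times)
    tibble::tibble(
      chemical = chem$name, soil = soil$name, species = worm$species,
      scenario = zi, route = route, kd_source = part$kd_source,
      log_dow = part$log_dow, log_kd = part$log_kd, log_kom = part$log_kom,
      kin = kin, kout = kout, bcf = steady_state_bcf(kin, kout),
      time = times, c_earthworm = cw, domain_flags = flag_str)
  })
  out <- dplyr::bind_rows(rows)
  n_out <- sum(out$domain_flags != "")
  if (domain_policy == "warn" && n_out > 0)
    warn(sprintf("%d prediction row(s) involve out-of-domain descriptors (see `domain_flags`)",
                 n_out),
         class = "wormkin_domain_warning")
  out
}

#' Pooled model-evaluation summary
#'
#' Computes the standard evaluation battery on paired observed/predicted
#' values: Nash-Sutcliffe efficiency ([nse()]), RMSE, and the percentage of
#' predictions within a factor of 3, 5 and 10 of the observations
#' ([pct_within_factor()]). Values are pooled across all rows by default;
#' `by` gives per-subset summaries (e.g. species or exposure-time windows).
#'
#' @param data Data frame holding the joined observations and predictions.
#' @param observed,predicted Column names (strings).
#' @param factors Fold-difference thresholds.
#' @param by Optional character vector of grouping columns.
#' @return An `evaluation_summary` tibble: `n`, `nse`, `rmse` and one
#'   `pct_within_<f>` column per factor (plus the `by` columns).
#' @examples
#' df <- data.frame(obs = c(1, 2, 3, 4), pred = c(1.2, 1.8, 3.5, 4.1))
#' evaluate_predictions(df, "obs", "pred")
#' @export
evaluate_predictions <- function(data, observed = "observed",
                                 predicted = "predicted",
                                 factors = c(3, 5, 10), by = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort_validation("data", "empty join")
  one <- function(d) {
    o <- d[[observed]]; p <- d[[predicted]]
    res <- tibble::tibble(n = length(o), nse = nse(o, p),
                          rmse = sqrt(mean((o - p)^2)))
    pw <- pct_within_factor(o, p, factors)
    for (i in seq_along(factors))
      res[[paste0("pct_within_", factors[i])]] <- pw[i]
    res
  }
  out <- if (is.null(by)) one(data) else {
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  }
  class(out) <- c("evaluation_summary", class(out))
  out
}
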