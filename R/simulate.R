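#' Default descriptor sampling ranges
#'
#' The applicability box of the packaged reference models: log K_om
#' 1.22-5.23, log K_ow / log D_ow 1.69-6.63, TPSA 0-50.9 A^2, OM
#' 0.97-39.9 %, clay 4.02-50.0 %, CEC 1.41-88.8 cmol+/kg, pH 5.11-6.97,
#' SSA 0.70-1.45 m^2/kg, lipid 1.55-2.64 % ww (SSAlipid is the product of
#' the SSA and lipid bounds).
#'
#' @return Named list of `c(low, high)` ranges.
#' @export
wormkin_domains <- function() {
  list(
    log_kom = c(1.22, 5.23), log_kow = c(1.69, 6.63), log_dow = c(1.69, 6.63),
    tpsa = c(0, 50.9), om = c(0.97, 39.9), clay = c(4.02, 50.0),
    cec = c(1.41, 88.8), ph = c(5.11, 6.97), ssa = c(0.70, 1.45),
    lipid = c(1.55, 2.64), ssalipid = c(0.70 * 1.55, 1.45 * 2.64)
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gaussian-copula companion with approximately the requested Pearson
# correlation between the resulting *uniform* marginals
companion_uniform <- function(z_base, r) {
  rho <- 2 * sin(pi * r / 6)
  z <- rho * z_base + sqrt(1 - rho^2) * rnorm(length(z_base))
  pnorm(z)
}

scale_to <- function(u, range) range[1] + u * (range[2] - range[1])

#' Simulate a descriptor table with realistic correlation structure
#'
#' Samples `n` pseudo-records uniformly over the applicability box
#' ([wormkin_domains()]) and induces the intercorrelations seen in real
#' earthworm toxicokinetic training data: log K_ow correlated with log K_om
#' (target r ~ 0.7), TPSA anticorrelated with log K_om (r ~ -0.85), and
#' clay / CEC / pH tracking soil OM. SSAlipid is the exact product
#' `ssa * lipid`, and `log_kd = log_kom + log10(om/100)` so the derived
#' sorption coefficient is self-consistent. Deterministic given `seed`.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param r_kow,r_tpsa Target correlations of the chemical companions with
#'   log K_om.
#' @param domains Sampling ranges, see [wormkin_domains()].
#' @return A tibble with columns `log_kom`, `log_kow`, `tpsa`, `om`, `clay`,
#'   `cec`, `ph`, `ssa`, `lipid`, `ssalipid` and `kd_measured` (the sorption
#'   coefficient implied by `log_kom` and `om`; log K_d itself is not a
#'   separate candidate descriptor because it is `log_kom + log10(om/100)`
#'   by definition and therefore carries no information beyond K_om once OM
#'   is a candidate).
#' @examples
#' sim_descriptor_table(n = 5, seed = 1)
#' @export
sim_descriptor_table <- function(n, seed, r_kow = 0.7, r_tpsa = -0.85,
                                 domains = wormkin_domains()) {
  stopifnot(n > 0)
  with_seed(seed, {
    z_chem <- rnorm(n)
    z_soil <- rnorm(n)
    tab <- tibble::tibble(
      log_kom = scale_to(pnorm(z_chem), domains$log_kom),
      log_kow = scale_to(companion_uniform(z_chem, r_kow), domains$log_kow),
      tpsa = scale_to(companion_uniform(z_chem, r_tpsa), domains$tpsa),
      om = scale_to(pnorm(z_soil), domains$om),
      clay = scale_to(companion_uniform(z_soil, 0.65), domains$clay),
      cec = scale_to(companion_uniform(z_soil, 0.70), domains$cec),
      ph = scale_to(companion_uniform(z_soil, -0.50), domains$ph),
      ssa = scale_to(runif(n), domains$ssa),
      lipid = scale_to(runif(n), domains$lipid)
    )
    tab$ssalipid <- tab$ssa * tab$lipid
    tab$kd_measured <- 10^(tab$log_kom + log10(tab$om / 100))
    tab
  })
}

#' Simulate a rate-constant training dataset from the packaged models
#'
#' Generates a descriptor table (or takes one) and adds uptake and
#' elimination rate constants for both exposure routes:
#' `log10(rate) = model linear predictor + Normal(0, noise_sigma_log10)`,
#' back-transformed, so all rates are strictly positive and regressions on
#' log10 scale see homoscedastic noise.
#'
#' @param n,seed Passed to [sim_descriptor_table()] (ignored if `table`
#'   given; the seed still drives the noise).
#' @param table Optional pre-built descriptor table.
#' @param models Packaged models, see [wormkin_models()].
#' @param noise_sigma_log10 Lognormal noise, log10 units (default 0.25,
#'   the residual scatter typical of OECD-317-derived rate constants).
#' @return The descriptor tibble with columns `kin_porewater`,
#'   `kout_porewater`, `kin_soil`, `kout_soil` appended.
#' @examples
#' sim_rate_dataset(n = 5, seed = 1)
#' @export
sim_rate_dataset <- function(n = 75, seed = 1, table = NULL,
                             models = wormkin_models(),
                             noise_sigma_log10 = 0.25) {
  stopifnot(noise_sigma_log10 >= 0)
  if (is.null(table)) table <- sim_descriptor_table(n, seed)
  n <- nrow(table)
  with_seed(seed + 1L, {
    for (nm in c("kin_porewater", "kout_porewater", "kin_soil", "kout_soil")) {
      eta <- predict(models[[nm]], table, transformed = TRUE)
      table[[nm]] <- 10^(eta + rnorm(n, 0, noise_sigma_log10))
    }
  })
  table
}

#' Simulate an OECD-317-style exposure / body-residue time series pair
#'
#' Exposure follows first-order decay `c0 * exp(-k0 * t)`, body residues the
#' one-compartment closed form; both are multiplied by lognormal noise with
#' coefficient of variation `cv` (mean-one noise, so expectations are
#' unbiased). Deterministic given `seed`.
#'
#' @inheritParams body_residue_closed_form
#' @param days Sampling days (e.g. `c(1, 2, 4, 7, 14, 21)`).
#' @param cv Coefficient of variation of the multiplicative noise (0 = exact
#'   curves).
#' @param seed Integer seed.
#' @return Tibble with columns `time`, `exposure`, `body_residue`.
#' @examples
#' sim_uptake_series(kin = 10, kout = 0.4, c0 = 0.5, k0 = 0.05,
#'                   days = c(1, 2, 4, 7, 14), cv = 0.1, seed = 1)
#' @export
sim_uptake_series <- function(kin, kout, c0, k0 = 0, days, cv = 0.1, seed = 1) {
  check_kinetic_params(kin, kout, c0, k0, days)
  stopifnot(cv >= 0)
  n <- length(days)
  with_seed(seed, {
    noise <- function() {
      if (cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble::tibble(
      time = days,
      exposure = c0 * exp(-k0 * days) * noise(),
      body_residue = closed_form_cw(kin, kout, c0, k0, days) * noise()
    )
  })
}
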