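test_that("kinetic fitting recovers noiseless closed-form parameters", {
  times <- c(1, 2, 4, 7, 10, 14, 21)
  tr <- body_residue_closed_form(10, 0.4, c0 = 0.5, k0 = 0.05, times)
  fit <- fit_kinetics_to_timeseries(
    data.frame(time = tr$time, value = tr$c_earthworm), c0 = 0.5, k0 = 0.05)
  expect_lt(abs(fit$kin - 10) / 10, 1e-4)
  expect_lt(abs(fit$kout - 0.4) / 0.4, 1e-4)
  td <- tidy(fit)
  expect_equal(td$term, c("kin", "kout"))

  # constant exposure (k0 = 0) is the one-compartment uptake curve
  tr0 <- body_residue_closed_form(10, 0.4, c0 = 0.5, k0 = 0, times)
  expect_equal(tr0$c_earthworm, 10 * 0.5 / 0.4 * (1 - exp(-0.4 * times)),
               tolerance = 1e-12)
  fit0 <- fit_kinetics_to_timeseries(
    data.frame(time = times, value = tr0$c_earthworm), c0 = 0.5, k0 = 0)
  expect_lt(abs(fit0$kout - 0.4) / 0.4, 1e-4)
})

test_that("a flat residue series is flagged non-identifiable", {
  flat <- data.frame(time = c(1, 3, 7, 14), value = rep(2, 4))
  expect_error(fit_kinetics_to_timeseries(flat, c0 = 1, k0 = 0),
               class = "wormkin_fit_error")
})

test_that("kinetic fitting tolerates realistic measurement noise", {
  # CV = 10% lognormal noise, 10 sampling days: median recovery error
  # below 15% over 100 replicates
  days <- c(1, 2, 3, 5, 7, 10, 14, 21, 28, 35)
  err <- t(vapply(1:100, function(s) {
    d <- sim_uptake_series(10, 0.4, c0 = 0.5, k0 = 0.05, days = days,
                           cv = 0.10, seed = 1000 + s)
    f <- fit_kinetics_to_timeseries(
      data.frame(time = d$time, value = d$body_residue), c0 = 0.5, k0 = 0.05)
    c(abs(f$kin - 10) / 10, abs(f$kout - 0.4) / 0.4)
  }, numeric(2)))
  expect_lt(median(err[, 1]), 0.15)
  expect_lt(median(err[, 2]), 0.15)
})

test_that("descriptor screening groups by significant intercorrelation", {
  set.seed(5)
  x <- rnorm(75)
  tab <- tibble::tibble(a = x, b = x, c = rnorm(75))
  g <- screen_descriptors(tab, categories = list(chem = c("a", "b", "c")))
  expect_equal(g$group[g$descriptor == "a"], g$group[g$descriptor == "b"])
  expect_false(g$group[g$descriptor == "c"] == g$group[g$descriptor == "a"])

  expect_error(
    screen_descriptors(tibble::tibble(a = rep(1, 10), b = rnorm(10)),
                       categories = list(chem = c("a", "b"))),
    class = "wormkin_validation_error")
})

test_that("independent descriptors are linked at about the nominal alpha rate", {
  links <- vapply(1:200, function(s) {
    set.seed(s)
    tab <- tibble::tibble(a = rnorm(75), b = rnorm(75))
    g <- screen_descriptors(tab, alpha = 0.01,
                            categories = list(chem = c("a", "b")))
    g$group[1] == g$group[2]
  }, logical(1))
  # expect ~1% false links; allow up to 4% (binomial upper tail, n = 200)
  expect_lt(mean(links), 0.04)
})

test_that("screening reproduces the expected chemical/soil/earthworm grouping on the calibration table", {
  tab <- reference_calibration()
  g <- screen_descriptors(tab)
  grp_of <- function(d) g$group[g$descriptor == d]
  expect_equal(grp_of("log_kow"), grp_of("log_kom"))
  expect_equal(grp_of("log_kow"), grp_of("tpsa"))
  expect_equal(grp_of("om"), grp_of("clay"))
  expect_equal(grp_of("om"), grp_of("cec"))
  expect_equal(grp_of("om"), grp_of("ph"))
  expect_equal(grp_of("lipid"), grp_of("ssa"))
  expect_equal(grp_of("lipid"), grp_of("ssalipid"))
  # the three categories remain distinct groups
  expect_equal(length(unique(g$group)), 3)
})

test_that("stepwise regression selects the true predictor and honors thresholds", {
  set.seed(21)
  n <- 75
  tab <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  tab$y <- 2 + 3 * tab$x1 + rnorm(n)
  sw <- build_regression_stepwise(
    tab, "y", groups = screen_descriptors(
      tab[, c("x1", "x2")], categories = list(a = "x1", b = "x2")))
  expect_equal(sw$selected, "x1")
  ci <- stats::confint(sw$model)["x1", ]
  expect_true(ci[1] < 3 && 3 < ci[2])
  expect_true(all(c("step", "action", "descriptor", "p_value") %in%
                    names(sw$trace)))
})

test_that("noiseless generated responses are recovered to machine precision", {
  tab <- sim_rate_dataset(n = 75, seed = 4, noise_sigma_log10 = 0)
  tab$y <- log10(tab$kin_porewater)
  # lm warns about essentially perfect fits: that is the point here
  sw <- suppressWarnings(build_regression_stepwise(tab, "y"))
  expect_setequal(sw$selected, c("log_kom", "om", "ssalipid"))
  co_true <- wormkin_models()$kin_porewater$coefficients
  co_fit <- coef(sw$model)
  expect_equal(co_fit[["(Intercept)"]], co_true[["intercept"]],
               tolerance = 1e-9)
  for (d in c("log_kom", "om", "ssalipid"))
    expect_equal(co_fit[[d]], co_true[[d]], tolerance = 1e-9)
  expect_equal(sw$stats$r_squared, 1, tolerance = 1e-12)
})

test_that("pure-noise responses fall back to an intercept-only model with a warning", {
  set.seed(33)
  tab <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40), y = rnorm(40))
  expect_warning(
    sw <- build_regression_stepwise(
      tab, "y", groups = screen_descriptors(
        tab[, c("x1", "x2")], categories = list(a = "x1", b = "x2")),
      alpha_enter = 0.001),
    class = "wormkin_stepwise_warning")
  expect_length(sw$selected, 0)
})

test_that("retained descriptors keep variance inflation factors below 2", {
  for (s in 1:10) {
    tab <- sim_rate_dataset(n = 75, seed = s)
    tab$y <- log10(tab$kin_porewater)
    sw <- suppressWarnings(build_regression_stepwise(tab, "y"))
    if (length(sw$selected) > 1) {
      v <- diag(solve(cor(as.matrix(tab[, sw$selected]))))
      expect_lt(max(v), 2)
    }
  }
})

test_that("LOO validation: perfect fits give Q2 = CCC = 1; permuted responses give Q2 <= 0", {
  set.seed(8)
  tab <- tibble::tibble(x = rnorm(30))
  tab$y <- 1 + 2 * tab$x
  loo <- loo_validate(tab, "y", "x")
  expect_equal(loo$q2_loo, 1, tolerance = 1e-8)
  expect_equal(loo$ccc_loo, 1, tolerance = 1e-8)

  tab$y <- 1 + 2 * tab$x + rnorm(30, 0, 0.5)
  neg <- vapply(1:200, function(s) {
    set.seed(s)
    perm <- tab
    perm$y <- sample(perm$y)
    loo_validate(perm, "y", "x")$q2_loo <= 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("Nash-Sutcliffe efficiency anchors and hand value", {
  o <- c(1, 2, 3)
  expect_equal(nse(o, o), 1)
  expect_equal(nse(o, rep(mean(o), 3)), 0)
  expect_equal(nse(o, c(1, 2, 4)), 0.5)
  expect_error(nse(c(1, 1), c(1, 2)), class = "wormkin_validation_error")
  # invariant under common affine rescaling
  p <- c(1.2, 1.9, 3.3)
  expect_equal(nse(10 + 3 * o, 10 + 3 * p), nse(o, p), tolerance = 1e-12)
})

test_that("factor-of-N percentages: hand counts, symmetry, monotonicity", {
  expect_equal(pct_within_factor(c(1, 2), c(1, 2), 1), 100)
  expect_equal(pct_within_factor(c(1, 1), c(4, 20), 5), 50)
  expect_equal(pct_within_factor(c(1, 1), c(4, 20), 10), 50)
  expect_equal(pct_within_factor(c(1, 1), c(4, 20), 25), 100)
  # boundary counts as within (closed inequality)
  expect_equal(pct_within_factor(1, 3, 3), 100)
  set.seed(2)
  o <- exp(rnorm(40)); p <- exp(rnorm(40))
  expect_equal(pct_within_factor(o, p, c(3, 5, 10)),
               pct_within_factor(p, o, c(3, 5, 10)))
  pw <- pct_within_factor(o, p, c(2, 3, 5, 10, 30))
  expect_true(all(diff(pw) >= 0))
  expect_error(pct_within_factor(c(-1, 1), c(1, 1), 3),
               class = "wormkin_validation_error")
})

test_that("Lin's concordance: anchors, hand value, scale invariance", {
  x <- c(1, 2, 3)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_equal(lin_ccc(x, c(2, 3, 4)), 4 / 7, tolerance = 1e-4)
  set.seed(3)
  a <- rnorm(25); b <- a + rnorm(25, 0, 0.3)
  expect_equal(lin_ccc(2 * a, 2 * b), lin_ccc(a, b), tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1), c(1, 2)), class = "wormkin_validation_error")
})

test_that("as_rate_model packages a stepwise fit with LOO statistics", {
  tab <- sim_rate_dataset(n = 75, seed = 10)
  tab$log_kin <- log10(tab$kin_porewater)
  sw <- suppressWarnings(build_regression_stepwise(tab, "log_kin"))
  rm_ <- as_rate_model(sw, response = "kin", route = "porewater", table = tab)
  expect_s3_class(rm_, "rate_model")
  expect_true(rm_$stats$q2_loo <= rm_$stats$r_squared)
  expect_gt(predict(rm_, tab[1, ]), 0)
})
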