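test_that("rate predictions are deterministic and match hand evaluation", {
  m <- wormkin_models()
  k1 <- predict_uptake_rate("porewater", 3, 10, 2, quiet = TRUE)
  k2 <- predict_uptake_rate("porewater", 3, 10, 2, quiet = TRUE)
  expect_identical(k1, k2)

  co <- m$kin_porewater$coefficients
  hand <- 10^(co[["intercept"]] + co[["log_kom"]] * 3 + co[["om"]] * 10 +
                co[["ssalipid"]] * 2)
  expect_equal(k1, hand, tolerance = 1e-12)

  # one calibration-table row, elimination model, hand-evaluated
  tab <- reference_calibration()[1, ]
  cos <- m$kout_soil$coefficients
  hand_out <- 10^(cos[["intercept"]] + cos[["tpsa"]] * tab$tpsa +
                    cos[["om"]] * tab$om + cos[["ssalipid"]] * tab$ssalipid)
  expect_equal(
    predict_elimination_rate("soil", tab$tpsa, tab$om, tab$ssalipid,
                             quiet = TRUE),
    hand_out, tolerance = 1e-12)
})

test_that("back-transformed rate predictions are strictly positive", {
  set.seed(11)
  for (i in 1:50) {
    lk <- runif(1, -2, 8); om <- runif(1, 0.1, 80)
    sl <- runif(1, 0.5, 6); tp <- runif(1, 0, 120)
    expect_gt(predict_uptake_rate("porewater", lk, om, sl, quiet = TRUE), 0)
    expect_gt(predict_uptake_rate("soil", lk, om, sl, quiet = TRUE), 0)
    expect_gt(predict_elimination_rate("porewater", tp, om, quiet = TRUE), 0)
    expect_gt(predict_elimination_rate("soil", tp, om, sl, quiet = TRUE), 0)
  }
})

test_that("porewater kout ignores earthworm traits; soil kout requires them", {
  a <- predict_elimination_rate("porewater", 25, 10, ssalipid = 1.1,
                                quiet = TRUE)
  b <- predict_elimination_rate("porewater", 25, 10, ssalipid = 3.8,
                                quiet = TRUE)
  expect_identical(a, b)
  expect_error(predict_elimination_rate("soil", 25, 10),
               class = "wormkin_validation_error")
})

test_that("in-domain predictions stay within the realistic rate ranges up to one RMSE", {
  m <- wormkin_models()
  d <- wormkin_domains()
  set.seed(42)
  n <- 1000
  tab <- tibble::tibble(
    log_kom = runif(n, d$log_kom[1], d$log_kom[2]),
    om = runif(n, d$om[1], d$om[2]),
    tpsa = runif(n, d$tpsa[1], d$tpsa[2]),
    ssa = runif(n, d$ssa[1], d$ssa[2]),
    lipid = runif(n, d$lipid[1], d$lipid[2]))
  tab$ssalipid <- tab$ssa * tab$lipid
  ranges <- list(kin_porewater = c(0.02, 4392), kin_soil = c(0.02, 2.30),
                 kout_porewater = c(0.02, 3.84), kout_soil = c(0.02, 4.40))
  for (nm in names(ranges)) {
    p <- predict(m[[nm]], tab)
    slack <- 10^m[[nm]]$stats$rmse
    expect_true(all(p >= ranges[[nm]][1] / slack & p <= ranges[[nm]][2] * slack),
                label = paste(nm, "within range"))
  }
})

test_that("predictions vary monotonically with the sign of each coefficient", {
  m <- wormkin_models()
  base <- list(log_kom = 3, om = 10, ssalipid = 2, tpsa = 25)
  for (nm in c("kin_porewater", "kin_soil", "kout_porewater", "kout_soil")) {
    mod <- m[[nm]]
    for (d in mod$descriptors) {
      lo <- base; hi <- base
      lo[[d]] <- base[[d]] * 0.8; hi[[d]] <- base[[d]] * 1.2
      delta <- predict(mod, tibble::as_tibble(hi)) -
        predict(mod, tibble::as_tibble(lo))
      expect_equal(sign(delta), sign(mod$coefficients[[d]]),
                   label = paste(nm, d))
    }
  }
})

test_that("stored model statistics reproduce under refit on the packaged calibration table", {
  tab <- reference_calibration()
  specs <- list(
    kin_porewater = c("log_kom", "om", "ssalipid"),
    kin_soil = c("log_kom", "om", "ssalipid"),
    kout_porewater = c("tpsa", "om"),
    kout_soil = c("tpsa", "om", "ssalipid"))
  for (nm in names(specs)) {
    tab$y <- log10(tab[[nm]])
    fit <- lm(stats::reformulate(specs[[nm]], "y"), data = tab)
    sm <- summary(fit)
    st <- wormkin_models()[[nm]]$stats
    expect_equal(sm$r.squared, st$r_squared, tolerance = 1e-6,
                 label = paste(nm, "R2"))
    expect_equal(sm$adj.r.squared, st$adj_r_squared, tolerance = 1e-6)
    expect_equal(sqrt(mean(residuals(fit)^2)), st$rmse, tolerance = 1e-6)
    loo <- loo_validate(tab, "y", specs[[nm]])
    expect_equal(loo$q2_loo, st$q2_loo, tolerance = 1e-6)
    expect_equal(loo$ccc_loo, st$ccc_loo, tolerance = 1e-6)
  }
})

test_that("packaged coefficients agree with an OLS refit within estimation error", {
  # two provenance paths: authored reference coefficients vs refit on the
  # synthetic calibration; they must agree within ~3 standard errors
  tab <- reference_calibration()
  tab$y <- log10(tab$kin_porewater)
  fit <- lm(y ~ log_kom + om + ssalipid, data = tab)
  sm <- summary(fit)$coefficients
  co <- wormkin_models()$kin_porewater$coefficients[
    c("intercept", "log_kom", "om", "ssalipid")]
  expect_true(all(abs(sm[, "Estimate"] - co) < 3 * sm[, "Std. Error"]))
})

test_that("rate models round-trip through JSON and the checksum guards the packaged file", {
  m <- wormkin_models()$kin_soil
  tmp <- tempfile(fileext = ".json")
  write_rate_models(list(kin_soil = m), tmp)
  back <- read_rate_models(tmp)$kin_soil
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$domain, m$domain)
  expect_equal(back$stats, m$stats, tolerance = 1e-12)
  expect_equal(back$response_transform, m$response_transform)

  # tampered copy with stale checksum must be refused
  src <- system.file("extdata", "reference_models_synthetic.json",
                     package = "wormkin")
  bad <- tempfile(fileext = ".json")
  txt <- readLines(src)
  writeLines(sub("-2.95", "-2.96", txt, fixed = TRUE), bad)
  file.copy(paste0(src, ".md5"), paste0(bad, ".md5"))
  expect_error(wormkin_models(bad), class = "wormkin_checksum_error")
})

test_that("tidy and glance expose coefficients and fit statistics", {
  m <- wormkin_models()$kout_porewater
  td <- tidy(m)
  expect_setequal(td$term, c("intercept", "tpsa", "om"))
  gl <- glance(m)
  expect_equal(gl$n, 75)
  expect_true(gl$r_squared > 0 && gl$r_squared <= 1)
})
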