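#' Fit uptake/elimination rate constants to a body-residue time series
#'
#' Least-squares fit of the one-compartment closed form (see
#' [body_residue_closed_form()]) to observed internal concentrations, with
#' the exposure described by `(c0, k0)` as in OECD-317-style first-order
#' fitting. Asymptotic standard errors are reported. A flat residue series
#' is non-identifiable and raises an error.
#'
#' @param body Data frame with columns `time` (d) and `value`
#'   (mg/kg wet weight); at least 4 points spanning the uptake phase.
#' @param c0,k0 Exposure parameters (from [fit_exposure_decay()] or known).
#' @param route `"porewater"` or `"soil"` (metadata only).
#' @return A `kinetics_fit` object with elements `kin`, `kout`, `se`,
#'   `route`, the underlying `nls` fit and the data; `tidy()`, `glance()`
#'   and `autoplot()` methods available.
#' @examples
#' tr <- body_residue_closed_form(10, 0.4, c0 = 0.5, k0 = 0.05,
#'                                times = c(1, 2, 4, 7, 14, 21))
#' fit_kinetics_to_timeseries(data.frame(time = tr$time,
#'                                       value = tr$c_earthworm),
#'                            c0 = 0.5, k0 = 0.05)
#' @export
fit_kinetics_to_timeseries <- function(body, c0, k0 = 0,
                                       route = c("porewater", "soil")) {
  route <- match.arg(route)
  body <- as.data.frame(body)
  if (!all(c("time", "value") %in% names(body)))
    abort_validation("body", "needs columns `time` and `value`")
  if (nrow(body) < 4) abort_validation("body", "needs >= 4 points")
  if (c0 <= 0) abort_validation("c0", "must be > 0 to identify kin")
  if (sd(body$value) < 1e-12 * max(abs(body$value), 1))
    abort("flat body-residue series: (kin, kout) not identifiable",
          class = "wormkin_fit_error")

  model_fun <- function(time, kin, kout) closed_form_cw(kin, kout, c0, k0, time)
  # multistart: kout spread over plausible elimination scales, kin matched
  # to the early-time slope Cw ~ kin*c0*t
  i1 <- which(body$time > 0)[1]
  kin0 <- max(body$value[i1] / (c0 * body$time[i1]), 1e-6)
  starts <- expand.grid(kin = kin0 * c(0.3, 1, 3),
                        kout = c(0.05, 0.2, 0.8, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ model_fun(time, kin, kout), data = body,
                        start = as.list(starts[i, ]),
                        lower = c(kin = 1e-12, kout = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    abort("kinetic fit failed from all starting values",
          class = "wormkin_fit_error")
  est <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 2), names(est)))
  structure(list(kin = est[["kin"]], kout = est[["kout"]], se = se,
                 route = route, c0 = c0, k0 = k0, fit = best$fit,
                 data = tibble::as_tibble(body)),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s route: kin = %.4g, kout = %.4g 1/d, BCF = %.4g\n",
              x$route, x$kin, x$kout, x$kin / x$kout))
  invisible(x)
}

#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble::tibble(term = c("kin", "kout"),
                 estimate = c(x$kin, x$kout),
                 std_error = unname(x$se[c("kin", "kout")]))
}

#' @export
glance.kinetics_fit <- function(x, ...) {
  r <- residuals(x$fit)
  tibble::tibble(n = nrow(x$data), rmse = sqrt(mean(r^2)),
                 bcf = x$kin / x$kout, route = x$route)
}

#' Collinearity screening of candidate descriptors
#'
#' Pearson bivariate correlations are computed for every descriptor pair
#' within a category (chemical, soil, earthworm); pairs significant at
#' `alpha` are linked and groups are the transitive closure of those links.
#' Only one representative per group may enter a regression (the one giving
#' the best single-descriptor fit, see [build_regression_stepwise()]),
#' keeping the variance inflation factor below 2.
#'
#' @param table Data frame containing the descriptor columns.
#' @param alpha Significance level for linking (default 0.01).
#' @param categories Named list mapping category -> descriptor names;
#'   defaults to the standard chemical / soil / earthworm partition of the
#'   columns present in `table`.
#' @return A `descriptor_groups` tibble: `descriptor`, `category`, `group`
#'   (integer id within the whole table).
#' @examples
#' tab <- sim_descriptor_table(n = 75, seed = 1)
#' screen_descriptors(tab)
#' @export
screen_descriptors <- function(table, alpha = 0.01, categories = NULL) {
  if (is.null(categories)) {
    std <- list(
      chemical = c("log_kow", "log_kom", "log_kd", "tpsa"),
      soil = c("om", "clay", "cec", "ph"),
      earthworm = c("lipid", "ssa", "ssalipid"))
    categories <- purrr::map(std, intersect, y = names(table))
    categories <- categories[lengths(categories) > 0]
  }
  all_desc <- unlist(categories, use.names = FALSE)
  for (d in all_desc) {
    x <- table[[d]]
    if (is.null(x)) abort_validation(d, "descriptor column missing")
    if (length(x) < 3) abort_validation(d, "needs >= 3 observations")
    if (sd(x) == 0) abort_validation(d, "constant descriptor column")
  }
  out <- purrr::imap(categories, function(desc, cat) {
    k <- length(desc)
    adj <- diag(k) > 0
    if (k > 1) {
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        p <- cor.test(table[[desc[i]]], table[[desc[j]]])$p.value
        adj[i, j] <- adj[j, i] <- p < alpha
      }
    }
    comp <- transitive_components(adj)
    tibble::tibble(descriptor = desc, category = cat, group_local = comp)
  })
  out <- dplyr::bind_rows(out)
  out$group <- as.integer(factor(paste(out$category, out$group_local)))
  out$group_local <- NULL
  class(out) <- c("descriptor_groups", class(out))
  out
}

# connected components of a symmetric logical adjacency matrix
transitive_components <- function(adj) {
  k <- nrow(adj)
  comp <- rep(NA_integer_, k)
  next_id <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    next_id <- next_id + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- next_id
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# variance inflation factors from the predictor correlation matrix
vif_values <- function(X) {
  if (ncol(X) < 2) return(setNames(rep(1, ncol(X)), colnames(X)))
  setNames(diag(solve(cor(X))), colnames(X))
}

#' Stepwise multiple linear regression with collinearity control
#'
#' Reproduces the classical QSAR model-building recipe: (1) within each
#' intercorrelated descriptor group, keep the representative giving the
#' highest R-squared of the resultant regression - found by coordinate
#' ascent on the multiple regression over one member per group, starting
#' from the best single-descriptor members; (2) forward selection with
#' p-value entry threshold `alpha_enter` and backward removal at
#' `alpha_remove`; (3) a candidate whose entry would push any variance
#' inflation factor to `max_vif` or above is barred. The final model is
#' refit by OLS and reported with R-squared, adjusted R-squared and RMSE
#' (`sqrt(RSS/n)`).
#'
#' @param table Data frame with the response and descriptor columns.
#' @param response Response column name (fit on the scale given; take
#'   `log10()` upstream for rate constants).
#' @param groups A `descriptor_groups` tibble from [screen_descriptors()]
#'   (computed from `table` if `NULL`).
#' @param alpha_enter,alpha_remove Entry / removal p-value thresholds
#'   (defaults 0.05 / 0.10).
#' @param max_vif Collinearity bound (exclusive), default 2.
#' @return A `stepwise_result`: list with `model` (the final `lm`),
#'   `selected`, `representatives`, `groups`, `trace` (entry/removal log
#'   with p-values and R-squared change) and `stats`
#'   (`n`, `r_squared`, `adj_r_squared`, `rmse`). If nothing reaches entry
#'   significance an intercept-only model is returned with a warning.
#' @examples
#' tab <- sim_rate_dataset(n = 75, seed = 7)
#' tab$y <- log10(tab$kin_porewater)
#' build_regression_stepwise(tab, "y")
#' @export
build_regression_stepwise <- function(table, response, groups = NULL,
                                      alpha_enter = 0.05, alpha_remove = 0.10,
                                      max_vif = 2) {
  table <- as.data.frame(table)
  if (is.null(table[[response]])) abort_validation(response, "response column missing")
  if (is.null(groups)) {
    groups <- screen_descriptors(
      table[, setdiff(names(table), response), drop = FALSE])
  }
  y <- table[[response]]

  # one representative per group, chosen by the R^2 of the resultant
  # multiple regression: start from the best single-descriptor member of
  # each group, then coordinate-ascend swapping one group's member at a
  # time until no swap improves the joint R^2
  members <- split(groups$descriptor, groups$group)
  r2_joint <- function(vars)
    summary(lm(stats::reformulate(vars, response), data = table))$r.squared
  reps <- vapply(members, function(ms) {
    r2 <- vapply(ms, function(d)
      summary(lm(y ~ table[[d]]))$r.squared, numeric(1))
    ms[which.max(r2)]
  }, character(1))
  if (length(members) > 1) {
    repeat {
      improved <- FALSE
      for (g in seq_along(members)) {
        cur <- r2_joint(reps)
        trial_r2 <- vapply(members[[g]], function(d) {
          r <- reps; r[g] <- d; r2_joint(r)
        }, numeric(1))
        best <- which.max(trial_r2)
        if (trial_r2[best] > cur + 1e-12 && members[[g]][best] != reps[g]) {
          reps[g] <- members[[g]][best]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  reps <- unname(reps)

  selected <- character(0)
  trace <- list()
  r2_of <- function(vars) {
    if (length(vars) == 0) return(0)
    summary(lm(stats::reformulate(vars, response), data = table))$r.squared
  }
  coef_p <- function(vars) {
    sm <- summary(lm(stats::reformulate(vars, response), data = table))
    sm$coefficients[-1, "Pr(>|t|)", drop = TRUE]
  }
  repeat {
    changed <- FALSE
    # forward step: most significant admissible candidate
    cands <- setdiff(reps, selected)
    if (length(cands) > 0) {
      pvals <- vapply(cands, function(d) {
        trial <- c(selected, d)
        if (length(trial) > 1 &&
            max(vif_values(as.matrix(table[, trial]))) >= max_vif)
          return(NA_real_)
        unname(coef_p(trial)[length(trial)])
      }, numeric(1))
      ok <- which(!is.na(pvals) & pvals < alpha_enter)
      if (length(ok) > 0) {
        pick <- cands[ok[which.min(pvals[ok])]]
        r2_before <- r2_of(selected)
        selected <- c(selected, pick)
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = length(trace) + 1L, action = "enter", descriptor = pick,
          p_value = min(pvals[ok], na.rm = TRUE),
          r_squared = r2_of(selected),
          delta_r_squared = r2_of(selected) - r2_before)
        changed <- TRUE
      }
    }
    # backward step: least significant retained descriptor above removal
    if (length(selected) > 0) {
      p <- coef_p(selected)
      worst <- which.max(p)
      if (p[worst] > alpha_remove) {
        drop_var <- selected[worst]
        r2_before <- r2_of(selected)
        selected <- setdiff(selected, drop_var)
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = length(trace) + 1L, action = "remove", descriptor = drop_var,
          p_value = unname(p[worst]), r_squared = r2_of(selected),
          delta_r_squared = r2_of(selected) - r2_before)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(selected) == 0) {
    warn("no descriptor reached entry significance; returning intercept-only model",
         class = "wormkin_stepwise_warning")
    model <- lm(stats::reformulate("1", response), data = table)
  } else {
    model <- lm(stats::reformulate(selected, response), data = table)
  }
  sm <- summary(model)
  n <- nrow(table)
  res <- structure(
    list(model = model, selected = selected, representatives = reps,
         groups = groups,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble::tibble(step = integer(), action = character(),
                          descriptor = character(), p_value = numeric(),
                          r_squared = numeric(), delta_r_squared = numeric()),
         stats = list(n = n, r_squared = sm$r.squared,
                      adj_r_squared = sm$adj.r.squared,
                      rmse = sqrt(mean(residuals(model)^2))),
         response = response),
    class = "stepwise_result")
  res
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %s ~ %s\n", x$response,
              if (length(x$selected)) paste(x$selected, collapse = " + ") else "1"))
  cat(sprintf("  n = %d, R2 = %.3f, adj R2 = %.3f, RMSE = %.3f\n",
              x$stats$n, x$stats$r_squared, x$stats$adj_r_squared,
              x$stats$rmse))
  invisible(x)
}

#' @export
tidy.stepwise_result <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                 std_error = sm[, "Std. Error"],
                 statistic = sm[, "t value"], p_value = sm[, "Pr(>|t|)"])
}

#' @export
glance.stepwise_result <- function(x, ...) {
  tibble::as_tibble(x$stats)
}

#' Convert a stepwise fit into a portable `rate_model`
#'
#' @param x A `stepwise_result` whose response was fit on log10 scale.
#' @param response,route Labels for the resulting [rate_model()].
#' @param domain Applicability ranges; defaults to the observed min/max of
#'   each selected descriptor in the training data.
#' @param table The training table (for default domains and LOO validation).
#' @return A [rate_model()] including LOO `q2_loo` and `ccc_loo` statistics.
#' @export
as_rate_model <- function(x, response, route, table, domain = NULL) {
  stopifnot(inherits(x, "stepwise_result"))
  co <- coef(x$model)
  names(co)[1] <- "intercept"
  if (is.null(domain)) {
    domain <- purrr::map(x$selected,
                         ~ range(table[[.x]])) |> setNames(x$selected)
  }
  loo <- loo_validate(table, x$response, x$selected)
  rate_model(response = response, route = route, coefficients = co,
             response_transform = "log10",
             stats = c(x$stats, list(q2_loo = loo$q2_loo, ccc_loo = loo$ccc_loo)),
             domain = domain, provenance = "refit")
}

#' Leave-one-out cross-validation of a fixed linear model
#'
#' Refits the OLS model `response ~ descriptors` n times leaving one
#' observation out, then reports `Q2 = 1 - PRESS / SS_tot` (SS_tot about the
#' full-sample mean) and Lin's concordance correlation ([lin_ccc()]) between
#' the observed values and the LOO predictions.
#'
#' @param table Training data frame.
#' @param response Response column name.
#' @param descriptors Character vector of descriptor columns (fixed set; no
#'   re-selection inside the folds).
#' @return List with `q2_loo`, `ccc_loo`, `press` and a `predictions` tibble
#'   (`observed`, `predicted_loo`, `fold`).
#' @examples
#' tab <- sim_rate_dataset(n = 30, seed = 2)
#' tab$y <- log10(tab$kin_porewater)
#' loo_validate(tab, "y", c("log_kom", "om", "ssalipid"))
#' @export
loo_validate <- function(table, response, descriptors) {
  table <- as.data.frame(table)
  n <- nrow(table)
  if (n <= length(descriptors) + 2)
    abort_validation("table", "too few observations for LOO validation")
  form <- stats::reformulate(descriptors, response)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(form, data = table[-i, , drop = FALSE])
    if (anyNA(coef(fit)))
      abort(sprintf("singular refit leaving out observation %d", i),
            class = "wormkin_fit_error")
    pred[i] <- predict(fit, newdata = table[i, , drop = FALSE])
  }
  obs <- table[[response]]
  press <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(q2_loo = 1 - press / ss_tot,
       ccc_loo = lin_ccc(obs, pred),
       press = press,
       predictions = tibble::tibble(observed = obs, predicted_loo = pred,
                                    fold = seq_len(n)))
}

#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((o - p)^2) / sum((o - mean(o))^2)`. Equals 1 for a perfect
#' model, 0 for a model no better than the observed mean, and is negative
#' below that benchmark.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2);
#'   `observed` must not be constant.
#' @return Dimensionless efficiency, at most 1.
#' @examples
#' nse(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
nse <- function(observed, predicted) {
  check_paired(observed, predicted)
  ss <- sum((observed - mean(observed))^2)
  if (ss == 0) abort_validation("observed", "zero variance")
  1 - sum((observed - predicted)^2) / ss
}

#' Percentage of predictions within a factor of the observations
#'
#' `100 * mean(pmax(p/o, o/p) <= factor)`; a ratio exactly equal to the
#' factor counts as within (closed bound). Symmetric in observed/predicted
#' and non-decreasing in `factor`.
#'
#' @param observed,predicted Strictly positive numeric vectors.
#' @param factor Fold-difference threshold(s), >= 1; vectorized.
#' @return Percent (0-100), one value per factor.
#' @examples
#' pct_within_factor(c(1, 1), c(4, 20), factor = c(3, 5, 10, 25))
#' @export
pct_within_factor <- function(observed, predicted, factor = c(3, 5, 10)) {
  check_paired(observed, predicted, min_n = 1)
  if (any(observed <= 0) || any(predicted <= 0))
    abort_validation("observed", "factor comparison needs strictly positive values")
  if (any(factor < 1)) abort_validation("factor", "must be >= 1")
  ratio <- pmax(predicted / observed, observed / predicted)
  vapply(factor, function(f) 100 * mean(ratio <= f), numeric(1))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurements with the 1:1 line:
#' `2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments.
#'
#' @param x,y Numeric vectors of equal length (n >= 2), each with nonzero
#'   variance.
#' @return CCC in `[-1, 1]`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4)) # 4/7
#' @export
lin_ccc <- function(x, y) {
  check_paired(x, y)
  n <- length(x)
  vx <- var(x) * (n - 1) / n
  vy <- var(y) * (n - 1) / n
  if (vx == 0 || vy == 0) abort_validation("x", "zero variance")
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

check_paired <- function(a, b, min_n = 2) {
  if (length(a) != length(b))
    abort_validation("predicted", "lengths differ")
  if (length(a) < min_n)
    abort_validation("observed", sprintf("needs >= %d points", min_n))
  if (anyNA(a) || anyNA(b))
    abort_validation("observed", "missing values not allowed")
  invisible(TRUE)
}
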