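test_that("Kaplan-Meier matches the hand product-limit calculation", {
  S <- km_curve(toy_surv())
  expect_equal(step_eval(S, c(0.5, 1.9)), c(1, 1))
  expect_equal(step_eval(S, 2), 0.5)  # risk set of 2 at t = 2
  expect_warning(S0 <- km_curve(tibble::tibble(time = 1:3, status = rep(0, 3))), "no events")
  expect_equal(step_eval(S0, c(1, 5)), c(1, 1))
  Sf <- km_curve(tibble::tibble(time = c(1, 2, 3), status = c(1, 1, 1)))
  expect_equal(step_eval(Sf, 3), 0)
  expect_error(km_curve(tibble::tibble(time = numeric(0), status = numeric(0))), "empty")
})

test_that("Nelson-Aalen matches the hand increment sum", {
  H <- na_curve(tibble::tibble(time = c(1, 2, 3), status = c(1, 0, 1)))
  expect_equal(step_eval(H, 1), 1 / 3)
  expect_equal(step_eval(H, 3), 1 / 3 + 1)
  expect_equal(step_eval(na_curve(tibble::tibble(time = 5, status = 1)), 5), 1)
  expect_warning(H0 <- na_curve(tibble::tibble(time = 1:3, status = rep(0, 3))), "no events")
  expect_equal(step_eval(H0, 10), 0)
})

test_that("KM and Nelson-Aalen agree with survfit and satisfy S_KM <= exp(-H_NA)", {
  set.seed(42)
  for (i in 1:5) {
    d <- tibble::tibble(time = rexp(80), status = rbinom(80, 1, 0.6))
    if (!any(d$status == 1)) next
    S <- km_curve(d); H <- na_curve(d)
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
    keep <- sf$n.event > 0
    expect_equal(S$knots, sf$time[keep])
    expect_equal(S$values, sf$surv[keep], tolerance = 1e-12)
    expect_equal(H$values, sf$cumhaz[keep], tolerance = 1e-12)
    expect_true(all(step_eval(S, S$knots) <= exp(-step_eval(H, S$knots)) + 1e-12))
  }
})

test_that("fit_ph maximizes the written-out Breslow partial likelihood", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0), x = c(1, 0, 1, 0))
  fit <- fit_ph(d, covariates = "x")
  bgrid <- stats::optimize(function(b) breslow_loglik(b, d$time, d$status, d$x),
                           c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(fit$coefficients), bgrid, tolerance = 1e-4)
  # duplicating every row leaves the estimate unchanged under Breslow ties
  fit2 <- fit_ph(d[rep(1:4, 2), ], covariates = "x")
  expect_equal(unname(fit2$coefficients), unname(fit$coefficients), tolerance = 1e-7)
})

test_that("null-model Breslow baseline equals Nelson-Aalen exactly", {
  set.seed(7)
  d <- tibble::tibble(time = rexp(100), status = rbinom(100, 1, 0.7))
  fit <- fit_ph(d)
  H <- na_curve(d)
  expect_identical(fit$baseline$knots, H$knots)
  expect_equal(fit$baseline$values, H$values, tolerance = 1e-14)
})

test_that("fit_ph rejects collinear or incomplete covariates", {
  d <- tibble::tibble(time = rexp(30), status = rbinom(30, 1, 0.7), x = rnorm(30))
  d$y <- 2 * d$x
  expect_error(fit_ph(d, c("x", "y")), "collinear")
  d$x[1] <- NA
  expect_error(fit_ph(d, "x"), "complete")
})

test_that("parameter draws are centred at the estimate with nondecreasing baselines", {
  set.seed(11)
  d <- tibble::tibble(time = rexp(300), status = rbinom(300, 1, 0.7),
                      x = rbinom(300, 1, 0.5))
  fit <- fit_ph(d, "x")
  frozen <- fit
  frozen$vcov <- matrix(0, 1, 1)
  expect_equal(draw_ph_parameters(frozen)$coefficients, fit$coefficients)
  draws <- replicate(2000, {
    dr <- draw_ph_parameters(fit)
    expect_false(is.unsorted(dr$baseline$values))
    unname(dr$coefficients)
  })
  se_mc <- sqrt(fit$vcov[1, 1] / 2000)
  expect_lt(abs(mean(draws) - unname(fit$coefficients)), 3 * se_mc)
})

test_that("model-based cumulative incidence follows the closed form", {
  set.seed(3)
  d <- tibble::tibble(time = rexp(200), status = rbinom(200, 1, 0.8),
                      x = rnorm(200))
  fit <- fit_ph(d, "x")
  expect_equal(cif_from_ph(fit, c(x = 0.3), 0.5 * min(fit$baseline$knots))$cif, 0)
  # null coefficients: baseline identity
  fit0 <- fit_ph(d)
  ts <- c(0.2, 0.8, 1.5)
  expect_equal(cif_from_ph(fit0, tibble::tibble(), ts)$cif,
               1 - exp(-step_eval(fit0$baseline, ts)))
  # monotone in the linear predictor wherever the baseline is positive
  lo <- cif_from_ph(fit, c(x = 0), ts)$cif
  hi <- cif_from_ph(fit, c(x = 2 / unname(fit$coefficients)), ts)$cif
  expect_true(all(hi > lo))
  expect_error(cif_from_ph(fit, c(notx = 1), ts), "covariate")
})

test_that("cumulative incidence is invariant to a consistent covariate shift", {
  set.seed(13)
  d <- tibble::tibble(time = rexp(300), status = rbinom(300, 1, 0.7), x = rnorm(300))
  d2 <- d; d2$x <- d$x + 5
  f1 <- fit_ph(d, "x"); f2 <- fit_ph(d2, "x")
  ts <- c(0.3, 1, 2)
  expect_equal(cif_from_ph(f1, c(x = 0.7), ts)$cif,
               cif_from_ph(f2, c(x = 5.7), ts)$cif, tolerance = 1e-6)
})

test_that("cif_variance is zero without parameter noise and before the first event", {
  fit <- manual_ph(beta = 0.5, jump = 0.4)
  v <- cif_variance(fit, c(X = 1), c(0.5, 1))
  expect_equal(v$var[1], 0)   # baseline still zero
  expect_true(all(v$var >= 0))
  set.seed(2)
  d <- tibble::tibble(time = rexp(100), status = rbinom(100, 1, 0.8), x = rnorm(100))
  f <- fit_ph(d, "x")
  expect_equal(cif_variance(f, c(x = 0), min(f$baseline$knots) / 2)$var, 0)
  expect_warning(cif_variance(f, c(x = 0), max(d$time) + 1), "carrying")
})

test_that("cloglog Wald intervals for the cumulative incidence attain nominal coverage", {
  set.seed(1234)
  params <- fg_correct_params(p = 0.65)
  truth <- true_cif(params, 0, 0, 1)
  hit <- logical(300)
  for (r in seq_along(hit)) {
    d <- gen_fg_correct(2000, params)
    cc <- make_subdist_time(d, "no_censoring")
    fit <- fit_ph(cc, c("X", "Z"), time = "V", status = "ev1")
    v <- cif_variance(fit, c(X = 0, Z = 0), 1)
    theta <- log(-log(1 - v$cif))
    ci <- 1 - exp(-exp(theta + c(-1, 1) * 1.959964 * sqrt(v$var_cloglog)))
    hit[r] <- min(ci) <= truth && truth <= max(ci)
  }
  expect_gt(mean(hit), 0.91)
  expect_lt(mean(hit), 0.985)
})
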