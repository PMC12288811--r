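#' Parameters of the proportional-subdistribution-hazards generator
#'
#' The cumulative incidence of the event of interest is specified directly as
#' F1(t | X, Z) = 1 - \[1 - p\{1 - exp(-b1 t^a1)\}\]^exp(beta1 X + beta2 Z),
#' a Fine-Gray model whose baseline cumulative incidence is a Weibull
#' distribution function (shape `a1`, rate `b1`; F(t) = 1 - exp(-b t^a))
#' scaled by `p`, the probability of the event of interest at time infinity
#' for a subject with X = Z = 0. Conditional on failing from the competing
#' event, times follow a proportional-hazards model with Weibull baseline
#' (shape `a2`, rate `b2`) and coefficients `beta1_star`, `beta2_star`.
#'
#' @param p Baseline cumulative incidence of the event of interest at
#'   infinity, in (0, 1).
#' @param beta1,beta2 Subdistribution log hazard ratios for X and Z.
#' @param a1,b1 Weibull shape and rate of the baseline cumulative incidence.
#' @param beta1_star,beta2_star Log hazard ratios of the conditional model
#'   for competing-event times.
#' @param a2,b2 Weibull shape and rate of the conditional competing-event
#'   baseline.
#' @return A list of class `fg_correct_params`.
#' @export
fg_correct_params <- function(p = 0.15, beta1 = 0.75, beta2 = 0.5,
                              a1 = 0.75, b1 = 1,
                              beta1_star = 0.75, beta2_star = 0.5,
                              a2 = 0.75, b2 = 1) {
  if (p <= 0 || p >= 1) stop_fgmi("p must be in (0, 1)")
  if (min(a1, b1, a2, b2) <= 0) stop_fgmi("Weibull shapes and rates must be positive")
  structure(list(p = p, beta1 = beta1, beta2 = beta2, a1 = a1, b1 = b1,
                 beta1_star = beta1_star, beta2_star = beta2_star, a2 = a2, b2 = b2),
            class = "fg_correct_params")
}

#' Parameters of the proportional-cause-specific-hazards generator
#'
#' Both cause-specific hazards are Weibull proportional hazards:
#' hk(t | X, Z) = ak bk t^(ak - 1) exp(gk1 X + gk2 Z). Under this mechanism
#' a proportional-subdistribution-hazards model for cause 1 is misspecified.
#'
#' @param a1,b1,g11,g12 Cause-1 shape, rate and log hazard ratios.
#' @param a2,b2,g21,g22 Cause-2 analogues.
#' @return A list of class `cs_hazard_params`.
#' @export
cs_hazard_params <- function(a1, b1, g11, g12, a2, b2, g21, g22) {
  if (min(a1, b1, a2, b2) <= 0) stop_fgmi("Weibull shapes and rates must be positive")
  structure(list(a1 = a1, b1 = b1, g11 = g11, g12 = g12,
                 a2 = a2, b2 = b2, g21 = g21, g22 = g22),
            class = "cs_hazard_params")
}

#' Generate baseline covariates
#'
#' Z ~ N(0, 1) and X | Z ~ Bernoulli(expit(Z)).
#'
#' @param n Number of subjects.
#' @return A tibble with columns `X`, `Z`.
#' @export
gen_covariates <- function(n) {
  Z <- rnorm(n)
  tibble::tibble(X = as.numeric(rbinom(n, 1, expit(Z))), Z = Z)
}

#' Generate competing-risks data with proportional subdistribution hazards
#'
#' Indirect simulation: the event indicator is drawn first,
#' D = 2 with probability (1 - p)^exp(beta1 X + beta2 Z), then event times
#' are drawn by inverse-transform sampling of the conditional distributions -
#' the closed-form inverse of the conditional cause-1 distribution, and a
#' Weibull proportional-hazards inverse for competing-event times.
#'
#' @param n Number of subjects.
#' @param params An [fg_correct_params()] object.
#' @param covariates Optional tibble with columns `X`, `Z` (generated if
#'   omitted).
#' @return A tibble with columns `time` (latent, uncensored), `status`
#'   (1 or 2), `X`, `Z`.
#' @export
gen_fg_correct <- function(n, params = fg_correct_params(), covariates = NULL) {
  stopifnot(inherits(params, "fg_correct_params"))
  cv <- covariates %||% gen_covariates(n)
  eta <- params$beta1 * cv$X + params$beta2 * cv$Z
  p2 <- (1 - params$p)^exp(eta)
  if (any(p2 <= 0 | p2 >= 1)) stop_fgmi("P(D = 1 | X, Z) outside (0, 1) for some subjects")
  d <- 1 + rbinom(n, 1, p2)
  t <- numeric(n)
  i1 <- d == 1
  if (any(i1)) t[i1] <- fg_inverse_time(runif(sum(i1)), eta[i1], params)
  i2 <- d == 2
  if (any(i2)) {
    eta2 <- params$beta1_star * cv$X[i2] + params$beta2_star * cv$Z[i2]
    t[i2] <- (-log(1 - runif(sum(i2))) / (params$b2 * exp(eta2)))^(1 / params$a2)
  }
  tibble::tibble(time = t, status = d, X = cv$X, Z = cv$Z)
}

#' Inverse of the conditional cause-1 failure-time distribution
#'
#' Closed-form inverse of
#' P(T <= t | D = 1, X, Z) = \[1 - \{1 - p(1 - exp(-b1 t^a1))\}^exp(eta)\] /
#' \[1 - (1 - p)^exp(eta)\], used for inverse-transform sampling.
#'
#' @param u Uniform(0, 1) draws.
#' @param eta Linear predictor values beta1 X + beta2 Z.
#' @param params An [fg_correct_params()] object.
#' @return Failure times (0 at u = 0).
#' @export
fg_inverse_time <- function(u, eta, params) {
  ee <- exp(eta)
  inner <- (1 - u * (1 - (1 - params$p)^ee))^(1 / ee)
  (-log(1 - (1 - inner) / params$p) / params$b1)^(1 / params$a1)
}

#' Generate competing-risks data with proportional cause-specific hazards
#'
#' Latent-failure-time simulation: one Weibull proportional-hazards time per
#' cause by inverse transform; the observed event is the earlier one.
#'
#' @param n Number of subjects.
#' @param params A [cs_hazard_params()] object.
#' @param covariates Optional tibble with `X`, `Z`.
#' @return A tibble with `time`, `status` (1 or 2), `X`, `Z`.
#' @export
gen_cs_hazards <- function(n, params, covariates = NULL) {
  stopifnot(inherits(params, "cs_hazard_params"))
  cv <- covariates %||% gen_covariates(n)
  t1 <- (-log(1 - runif(n)) / (params$b1 * exp(params$g11 * cv$X + params$g12 * cv$Z)))^(1 / params$a1)
  t2 <- (-log(1 - runif(n)) / (params$b2 * exp(params$g21 * cv$X + params$g22 * cv$Z)))^(1 / params$a2)
  tibble::tibble(time = pmin(t1, t2), status = ifelse(t1 <= t2, 1, 2),
                 X = cv$X, Z = cv$Z)
}

#' Censoring specification
#'
#' @param kind `"none"`, `"administrative"` (exponential draws, retained as
#'   known potential censoring times for everyone), `"random"` (same draws,
#'   unknown beyond the observed minimum) or `"covariate_dependent"`
#'   (exponential with rate `rate * exp(z_coef * Z)`).
#' @param rate Exponential censoring rate.
#' @param z_coef Log-linear effect of Z on the censoring rate
#'   (`"covariate_dependent"` only).
#' @return A list of class `censoring_spec`.
#' @export
censoring_spec <- function(kind = c("none", "administrative", "random", "covariate_dependent"),
                           rate = 0.49, z_coef = 1) {
  kind <- match.arg(kind)
  if (kind != "none" && rate <= 0) stop_fgmi("censoring rate must be positive")
  structure(list(kind = kind, rate = rate, z_coef = z_coef,
                 known = kind == "administrative"), class = "censoring_spec")
}

#' Apply right-censoring to generated event times
#'
#' Draws censoring times, truncates follow-up and zeroes the event indicator
#' for censored subjects. With administrative censoring the potential
#' censoring time is retained in column `C` for all subjects.
#'
#' @param data Output of a generator (columns `time`, `status`, `Z`).
#' @param spec A [censoring_spec()].
#' @return A tibble with censored `time`, `status` in 0/1/2, and `C` when
#'   censoring times are known.
#' @export
apply_censoring <- function(data, spec = censoring_spec("random")) {
  stopifnot(inherits(spec, "censoring_spec"))
  out <- tibble::as_tibble(data)
  if (spec$kind == "none") return(out)
  n <- nrow(out)
  rate <- if (spec$kind == "covariate_dependent") spec$rate * exp(spec$z_coef * out$Z) else rep(spec$rate, n)
  C <- rexp(n, rate)
  cens <- C < out$time
  out$status[cens] <- 0
  out$time <- pmin(out$time, C)
  if (spec$known) out$C <- C
  out
}

#' Missingness specification
#'
#' Missing-at-random mechanisms for the partially observed covariate:
#' `"mar_z"` has logit P(missing | Z) = eta0 + eta1 Z (default slope 1.5);
#' `"mar_t"` has logit P(missing | T) = eta0 + eta1 log(T + 1) (default slope
#' -1.5, outcome-dependent). The intercept is calibrated by
#' [calibrate_missingness()] so the average missingness equals
#' `target_rate`.
#'
#' @param mechanism `"mar_z"` or `"mar_t"`.
#' @param eta1 Slope.
#' @param target_rate Average missingness probability.
#' @param eta0 Optional pre-solved intercept.
#' @return A list of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("mar_z", "mar_t"),
                             eta1 = NULL, target_rate = 0.4, eta0 = NULL) {
  mechanism <- match.arg(mechanism)
  if (target_rate <= 0 || target_rate >= 1) stop_fgmi("target_rate must be in (0, 1)")
  eta1 <- eta1 %||% if (mechanism == "mar_z") 1.5 else -1.5
  structure(list(mechanism = mechanism, eta1 = eta1, target_rate = target_rate,
                 eta0 = eta0), class = "missingness_spec")
}

#' Calibrate the missingness intercept
#'
#' Root-solves eta0 such that E\{expit(eta0 + eta1 W)\} equals the target
#' rate, where W = Z ~ N(0, 1) (expectation by adaptive quadrature against
#' the normal density - no randomness) or W = log(T + 1) (empirical average
#' over a supplied reference sample).
#'
#' @param spec A [missingness_spec()].
#' @param data Reference sample with column `time` (required for
#'   `"mar_t"`).
#' @param tol Root tolerance.
#' @return The spec with `eta0` filled in.
#' @export
calibrate_missingness <- function(spec, data = NULL, tol = 1e-8) {
  stopifnot(inherits(spec, "missingness_spec"))
  if (spec$eta1 == 0) {
    spec$eta0 <- qlogis(spec$target_rate)
    return(spec)
  }
  mean_p <- if (spec$mechanism == "mar_z") {
    function(e0) integrate(function(z) expit(e0 + spec$eta1 * z) * dnorm(z),
                           -Inf, Inf, rel.tol = 1e-10)$value
  } else {
    if (is.null(data)) stop_fgmi("mar_t calibration requires a reference sample with a `time` column")
    w <- log(data$time + 1)
    function(e0) mean(expit(e0 + spec$eta1 * w))
  }
  f <- function(e0) mean_p(e0) - spec$target_rate
  lo <- -20; hi <- 20
  while (f(lo) > 0 && lo > -200) lo <- lo * 2
  while (f(hi) < 0 && hi < 200) hi <- hi * 2
  if (f(lo) > 0 || f(hi) < 0) stop_fgmi("could not bracket the missingness intercept")
  spec$eta0 <- uniroot(f, c(lo, hi), tol = tol)$root
  spec
}

#' Induce missingness in the partially observed covariate
#'
#' Blanks X where a logistic missingness model (in Z, or in log(T + 1))
#' fires. Calibrates the intercept first if not yet solved.
#'
#' @param data A data frame with columns `X`, `Z`, `time`.
#' @param spec A [missingness_spec()].
#' @param target Column to blank.
#' @return The data with `NA` in the blanked cells.
#' @export
induce_missingness <- function(data, spec = missingness_spec("mar_z"), target = "X") {
  stopifnot(inherits(spec, "missingness_spec"))
  if (is.null(spec$eta0)) spec <- calibrate_missingness(spec, data)
  w <- if (spec$mechanism == "mar_z") data$Z else log(data$time + 1)
  out <- tibble::as_tibble(data)
  miss <- runif(nrow(out)) < expit(spec$eta0 + spec$eta1 * w)
  out[[target]][miss] <- NA
  out
}

#' True cumulative incidence of the event of interest
#'
#' Closed form under the proportional-subdistribution-hazards mechanism; for
#' the cause-specific mechanism the integral of h1(u|x,z) S(u|x,z) is
#' evaluated by adaptive quadrature.
#'
#' @param params [fg_correct_params()] or [cs_hazard_params()].
#' @param x,z Covariate values (scalars).
#' @param times Evaluation times.
#' @param abs_tol Quadrature absolute tolerance.
#' @return Vector of F1(t | x, z).
#' @export
true_cif <- function(params, x, z, times, abs_tol = 1e-8) {
  if (inherits(params, "fg_correct_params")) {
    F01 <- params$p * (1 - exp(-params$b1 * times^params$a1))
    return(1 - (1 - F01)^exp(params$beta1 * x + params$beta2 * z))
  }
  stopifnot(inherits(params, "cs_hazard_params"))
  e1 <- exp(params$g11 * x + params$g12 * z)
  e2 <- exp(params$g21 * x + params$g22 * z)
  f <- function(u) {
    params$a1 * params$b1 * u^(params$a1 - 1) * e1 *
      exp(-params$b1 * u^params$a1 * e1 - params$b2 * u^params$a2 * e2)
  }
  vapply(times, function(tt) {
    if (tt <= 0) return(0)
    integrate(f, 0, tt, abs.tol = abs_tol)$value
  }, numeric(1))
}

# Weibull proportional-hazards ML fit via the accelerated-failure-time
# parametrization of survreg: shape = 1/scale, rate = exp(-intercept*shape),
# hazard coefficients = -(AFT coefficients)*shape. Exact reparametrization.
fit_weibull_ph <- function(time, status, X) {
  sr <- survival::survreg(survival::Surv(time, status) ~ X, dist = "weibull")
  if (is.na(sr$scale) || any(is.na(coef(sr)))) stop_fgmi("Weibull fit did not converge; consider restarting from a coarse parameter grid")
  shape <- 1 / sr$scale
  list(shape = shape,
       rate = exp(-coef(sr)[[1]] * shape),
       beta = -coef(sr)[-1] * shape)
}

#' Least-false cause-specific Weibull parameters
#'
#' Generates a large dataset under the proportional-subdistribution-hazards
#' mechanism and fits one parametric Weibull proportional-hazards model per
#' cause by maximum likelihood; the point estimates define the
#' cause-specific generator whose incidence curves closely track the original
#' mechanism while proportionality holds on the cause-specific scale.
#' Censoring is not applied by default (the matched mechanisms are defined
#' before any loss to follow-up); a censoring spec can be supplied to study
#' the alternative convention.
#'
#' @param fg_params An [fg_correct_params()] object.
#' @param n_large Size of the calibration dataset.
#' @param censoring Optional [censoring_spec()] applied before fitting.
#' @return A [cs_hazard_params()] object.
#' @export
derive_least_false_cs_params <- function(fg_params, n_large = 5e5, censoring = NULL) {
  d <- gen_fg_correct(n_large, fg_params)
  if (!is.null(censoring)) d <- apply_censoring(d, censoring)
  X <- as.matrix(d[c("X", "Z")])
  f1 <- fit_weibull_ph(d$time, as.numeric(d$status == 1), X)
  f2 <- fit_weibull_ph(d$time, as.numeric(d$status == 2), X)
  cs_hazard_params(a1 = f1$shape, b1 = f1$rate, g11 = f1$beta[[1]], g12 = f1$beta[[2]],
                   a2 = f2$shape, b2 = f2$rate, g21 = f2$beta[[1]], g22 = f2$beta[[2]])
}

#' Least-false subdistribution log hazard ratios
#'
#' The probability limit of the (misspecified) proportional-subdistribution-
#' hazards coefficients under a cause-specific-hazards mechanism: a large
#' dataset is generated, the requested censoring applied with censoring times
#' treated as known, subdistribution times constructed, and the model fitted
#' in its censoring-complete Cox representation.
#'
#' @param cs_params A [cs_hazard_params()] object.
#' @param censoring A [censoring_spec()] (`"none"` for the uncensored
#'   target; exponential kinds are treated as known here).
#' @param n_large Evaluation dataset size.
#' @return Named vector `c(X = , Z = )` of time-averaged log hazard ratios.
#' @export
true_least_false_beta <- function(cs_params, censoring = censoring_spec("none"),
                                  n_large = 5e5) {
  d <- gen_cs_hazards(n_large, cs_params)
  if (censoring$kind == "none") {
    cc <- make_subdist_time(d, "no_censoring")
  } else {
    spec <- censoring
    spec$known <- TRUE                 # censoring times treated as known here
    d <- apply_censoring(d, spec)
    cc <- make_subdist_time(d, "administrative", admin = "C")
  }
  fit <- fit_ph(cc, covariates = c("X", "Z"), time = "V", status = "ev1")
  setNames(unname(fit$coefficients), c("X", "Z"))
}
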