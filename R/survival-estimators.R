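#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of a survival function, returned as a
#' right-continuous [fg_stepfun] with knots at the distinct event times.
#' Depending on how `status` is coded this estimates event-free survival,
#' cause-specific "survival", or - with `status = 1 - I(D > 0)` - the
#' survival function G(t) of the censoring times, which is the estimate the
#' censoring-time imputation conditions on.
#'
#' @param data A data frame.
#' @param time,status Column names of the observation time (positive) and the
#'   binary event indicator.
#' @param weights Optional column name of positive case weights.
#' @return An [fg_stepfun] of type `"surv"`.
#' @export
km_curve <- function(data, time = "time", status = "status", weights = NULL) {
  s <- as_survival_sample(data, time, status, weights)
  if (!any(s$status == 1)) {
    warning("no events: survival curve is constant 1", call. = FALSE)
    return(fg_stepfun(numeric(0), numeric(0), v0 = 1, type = "surv"))
  }
  sf <- survival::survfit(survival::Surv(s$time, s$status) ~ 1,
                          weights = s$weights, se.fit = FALSE)
  keep <- sf$n.event > 0
  fg_stepfun(sf$time[keep], sf$surv[keep], v0 = 1, type = "surv")
}

#' Nelson-Aalen cumulative hazard
#'
#' H(t) = sum over event times tj <= t of dj / nj, with dj the (weighted)
#' number of events and nj the (weighted) number at risk at tj.
#'
#' @inheritParams km_curve
#' @return An [fg_stepfun] of type `"cumhaz"`.
#' @export
na_curve <- function(data, time = "time", status = "status", weights = NULL) {
  s <- as_survival_sample(data, time, status, weights)
  if (!any(s$status == 1)) {
    warning("no events: cumulative hazard is constant 0", call. = FALSE)
    return(fg_stepfun(numeric(0), numeric(0), v0 = 0, type = "cumhaz"))
  }
  bh <- breslow_increments(s$time, s$status, rep(1, length(s$time)), s$weights)
  fg_stepfun(bh$time, cumsum(bh$jump), v0 = 0, type = "cumhaz")
}

as_survival_sample <- function(data, time, status, weights = NULL) {
  assert_cols(data, c(time, status), "a survival estimator")
  t <- data[[time]]; d <- data[[status]]
  if (!length(t)) stop_fgmi("empty sample")
  if (any(!is.finite(t)) || any(t <= 0)) stop_fgmi("all times must be positive and finite")
  if (!all(d %in% c(0, 1))) stop_fgmi("status must be binary 0/1")
  w <- if (is.null(weights)) rep(1, length(t)) else data[[weights]]
  if (any(w <= 0)) stop_fgmi("weights must be positive")
  list(time = t, status = as.numeric(d), weights = w)
}

# Breslow / Nelson-Aalen increments: at each distinct event time tj,
# jump_j = sum of event weights at tj / sum of w * exp(lp) over the risk set
# {time >= tj}. With exp(lp) = 1 this is the Nelson-Aalen increment.
breslow_increments <- function(time, status, explp, weights = NULL) {
  w <- weights %||% rep(1, length(time))
  o <- order(time)
  t_s <- time[o]; d_s <- status[o]; r_s <- (w * explp)[o]; w_s <- w[o]
  risk <- rev(cumsum(rev(r_s)))
  ev <- d_s == 1
  if (!any(ev)) return(list(time = numeric(0), jump = numeric(0)))
  tj <- unique(t_s[ev])
  s0 <- risk[match(tj, t_s)]
  dj <- as.numeric(rowsum(w_s[ev], match(t_s[ev], tj))[, 1L])
  list(time = tj, jump = dj / s0)
}

#' Fit a proportional hazards model with Breslow baseline
#'
#' Thin wrapper around [survival::coxph()] with Breslow tie handling that
#' additionally stores the Breslow cumulative baseline hazard evaluated at
#' covariates exactly 0 (raw covariates, no internal centering) and the
#' fitting sample, so that the baseline can be recomputed at drawn
#' coefficients and used inside imputation densities. With an empty covariate
#' set the baseline reduces exactly to the Nelson-Aalen estimate.
#'
#' @param data A data frame with no missing values in the used columns.
#' @param covariates Character vector of covariate column names (possibly
#'   empty for a null model).
#' @param time,status Column names of the outcome.
#' @param weights Optional column name of case weights.
#' @return An object of class `fgmi_ph` with elements `coefficients`,
#'   `vcov`, `baseline` (an [fg_stepfun]), `covariate_names`, `n_events`.
#' @export
fit_ph <- function(data, covariates = character(), time = "time", status = "status",
                   weights = NULL) {
  s <- as_survival_sample(data, time, status, weights)
  p <- length(covariates)
  if (p) {
    assert_cols(data, covariates, "fit_ph")
    X <- as.matrix(data[covariates])
    storage.mode(X) <- "double"
    if (anyNA(X)) stop_fgmi("fit_ph requires complete covariates")
    if (qr(cbind(X))$rank < p) stop_fgmi("collinear covariates in fit_ph")
    # coxph.fit is the engine behind survival::coxph; calling it directly
    # skips formula/model-frame overhead, which matters inside imputation
    # chains that refit the model at every iteration
    fit <- survival::coxph.fit(X, survival::Surv(s$time, s$status),
                               strata = NULL, offset = NULL, init = NULL,
                               control = survival::coxph.control(),
                               weights = s$weights, method = "breslow",
                               rownames = NULL)
    beta <- unname(fit$coefficients)
    if (anyNA(beta) || any(abs(beta) > 20)) {
      stop_fgmi(sprintf(
        "partial likelihood did not converge (iterations: %d; coefficients: %s); possible separation or monotone likelihood",
        fit$iter, paste(signif(beta, 3), collapse = ", ")))
    }
    V <- unname(fit$var)
    explp <- exp(drop(X %*% beta))
  } else {
    X <- matrix(numeric(0), nrow = length(s$time), ncol = 0)
    beta <- numeric(0)
    V <- matrix(numeric(0), 0, 0)
    explp <- rep(1, length(s$time))
  }
  bh <- breslow_increments(s$time, s$status, explp, s$weights)
  structure(list(
    coefficients = setNames(beta, covariates),
    vcov = V,
    baseline = fg_stepfun(bh$time, cumsum(bh$jump), v0 = 0, type = "cumhaz"),
    baseline_jumps = bh$jump,
    covariate_names = covariates,
    n_events = sum(s$status * s$weights),
    sample = list(time = s$time, status = s$status, X = X, weights = s$weights),
    drawn = FALSE
  ), class = "fgmi_ph")
}

#' @export
print.fgmi_ph <- function(x, ...) {
  cat(sprintf("<fgmi_ph: %d coefficient(s), %g events%s>\n",
              length(x$coefficients), x$n_events,
              if (x$drawn) ", drawn parameters" else ""))
  if (length(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' @rdname fit_ph
#' @param x An `fgmi_ph` object.
#' @param ... Unused.
#' @method tidy fgmi_ph
#' @export
tidy.fgmi_ph <- function(x, ...) {
  se <- if (length(x$coefficients)) sqrt(diag(as.matrix(x$vcov))) else numeric(0)
  tibble::tibble(term = x$covariate_names,
                 estimate = unname(x$coefficients),
                 std.error = se,
                 conf.low = unname(x$coefficients) - 1.959964 * se,
                 conf.high = unname(x$coefficients) + 1.959964 * se)
}

#' @rdname fit_ph
#' @method glance fgmi_ph
#' @export
glance.fgmi_ph <- function(x, ...) {
  tibble::tibble(n = length(x$sample$time), n_events = x$n_events,
                 n_terms = length(x$coefficients))
}

#' Approximate posterior draw of proportional-hazards parameters
#'
#' Draws coefficients from a multivariate normal centred at the estimate with
#' the estimated covariance (approximate Bayesian posterior), and recomputes
#' the Breslow baseline cumulative hazard at the drawn coefficients on the
#' fitting sample. Substantive-model-compatible imputation uses one such draw
#' per chain iteration.
#'
#' @param fit An [fit_ph()] object.
#' @return A modified `fgmi_ph` with `drawn = TRUE`.
#' @export
draw_ph_parameters <- function(fit) {
  stopifnot(inherits(fit, "fgmi_ph"))
  beta <- mvn_draw(unname(fit$coefficients), fit$vcov)
  s <- fit$sample
  explp <- if (length(beta)) exp(drop(s$X %*% beta)) else rep(1, length(s$time))
  bh <- breslow_increments(s$time, s$status, explp, s$weights)
  fit$coefficients <- setNames(beta, fit$covariate_names)
  fit$baseline <- fg_stepfun(bh$time, cumsum(bh$jump), v0 = 0, type = "cumhaz")
  fit$baseline_jumps <- bh$jump
  fit$drawn <- TRUE
  fit
}

new_row_lp <- function(fit, newdata) {
  if (!length(fit$covariate_names)) return(0)
  x <- unlist(newdata)[fit$covariate_names]
  if (anyNA(x)) stop_fgmi("newdata must supply a value for every model covariate")
  drop(sum(x * unname(fit$coefficients)))
}

#' Cumulative incidence implied by a proportional hazards fit
#'
#' F(t | x) = 1 - exp\{-Lambda0(t) exp(beta'x)\}. When the fit is the Cox
#' representation of a Fine-Gray model on the subdistribution time, this is
#' the model-based cumulative incidence for the event of interest.
#'
#' @param fit An [fit_ph()] object.
#' @param newdata A one-row data frame (or named vector coercible to one)
#'   giving the covariate values; the baseline reference is covariates = 0.
#' @param times Nonnegative evaluation times.
#' @return A tibble with columns `time` and `cif`.
#' @export
cif_from_ph <- function(fit, newdata, times) {
  stopifnot(inherits(fit, "fgmi_ph"))
  if (any(times < 0)) stop_fgmi("times must be nonnegative")
  lp <- new_row_lp(fit, newdata)
  H <- step_eval(fit$baseline, times) * exp(lp)
  tibble::tibble(time = as.numeric(times), cif = 1 - exp(-H))
}

#' Asymptotic variance of a model-based cumulative incidence
#'
#' Delta-method variance of F(t | x) = 1 - exp\{-Lambda(t | x)\} based on the
#' standard Cox large-sample decomposition of the Breslow estimator:
#' Var\{Lambda(t|x)\} = exp(2 b'x) * sum_j dj / S0(tj)^2  +  g(t)' V g(t),
#' with S0(tj) the risk-set sum of exp(lp), g(t) = exp(b'x) * sum_j
#' (x - S1(tj)/S0(tj)) dj / S0(tj) the gradient in the coefficients, and V
#' the coefficient covariance. Then Var(F) = (1-F)^2 Var(Lambda), and on the
#' complementary log-log scale Var(cloglog F) = Var(Lambda) / Lambda^2.
#'
#' @inheritParams cif_from_ph
#' @return A tibble with columns `time`, `cif`, `var`, `var_cloglog`.
#' @export
cif_variance <- function(fit, newdata, times) {
  stopifnot(inherits(fit, "fgmi_ph"))
  s <- fit$sample
  p <- length(fit$covariate_names)
  x <- if (p) unlist(newdata)[fit$covariate_names] else numeric(0)
  lp <- new_row_lp(fit, newdata)
  o <- order(s$time)
  t_s <- s$time[o]; d_s <- s$status[o]; w_s <- s$weights[o]
  explp <- if (p) exp(drop(s$X %*% unname(fit$coefficients))) else rep(1, length(t_s))
  r_s <- (s$weights * explp)[o]
  tj <- fit$baseline$knots
  if (length(times) && length(tj) && max(times) > max(t_s)) {
    warning("times beyond the last observation: carrying the last value forward", call. = FALSE)
  }
  if (!length(tj)) {
    F0 <- rep(0, length(times))
    return(tibble::tibble(time = as.numeric(times), cif = F0, var = 0, var_cloglog = NA_real_))
  }
  first <- match(tj, t_s)
  s0 <- rev(cumsum(rev(r_s)))[first]
  dj <- as.numeric(rowsum(w_s[d_s == 1], factor(t_s[d_s == 1], levels = tj))[, 1L])
  # S1(tj): p-vector risk sums of x_i * w_i * exp(lp_i)
  if (p) {
    Xr <- (s$X * (s$weights * explp))[o, , drop = FALSE]
    S1 <- apply(Xr, 2, function(col) rev(cumsum(rev(col)))[first])
    S1 <- matrix(S1, nrow = length(tj), ncol = p)
    gincr <- (matrix(x, length(tj), p, byrow = TRUE) - S1 / s0) * (dj / s0)
    Gcum <- apply(gincr, 2, cumsum)
    Gcum <- matrix(Gcum, nrow = length(tj), ncol = p)
  }
  v0cum <- cumsum(dj / s0^2)
  idx <- findInterval(times, tj)
  elp <- exp(lp)
  H <- c(0, cumsum(dj / s0))[idx + 1L] * elp
  varL <- numeric(length(times))
  pos <- idx > 0
  varL[pos] <- elp^2 * v0cum[idx[pos]]
  if (p) {
    g <- matrix(0, length(times), p)
    g[pos, ] <- elp * Gcum[idx[pos], , drop = FALSE]
    varL <- varL + rowSums((g %*% fit$vcov) * g)
  }
  Fhat <- 1 - exp(-H)
  tibble::tibble(time = as.numeric(times),
                 cif = Fhat,
                 var = (1 - Fhat)^2 * varL,
                 var_cloglog = ifelse(H > 0, varL / H^2, NA_real_))
}
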