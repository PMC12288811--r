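#' Rubin's-rules pooling of coefficient estimates
#'
#' Pools M per-dataset estimates and variances: pooled estimate is the mean;
#' within variance W is the mean of the variances; between variance B the
#' sample variance of the estimates; total variance T = W + (1 + 1/M) B.
#' Degrees of freedom use the Barnard-Rubin small-sample adjustment with
#' complete-data degrees of freedom `df_com` (n - p by default in the
#' higher-level wrappers); intervals are t-based.
#'
#' @param estimates M x p matrix (or vector for p = 1) of per-dataset
#'   estimates.
#' @param variances M x p matrix of per-dataset squared standard errors.
#' @param df_com Complete-data degrees of freedom.
#' @param terms Optional term labels.
#' @param level Confidence level.
#' @return An object of class `fgmi_pooled`; see [tidy.fgmi_pooled()].
#' @export
pool_coefficients <- function(estimates, variances, df_com = Inf, terms = NULL,
                              level = 0.95) {
  Q <- rbind(estimates)
  U <- rbind(variances)
  M <- nrow(Q)
  p <- ncol(Q)
  terms <- terms %||% colnames(Q) %||% paste0("term", seq_len(p))
  qbar <- unname(colMeans(Q))
  W <- unname(colMeans(U))
  if (M == 1) {
    warning("single dataset: between-imputation variance not estimable; no interval", call. = FALSE)
    res <- tibble::tibble(term = terms, estimate = qbar, within = W, between = NA_real_,
                          total = W, std.error = sqrt(W), df = NA_real_,
                          conf.low = NA_real_, conf.high = NA_real_)
    return(structure(list(table = res, m = 1, level = level), class = "fgmi_pooled"))
  }
  B <- unname(apply(Q, 2, var))
  Tv <- W + (1 + 1 / M) * B
  df <- barnard_rubin_df(M, B, Tv, df_com)
  a <- qt(1 - (1 - level) / 2, df)
  res <- tibble::tibble(term = terms, estimate = qbar, within = W, between = B,
                        total = Tv, std.error = sqrt(Tv), df = df,
                        conf.low = qbar - a * sqrt(Tv), conf.high = qbar + a * sqrt(Tv))
  structure(list(table = res, m = M, level = level), class = "fgmi_pooled")
}

# Barnard & Rubin (1999) adjusted degrees of freedom
barnard_rubin_df <- function(M, B, Tv, df_com) {
  lambda <- (1 + 1 / M) * B / Tv
  lambda <- pmax(lambda, 1e-12)
  df_old <- (M - 1) / lambda^2
  if (is.infinite(df_com)) return(df_old)
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  df_old * df_obs / (df_old + df_obs)
}

#' @export
print.fgmi_pooled <- function(x, ...) {
  cat(sprintf("<fgmi_pooled: %d term(s) pooled over %d dataset(s)>\n",
              nrow(x$table), x$m))
  print(x$table)
  invisible(x)
}

#' Tidy a pooled-coefficients object
#'
#' @param x An `fgmi_pooled` object.
#' @param ... Unused.
#' @return A tibble with one row per term: estimate, within/between/total
#'   variance, std.error, df, confidence limits.
#' @method tidy fgmi_pooled
#' @export
tidy.fgmi_pooled <- function(x, ...) x$table

#' @rdname tidy.fgmi_pooled
#' @method glance fgmi_pooled
#' @export
glance.fgmi_pooled <- function(x, ...) {
  tibble::tibble(m = x$m, level = x$level, n_terms = nrow(x$table))
}

#' Fit a Fine-Gray model in each completed dataset and pool
#'
#' Fits the Cox representation of the Fine-Gray model (outcome `V`, event
#' indicator `ev1`) in every dataset of an imputation stack and pools the
#' coefficients with Rubin's rules (complete-data df = n - p).
#'
#' @param stack An `fgmi_stack` (or plain list of data frames), each dataset
#'   censoring-complete and with complete covariates.
#' @param covariates Covariate column names.
#' @param level Confidence level.
#' @return An `fgmi_pooled` object with the per-dataset fits in `$fits`.
#' @export
pool_fg <- function(stack, covariates, level = 0.95) {
  datasets <- if (inherits(stack, "fgmi_stack")) stack$datasets else stack
  fits <- lapply(datasets, fit_ph, covariates = covariates, time = "V", status = "ev1")
  est <- do.call(rbind, lapply(fits, function(f) unname(f$coefficients)))
  va <- do.call(rbind, lapply(fits, function(f) diag(as.matrix(f$vcov))))
  colnames(est) <- colnames(va) <- covariates
  df_com <- nrow(datasets[[1]]) - length(covariates)
  out <- pool_coefficients(est, va, df_com = df_com, terms = covariates, level = level)
  out$fits <- fits
  out
}

#' Pool cumulative incidence curves on the complementary log-log scale
#'
#' Per-dataset curves F_m(t) with delta-method variances are transformed to
#' theta_m = log(-log(1 - F_m)), pooled by Rubin's rules, and
#' back-transformed (predict-then-pool). Grid points where any F_m lies
#' outside (0, 1) are not transformable: there the pooled estimate is the
#' plain mean and the interval falls back to the untransformed bounds 0 / 1.
#'
#' @param cifs M x G matrix of per-dataset cumulative incidences on a shared
#'   time grid.
#' @param variances M x G matrix of variances of the F_m (natural scale, as
#'   from [cif_variance()]).
#' @param times The shared grid (length G).
#' @param df_com Complete-data degrees of freedom.
#' @param level Confidence level.
#' @return An object of class `fgmi_pooled_cif` whose `$table` has columns
#'   `time`, `estimate`, `conf.low`, `conf.high`.
#' @export
pool_cif <- function(cifs, variances, times, df_com = Inf, level = 0.95) {
  Fm <- rbind(cifs); Vm <- rbind(variances)
  M <- nrow(Fm)
  G <- ncol(Fm)
  stopifnot(length(times) == G)
  est <- lo <- hi <- numeric(G)
  for (g in seq_len(G)) {
    f <- Fm[, g]; v <- Vm[, g]
    if (any(f <= 0 | f >= 1 | !is.finite(v))) {
      est[g] <- mean(f)
      lo[g] <- 0; hi[g] <- if (any(f >= 1)) 1 else max(est[g], 0)
      if (all(f == 0)) { lo[g] <- 0; hi[g] <- 0 }
      next
    }
    theta <- log(-log(1 - f))
    vtheta <- v / ((1 - f) * log(1 - f))^2
    qbar <- mean(theta)
    W <- mean(vtheta)
    if (M == 1) {
      Tv <- W; df <- Inf
    } else {
      B <- var(theta)
      Tv <- W + (1 + 1 / M) * B
      df <- barnard_rubin_df(M, B, Tv, df_com)
    }
    a <- qt(1 - (1 - level) / 2, df)
    est[g] <- 1 - exp(-exp(qbar))
    lo[g] <- 1 - exp(-exp(qbar - a * sqrt(Tv)))
    hi[g] <- 1 - exp(-exp(qbar + a * sqrt(Tv)))
  }
  tab <- tibble::tibble(time = as.numeric(times), estimate = est,
                        conf.low = pmin(lo, hi), conf.high = pmax(lo, hi))
  structure(list(table = tab, m = M, level = level), class = "fgmi_pooled_cif")
}

#' @export
print.fgmi_pooled_cif <- function(x, ...) {
  cat(sprintf("<fgmi_pooled_cif: %d grid point(s), pooled over %d dataset(s)>\n",
              nrow(x$table), x$m))
  invisible(x)
}

#' @rdname pool_cif
#' @param x An `fgmi_pooled_cif` object.
#' @param ... Unused.
#' @method tidy fgmi_pooled_cif
#' @export
tidy.fgmi_pooled_cif <- function(x, ...) x$table

#' Predict-then-pool cumulative incidence for an imputation stack
#'
#' Computes the model-based cumulative incidence and its variance in each
#' completed dataset at a covariate profile, then pools on the cloglog scale.
#'
#' @param pooled An object from [pool_fg()] (its per-dataset fits are
#'   reused).
#' @param newdata One-row covariate profile.
#' @param times Time grid (default 101 points on \[0, 5\]).
#' @param level Confidence level.
#' @return An `fgmi_pooled_cif`.
#' @export
pooled_cif_at <- function(pooled, newdata, times = seq(0, 5, length.out = 101),
                          level = 0.95) {
  stopifnot(inherits(pooled, "fgmi_pooled"), !is.null(pooled$fits))
  per <- lapply(pooled$fits, cif_variance, newdata = newdata, times = times)
  Fm <- do.call(rbind, lapply(per, function(d) d$cif))
  Vm <- do.call(rbind, lapply(per, function(d) d$var))
  n <- length(pooled$fits[[1]]$sample$time)
  pool_cif(Fm, Vm, times, df_com = n - length(pooled$fits[[1]]$coefficients), level = level)
}
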