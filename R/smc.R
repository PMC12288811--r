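#' Covariate model specification
#'
#' Describes the model f(Xj | X(-j), Z; phi) for one partially observed
#' covariate used by substantive-model-compatible imputation. Predictors must
#' not include outcome variables: the outcome enters only through the
#' substantive-model likelihood factor.
#'
#' @param target Name of the partially observed covariate.
#' @param family `"logistic"` (binary 0/1), `"linear"` (continuous),
#'   `"multinomial"` (unordered factor) or `"prop_odds"` (ordered factor).
#' @param predictors Names of the predictor columns.
#' @return A `fgmi_cov_model` list.
#' @export
cov_model <- function(target, family = c("logistic", "linear", "multinomial", "prop_odds"),
                      predictors = character()) {
  family <- match.arg(family)
  bad <- intersect(predictors, c("V", "ev1", "L1_V", "H1_T", "H2_T", "time", "status", "v_imputed"))
  if (length(bad)) {
    stop_fgmi(sprintf("covariate-model predictors must not contain outcome variables (%s)",
                      paste(bad, collapse = ", ")))
  }
  structure(list(target = target, family = family, predictors = predictors),
            class = "fgmi_cov_model")
}

# ---- covariate model fitting, approximate-Bayes parameter draws, sampling ----

fit_cov_fam <- function(data, model, ridge = 1e-4) {
  W <- cbind(`(Intercept)` = 1, as.matrix(
    if (length(model$predictors)) data_to_numeric(data[model$predictors]) else
      matrix(numeric(0), nrow(data), 0)))
  # drop aliased columns (e.g. event-indicator contrasts that sum to 1 when
  # nobody is censored) keeping a full-rank basis; callers subset their
  # prediction matrix with `keep`
  q <- qr(W)
  keep <- sort(q$pivot[seq_len(q$rank)])
  W <- W[, keep, drop = FALSE]
  y <- data[[model$target]]
  out <- switch(model$family,
    logistic = {
      fit <- suppressWarnings(glm.fit(W, as.numeric(y), family = binomial()))
      if (!fit$converged || anyNA(fit$coefficients) || any(abs(fit$coefficients) > 15)) {
        fit <- ridge_logistic(W, as.numeric(y), ridge)
        warning("separation in logistic covariate model; ridge fallback used", call. = FALSE)
      }
      list(coef = fit$coefficients, vcov = fit$vcov %||% glm_vcov(fit, W))
    },
    linear = {
      fit <- lm.fit(W, as.numeric(y))
      rdf <- fit$df.residual
      s2 <- sum(fit$residuals^2) / rdf
      XtXinv <- chol2inv(chol(crossprod(W)))
      list(coef = fit$coefficients, XtXinv = XtXinv, sigma2 = s2, df = rdf)
    },
    multinomial = {
      df <- data.frame(.y = factor(y), W[, -1, drop = FALSE])
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
      list(coef = c(t(coef(fit))), vcov = vcov(fit), fit = fit, levels = levels(factor(y)))
    },
    prop_odds = {
      df <- data.frame(.y = factor(y, ordered = TRUE), W[, -1, drop = FALSE])
      fit <- MASS::polr(.y ~ ., data = df, Hess = TRUE)
      list(coef = c(coef(fit), fit$zeta), vcov = vcov(fit), fit = fit,
           levels = levels(factor(y, ordered = TRUE)))
    })
  out$keep <- keep
  out
}

glm_vcov <- function(fit, W) {
  p <- fit$fitted.values
  wgt <- p * (1 - p)
  chol2inv(chol(crossprod(W * sqrt(wgt))))
}

# logistic IRLS with a small L2 penalty; used when plain ML separates
ridge_logistic <- function(W, y, lambda = 1e-4, maxit = 50) {
  beta <- rep(0, ncol(W))
  P <- diag(lambda, ncol(W)); P[1, 1] <- 0
  for (i in seq_len(maxit)) {
    eta <- drop(W %*% beta)
    mu <- expit(eta)
    wgt <- pmax(mu * (1 - mu), 1e-10)
    I <- crossprod(W * sqrt(wgt)) + P
    g <- crossprod(W, y - mu) - P %*% beta
    step <- solve(I, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  list(coefficients = drop(beta), vcov = solve(I), converged = TRUE)
}

draw_cov_params <- function(cf, family) {
  switch(family,
    logistic = ,
    multinomial = ,
    prop_odds = { out <- cf; out$coef <- mvn_draw(cf$coef, cf$vcov); out },
    linear = {
      out <- cf
      out$sigma2 <- cf$sigma2 * cf$df / rchisq(1, cf$df)
      out$coef <- mvn_draw(cf$coef, out$sigma2 * cf$XtXinv)
      out
    })
}

# per-row probabilities over target levels (n x K) under drawn parameters
cov_level_probs <- function(cf, family, Wmis, levels) {
  n <- nrow(Wmis)
  switch(family,
    logistic = {
      p1 <- expit(drop(Wmis %*% cf$coef))
      cbind(1 - p1, p1)
    },
    multinomial = {
      K <- length(levels)
      B <- matrix(cf$coef, nrow = K - 1, byrow = TRUE)
      eta <- Wmis %*% t(B)
      ex <- cbind(1, exp(eta))
      ex / rowSums(ex)
    },
    prop_odds = {
      K <- length(levels)
      nb <- ncol(Wmis) - 1
      beta <- cf$coef[seq_len(nb)]
      zeta <- sort(cf$coef[nb + seq_len(K - 1)])
      lp <- drop(Wmis[, -1, drop = FALSE] %*% beta)
      cum <- vapply(zeta, function(z) expit(z - lp), numeric(n))
      cum <- cbind(matrix(cum, nrow = n), 1)
      probs <- cum - cbind(0, cum[, -K, drop = FALSE])
      pmax(probs, 0)
    },
    stop_fgmi("level probabilities only defined for discrete families"))
}

data_to_numeric <- function(df) {
  out <- lapply(df, function(col) {
    if (is.factor(col)) stats::model.matrix(~col)[, -1, drop = FALSE] else as.numeric(col)
  })
  do.call(cbind, out)
}

# ---- outcome-model densities ----

#' Fine-Gray outcome density for imputation
#'
#' Evaluates f(V, D | X, Z) = lambda1(V|x)^I(D=1) exp\{-Lambda1(V|x)\} under
#' the Cox representation of a Fine-Gray model on the subdistribution time,
#' with Lambda1(V|x) = Lambda01(V) exp(beta'x) and the baseline jump at V as
#' lambda01(V) (events sit on a Breslow jump of the fit; for an event time
#' carrying no jump the jump of the containing risk-set time is used). The
#' baseline-jump factor is retained, not cancelled, so the same code path
#' serves the cause-specific density.
#'
#' @param V Subdistribution times (vector).
#' @param ev1 Event-of-interest indicators (vector).
#' @param x Matrix or data frame of covariate values, columns matching
#'   `fit$covariate_names`.
#' @param fit An [fit_ph()] object fitted on (V, ev1).
#' @return Nonnegative density values, one per row.
#' @export
outcome_density_fg <- function(V, ev1, x, fit) {
  x <- as.matrix(x)[, fit$covariate_names, drop = FALSE]
  lp <- drop(x %*% unname(fit$coefficients))
  H0 <- step_eval(fit$baseline, V)
  dens <- exp(-H0 * exp(lp))
  ev <- which(ev1 == 1)
  if (length(ev)) {
    idx <- findInterval(V[ev], fit$baseline$knots)
    if (any(idx == 0)) stop_fgmi("an event time precedes every baseline jump; cannot evaluate the hazard factor")
    dens[ev] <- dens[ev] * fit$baseline_jumps[idx] * exp(lp[ev])
  }
  dens
}

#' Cause-specific outcome density for imputation
#'
#' Evaluates f(T, D | X, Z) = \{h1 S\}^I(D=1) \{h2 S\}^I(D=2) S^I(D=0) with
#' S(T|x) = exp\{-H1(T|x) - H2(T|x)\} under two cause-specific proportional
#' hazards fits (cause k as event, the rest censored).
#'
#' @param time Observation times.
#' @param d Event indicators in 0/1/2.
#' @param x Covariate values (rows aligned with `time`).
#' @param fit1,fit2 [fit_ph()] objects for cause 1 and cause 2.
#' @return Nonnegative density values, one per row.
#' @export
outcome_density_cs <- function(time, d, x, fit1, fit2) {
  x <- as.matrix(x)
  dens <- rep(1, length(time))
  for (k in 1:2) {
    fit <- list(fit1, fit2)[[k]]
    if (is.null(fit)) next  # a cause with no events contributes hazard 0
    xk <- x[, fit$covariate_names, drop = FALSE]
    lp <- drop(xk %*% unname(fit$coefficients))
    dens <- dens * exp(-step_eval(fit$baseline, time) * exp(lp))
    ev <- which(d == k)
    if (length(ev)) {
      idx <- findInterval(time[ev], fit$baseline$knots)
      if (any(idx == 0)) stop_fgmi("an event time precedes every baseline jump; cannot evaluate the hazard factor")
      dens[ev] <- dens[ev] * fit$baseline_jumps[idx] * exp(lp[ev])
    }
  }
  dens
}

# ---- sampling of imputed values ----

#' Direct sampling of a discrete covariate from the compatible density
#'
#' For a discrete target the substantive-model-compatible conditional is
#' available in closed form: P(level) is proportional to
#' outcome_density(level) x prior(level), normalized over levels, so no
#' rejection step is needed.
#'
#' @param density n x K matrix of outcome-model densities, one column per level.
#' @param prior n x K matrix of covariate-model probabilities.
#' @param levels Vector of K level values.
#' @return List with `values` (n sampled levels) and `probs` (n x K matrix).
#' @export
smc_sample_discrete <- function(density, prior, levels) {
  num <- density * prior
  tot <- rowSums(num)
  if (any(tot <= 0 | !is.finite(tot))) {
    bad <- which(tot <= 0 | !is.finite(tot))
    stop_fgmi(sprintf("product density vanished for %d row(s) (first row index %d); imputation impossible",
                      length(bad), bad[1]))
  }
  probs <- num / tot
  u <- runif(nrow(probs))
  cum <- t(apply(probs, 1, cumsum))
  cum <- matrix(cum, nrow = nrow(probs))
  cum[, ncol(cum)] <- Inf  # guard against cumulative rounding below 1
  # first level whose cumulative probability exceeds u
  pick <- max.col(u < cum, ties.method = "first")
  list(values = levels[pick], probs = probs)
}

#' Rejection sampling of a continuous covariate
#'
#' Proposes from the covariate model and accepts with probability
#' outcome_density / bound, where the bound is adapted per row from a
#' pre-sample of proposals (max density, inflated). Rows hitting the attempt
#' cap keep the proposal with the highest product density seen (counted in
#' the diagnostics).
#'
#' @param propose Function `(rows) -> proposals`, one value per requested row.
#' @param density Function `(values, rows) -> outcome densities`.
#' @param n Number of rows to impute.
#' @param presample Pre-sample size used to adapt the bound.
#' @param inflate Bound inflation factor.
#' @param cap Maximum number of proposal rounds.
#' @return List with `values`, `acceptance_rate`, `n_fallback`.
#' @export
smc_sample_continuous <- function(propose, density, n, presample = 25, inflate = 1.2, cap = 1000) {
  rows <- seq_len(n)
  dmax <- rep(0, n)
  for (b in seq_len(presample)) {
    pr <- propose(rows)
    dmax <- pmax(dmax, density(pr, rows))
  }
  bound <- pmax(dmax * inflate, .Machine$double.xmin)
  out <- rep(NA_real_, n)
  best_val <- rep(NA_real_, n)
  best_d <- rep(-Inf, n)
  pending <- rows
  n_prop <- 0L; n_acc <- 0L
  for (att in seq_len(cap)) {
    pr <- propose(pending)
    dd <- density(pr, pending)
    n_prop <- n_prop + length(pending)
    better <- dd > best_d[pending]
    best_val[pending[better]] <- pr[better]
    best_d[pending[better]] <- dd[better]
    acc <- runif(length(pending)) < dd / bound[pending]
    n_acc <- n_acc + sum(acc)
    out[pending[acc]] <- pr[acc]
    pending <- pending[!acc]
    if (!length(pending)) break
  }
  n_fb <- length(pending)
  if (n_fb) out[pending] <- best_val[pending]
  list(values = out, acceptance_rate = n_acc / max(n_prop, 1), n_fallback = n_fb)
}

# ---- the chained SMC-FCS sampler ----

#' Substantive-model-compatible chained imputation of missing covariates
#'
#' Imputes missing covariate cells from the density proportional to
#' (substantive-model likelihood) x (covariate model), chained across
#' partially observed covariates. Two substantive models are supported:
#' `"fine_gray"` - a Fine-Gray model for the event of interest in its Cox
#' representation, requiring censoring-complete columns `V` and `ev1` (see
#' [make_subdist_time()] / [impute_censoring_times()]); and
#' `"cause_specific"` - two cause-specific Cox models on (`time`, `status`)
#' with status coded 0/1/2.
#'
#' Each chain iteration refits the substantive model(s) on the current
#' completed data, draws coefficients from their approximate posterior
#' (baseline recomputed by the Breslow formula at the drawn coefficients),
#' then for each partially observed covariate in turn (ascending missingness)
#' fits and draws its covariate model and re-imputes the missing cells:
#' discrete targets by direct sampling of the normalized product density,
#' continuous targets by adaptive rejection sampling. Missing cells are
#' initialized by draws from the observed marginal.
#'
#' @param data A data frame (one censoring-complete dataset for
#'   `"fine_gray"`).
#' @param substantive `"fine_gray"` or `"cause_specific"`.
#' @param covariates Covariates of the substantive model: a character vector,
#'   or for `"cause_specific"` optionally a list of two character vectors
#'   (per cause). Every partially observed covariate must appear.
#' @param covariate_models List of [cov_model()] specifications, one per
#'   partially observed covariate.
#' @param m Number of imputed datasets.
#' @param iterations Chain iterations per dataset.
#' @param seed Optional integer; one sub-stream per imputed dataset.
#' @param time,status Outcome column names for `"cause_specific"`.
#' @param rejection List of rejection-sampler controls
#'   (`presample`, `inflate`, `cap`).
#' @return An `fgmi_stack` with `m` completed datasets and acceptance
#'   diagnostics in `meta`.
#' @export
run_smcfcs <- function(data, substantive = c("fine_gray", "cause_specific"),
                       covariates, covariate_models, m = 5, iterations = 20,
                       seed = NULL, time = "time", status = "status",
                       rejection = list(presample = 25, inflate = 1.2, cap = 1000)) {
  substantive <- match.arg(substantive)
  data <- tibble::as_tibble(data)
  covs <- if (is.list(covariates)) covariates else list(covariates, covariates)
  all_covs <- unique(unlist(covs))
  if (substantive == "fine_gray") {
    assert_cols(data, c("V", "ev1"), "run_smcfcs(fine_gray)")
    if (anyNA(data$V)) stop_fgmi("V must be complete; impute censoring times first")
  } else {
    assert_cols(data, c(time, status), "run_smcfcs(cause_specific)")
  }
  targets <- vapply(covariate_models, `[[`, "", "target")
  names(covariate_models) <- targets
  if (!all(targets %in% all_covs)) {
    stop_fgmi("every partially observed covariate must appear in the substantive model")
  }
  miss <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(miss) <- targets
  frac <- vapply(miss, length, 0L) / nrow(data)
  visit <- targets[order(frac)]               # ascending missingness, ties by column order
  if (all(frac == 0)) {
    return(new_fgmi_stack(rep(list(data), m),
                          meta = list(m = m, kind = "covariate", iterations = iterations,
                                      note = "no missing cells")))
  }
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, m) else spawn_seeds(seed, m)
  datasets <- vector("list", m)
  diag <- list()
  for (j in seq_len(m)) {
    set.seed(seeds[j])
    res <- NULL
    for (attempt in 1:2) {
      completed <- init_missing(data, miss)
      res <- tryCatch(
        smcfcs_chain(completed, substantive, covs, covariate_models, miss, visit,
                     iterations, time, status, rejection),
        error = function(e) e)
      if (!inherits(res, "error")) break
      if (attempt == 2) {
        stop_fgmi(sprintf("imputation chain failed twice for dataset %d: %s", j, conditionMessage(res)))
      }
    }
    datasets[[j]] <- res$data
    diag[[j]] <- res$diag
  }
  new_fgmi_stack(datasets, meta = list(m = m, kind = "covariate", seeds = seeds,
                                       iterations = iterations, method = paste0(substantive, "_smc"),
                                       diagnostics = diag))
}

init_missing <- function(data, miss) {
  for (v in names(miss)) {
    rows <- miss[[v]]
    if (!length(rows)) next
    obs <- data[[v]][!is.na(data[[v]])]
    data[[v]][rows] <- sample(obs, length(rows), replace = TRUE)
  }
  data
}

smcfcs_chain <- function(completed, substantive, covs, covariate_models, miss, visit,
                         iterations, time, status, rejection) {
  diag <- list(acceptance = list(), fallbacks = 0L)
  for (it in seq_len(iterations)) {
    if (substantive == "fine_gray") {
      sfit <- draw_ph_parameters(fit_ph(completed, covs[[1]], time = "V", status = "ev1"))
      dens_fun <- function(xdf, rows) {
        outcome_density_fg(completed$V[rows], completed$ev1[rows], xdf, sfit)
      }
    } else {
      d1 <- data.frame(time = completed[[time]], status = as.numeric(completed[[status]] == 1))
      d2 <- data.frame(time = completed[[time]], status = as.numeric(completed[[status]] == 2))
      d1[unique(unlist(covs))] <- completed[unique(unlist(covs))]
      d2[unique(unlist(covs))] <- completed[unique(unlist(covs))]
      sfit1 <- draw_ph_parameters(fit_ph(d1, covs[[1]]))
      sfit2 <- if (any(d2$status == 1)) draw_ph_parameters(fit_ph(d2, covs[[2]])) else NULL
      dens_fun <- function(xdf, rows) {
        outcome_density_cs(completed[[time]][rows], completed[[status]][rows], xdf, sfit1, sfit2)
      }
    }
    for (v in visit) {
      rows <- miss[[v]]
      if (!length(rows)) next
      model <- covariate_models[[v]]
      cf <- draw_cov_params(fit_cov_fam(completed, model), model$family)
      Wmis <- cbind(1, if (length(model$predictors))
        data_to_numeric(completed[rows, model$predictors, drop = FALSE]) else
        matrix(numeric(0), length(rows), 0))
      Wmis <- Wmis[, cf$keep, drop = FALSE]
      xbase <- completed[rows, unique(unlist(covs)), drop = FALSE]
      if (model$family %in% c("logistic", "multinomial", "prop_odds")) {
        levels <- target_levels(completed[[v]], model$family)
        prior <- cov_level_probs(cf, model$family, Wmis, levels)
        dens <- vapply(levels, function(lv) {
          xl <- xbase; xl[[v]] <- rep(lv, nrow(xl))
          dens_fun(data_to_numeric(xl), rows)
        }, numeric(length(rows)))
        dens <- matrix(dens, nrow = length(rows))
        smp <- smc_sample_discrete(dens, prior, levels)
        completed[[v]][rows] <- smp$values
      } else {
        mu <- drop(Wmis %*% cf$coef)
        sdv <- sqrt(cf$sigma2)
        propose <- function(idx) rnorm(length(idx), mu[idx], sdv)
        density <- function(vals, idx) {
          xl <- xbase[idx, , drop = FALSE]
          xl[[v]] <- vals
          dens_fun(data_to_numeric(xl), rows[idx])
        }
        smp <- smc_sample_continuous(propose, density, length(rows),
                                     rejection$presample %||% 25,
                                     rejection$inflate %||% 1.2,
                                     rejection$cap %||% 1000)
        completed[[v]][rows] <- smp$values
        diag$acceptance[[v]] <- c(diag$acceptance[[v]], smp$acceptance_rate)
        diag$fallbacks <- diag$fallbacks + smp$n_fallback
      }
    }
  }
  list(data = completed, diag = diag)
}

# targets entering a proportional-hazards linear predictor must be numeric;
# multi-level targets are handled through their numeric level codes
target_levels <- function(col, family) {
  if (family == "logistic") c(0, 1) else sort(unique(col[!is.na(col)]))
}
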