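#' Predictor matrix for approximately compatible imputation
#'
#' Builds the design matrix of the directly specified (chained-equations)
#' imputation model for one target covariate. For the Fine-Gray flavor the
#' mandated predictors are the remaining covariates plus the event-of-interest
#' indicator `ev1` and the marginal cumulative subdistribution hazard `L1_V`;
#' for the cause-specific flavor they are the remaining covariates, the event
#' indicator as factor contrasts (`D1`, `D2` against censored), and the
#' marginal cause-specific cumulative hazards `H1_T`, `H2_T`.
#'
#' @param data A data frame carrying the required outcome summary columns.
#' @param flavor `"fg_approx"` or `"cs_approx"`.
#' @param other_covariates The substantive-model covariates other than the
#'   target.
#' @param interaction Also include the `ev1 x L1_V` interaction
#'   (`"fg_approx"` only; default off).
#' @param status Status column name (`"cs_approx"`).
#' @return A list with `matrix` (numeric, no intercept) and `labels`.
#' @export
build_predictor_matrix <- function(data, flavor = c("fg_approx", "cs_approx"),
                                   other_covariates = character(),
                                   interaction = FALSE, status = "status") {
  flavor <- match.arg(flavor)
  W <- if (length(other_covariates)) {
    as.data.frame(data[other_covariates])
  } else {
    data.frame(row.names = seq_len(nrow(data)))
  }
  if (flavor == "fg_approx") {
    assert_cols(data, c("ev1", "L1_V"),
                "build_predictor_matrix (run make_subdist_time()/impute_censoring_times() and add_subdist_hazard() first)")
    W$ev1 <- data$ev1
    W$L1_V <- data$L1_V
    if (interaction) W$`ev1:L1_V` <- data$ev1 * data$L1_V
  } else {
    assert_cols(data, c("H1_T", "H2_T"),
                "build_predictor_matrix (run attach_cause_specific_hazards() first)")
    assert_cols(data, status, "build_predictor_matrix")
    W$D1 <- as.numeric(data[[status]] == 1)
    W$D2 <- as.numeric(data[[status]] == 2)
    W$H1_T <- data$H1_T
    W$H2_T <- data$H2_T
  }
  M <- if (ncol(W)) data_to_numeric(W) else matrix(numeric(0), nrow(data), 0)
  colnames(M) <- names(W)
  list(matrix = M, labels = names(W))
}

#' Approximately compatible chained imputation (MICE-style)
#'
#' Imputes missing covariates from directly specified univariate models whose
#' predictors include the outcome summaries mandated by the flavor (see
#' [build_predictor_matrix()]). Each imputed dataset uses a fresh approximate
#' Bayesian parameter draw (normal perturbation of the MLE; linear models
#' additionally draw the residual variance). Continuous targets default to
#' predictive mean matching with 5 donors; Bayesian linear-regression draws
#' are available with `pmm = FALSE`. With a single partially observed
#' covariate one iteration suffices (there is no feedback path between
#' imputation models).
#'
#' @param data A data frame; for `"fg"` it must carry `ev1` and `L1_V`, for
#'   `"cs"` it must carry `status`, `H1_T` and `H2_T`.
#' @param flavor `"fg"` or `"cs"`.
#' @param covariates Substantive-model covariate names.
#' @param covariate_models List of [cov_model()] specs (target + family +
#'   the other covariates as predictors); the mandated outcome predictors are
#'   appended automatically.
#' @param m Number of imputed datasets.
#' @param iterations Cycles across targets per dataset.
#' @param pmm Use predictive mean matching for `"linear"` targets.
#' @param donors Number of donors for predictive mean matching.
#' @param interaction Include the `ev1 x L1_V` interaction (fg flavor).
#' @param seed Optional integer; one sub-stream per dataset.
#' @param status Status column name (cs flavor).
#' @return An `fgmi_stack` of `m` completed datasets.
#' @export
impute_approx <- function(data, flavor = c("fg", "cs"), covariates, covariate_models,
                          m = 5, iterations = 1, pmm = TRUE, donors = 5L,
                          interaction = FALSE, seed = NULL, status = "status") {
  flavor <- match.arg(flavor)
  data <- tibble::as_tibble(data)
  targets <- vapply(covariate_models, `[[`, "", "target")
  names(covariate_models) <- targets
  miss <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(miss) <- targets
  frac <- vapply(miss, length, 0L) / nrow(data)
  visit <- targets[order(frac)]
  if (all(frac == 0)) {
    return(new_fgmi_stack(rep(list(data), m),
                          meta = list(m = m, kind = "covariate", note = "no missing cells")))
  }
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, m) else spawn_seeds(seed, m)
  datasets <- vector("list", m)
  for (j in seq_len(m)) {
    set.seed(seeds[j])
    completed <- init_missing(data, miss)
    for (it in seq_len(iterations)) {
      for (v in visit) {
        rows <- miss[[v]]
        if (!length(rows)) next
        model <- covariate_models[[v]]
        pm <- build_predictor_matrix(completed,
                                     flavor = paste0(flavor, "_approx"),
                                     other_covariates = setdiff(union(model$predictors, covariates), v),
                                     interaction = interaction, status = status)
        completed[[v]][rows] <- impute_one_approx(
          y = data[[v]], W = pm$matrix, rows = rows, family = model$family,
          pmm = pmm, donors = donors, current = completed[[v]])
      }
    }
    datasets[[j]] <- completed
  }
  new_fgmi_stack(datasets, meta = list(m = m, kind = "covariate", seeds = seeds,
                                       iterations = iterations,
                                       method = paste0(flavor, "_approx")))
}

# fit on originally observed rows, draw parameters, impute the missing rows
impute_one_approx <- function(y, W, rows, family, pmm, donors, current) {
  obs <- which(!seq_along(y) %in% rows)
  dfit <- tibble::as_tibble(as.data.frame(W[obs, , drop = FALSE]))
  dfit$.target <- y[obs]
  spec <- list(target = ".target", family = family, predictors = colnames(W))
  cf <- fit_cov_fam(dfit, spec)
  cfd <- draw_cov_params(cf, family)
  Wm <- cbind(1, W[rows, , drop = FALSE])[, cf$keep, drop = FALSE]
  switch(family,
    logistic = rbinom(length(rows), 1, expit(drop(Wm %*% cfd$coef))),
    multinomial = ,
    prop_odds = {
      levels <- sort(unique(y[obs]))
      probs <- cov_level_probs(cfd, family, Wm, levels)
      smc_sample_discrete(matrix(1, length(rows), length(levels)), probs, levels)$values
    },
    linear = {
      mu_mis <- drop(Wm %*% cfd$coef)
      if (!pmm) {
        rnorm(length(rows), mu_mis, sqrt(cfd$sigma2))
      } else {
        # type-1 matching: observed predictions at the MLE, missing at the draw
        mu_obs <- drop(cbind(1, W[obs, , drop = FALSE])[, cf$keep, drop = FALSE] %*% cf$coef)
        vapply(mu_mis, function(mm) {
          d <- abs(mu_obs - mm)
          cand <- order(d)[seq_len(min(donors, length(d)))]
          y[obs][sample(cand, 1L)]
        }, numeric(1))
      }
    })
}
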