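#' Simulation scenario
#'
#' Bundles a data-generating mechanism, censoring and missingness
#' specifications, and the imputation settings used by [run_replicate()].
#' The study grid crosses mechanism (proportional subdistribution hazards vs
#' proportional cause-specific hazards), the baseline incidence level `p`,
#' and censoring type (none / administrative / random).
#'
#' @param mechanism `"fg_correct"` or `"cs_hazards"`.
#' @param p Baseline cumulative incidence at infinity (used to build default
#'   parameters).
#' @param censoring A [censoring_spec()].
#' @param missingness A [missingness_spec()] (calibrated lazily).
#' @param n Subjects per replicate.
#' @param m Imputed datasets per replicate.
#' @param iterations Chain iterations for substantive-model-compatible
#'   imputation.
#' @param fg_params Override the default [fg_correct_params()].
#' @param cs_params A [cs_hazard_params()] object; required when
#'   `mechanism = "cs_hazards"` (see [derive_least_false_cs_params()]).
#' @return A list of class `fgmi_scenario`.
#' @export
scenario <- function(mechanism = c("fg_correct", "cs_hazards"), p = 0.15,
                     censoring = censoring_spec("none"),
                     missingness = missingness_spec("mar_z"),
                     n = 2000, m = 10, iterations = 20,
                     fg_params = NULL, cs_params = NULL) {
  mechanism <- match.arg(mechanism)
  fg_params <- fg_params %||% fg_correct_params(p = p)
  if (mechanism == "cs_hazards" && is.null(cs_params)) {
    stop_fgmi("cs_hazards scenarios need cs_params (see derive_least_false_cs_params())")
  }
  if (is.null(missingness$eta0) && missingness$mechanism == "mar_z") {
    missingness <- calibrate_missingness(missingness)
  }
  structure(list(mechanism = mechanism, p = p, censoring = censoring,
                 missingness = missingness, n = n, m = m, iterations = iterations,
                 fg_params = fg_params, cs_params = cs_params),
            class = "fgmi_scenario")
}

fgmi_methods <- c("full", "cca", "cs_smc", "cs_approx", "fg_smc", "fg_approx")

#' Run one simulation replicate
#'
#' Generates one dataset under the scenario, applies censoring and
#' missingness, constructs (or multiply imputes) the subdistribution times,
#' runs the requested covariate-handling methods, fits the
#' proportional-subdistribution-hazards model in each completed dataset and
#' pools. All methods share the generated data and - under random censoring -
#' the same censoring-time imputations, so method contrasts are paired.
#'
#' @param scn A [scenario()].
#' @param methods Subset of `"full"`, `"cca"`, `"cs_smc"`, `"cs_approx"`,
#'   `"fg_smc"`, `"fg_approx"`.
#' @param seed Integer replicate seed.
#' @param cif Also compute pooled cumulative incidence curves.
#' @param cif_times Grid for the curves.
#' @param cif_profiles List of covariate profiles.
#' @return A tibble with one row per method x term (`estimate`,
#'   `std.error`, `df`, `conf.low`, `conf.high`), plus a `cif` list-column
#'   when requested.
#' @export
run_replicate <- function(scn, methods = fgmi_methods, seed = 1L, cif = FALSE,
                          cif_times = seq(0, 5, length.out = 21),
                          cif_profiles = list(c(X = 0, Z = 0), c(X = 1, Z = 1))) {
  stopifnot(inherits(scn, "fgmi_scenario"))
  methods <- match.arg(methods, fgmi_methods, several.ok = TRUE)
  set.seed(seed)
  latent <- if (scn$mechanism == "fg_correct") {
    gen_fg_correct(scn$n, scn$fg_params)
  } else {
    gen_cs_hazards(scn$n, scn$cs_params)
  }
  obs <- apply_censoring(latent, scn$censoring)
  mis <- induce_missingness(obs, scn$missingness)
  random_cens <- scn$censoring$kind %in% c("random", "covariate_dependent") && !scn$censoring$known
  covs <- c("X", "Z")
  xmod <- list(cov_model("X", "logistic", "Z"))

  mis <- attach_cause_specific_hazards(mis)
  if (random_cens) {
    cmod_kind <- if (scn$censoring$kind == "covariate_dependent") "ph_model" else "marginal_km"
    cmod <- fit_censoring_model(mis, cmod_kind,
                                covariates = if (cmod_kind == "ph_model") "Z" else character())
    cens_stack <- impute_censoring_times(mis, cmod, m = scn$m)$datasets
  } else {
    cc <- if (scn$censoring$kind == "none") {
      make_subdist_time(mis, "no_censoring")
    } else {
      make_subdist_time(mis, "administrative", admin = "C")
    }
    cc <- add_subdist_hazard(cc)
  }

  complete_stack_for <- function(method) {
    switch(method,
      full = {
        base <- if (random_cens) cens_stack else list(cc)
        lapply(base, function(d) { d$X <- obs$X; d })
      },
      cca = {
        keep <- !is.na(mis$X)
        base <- if (random_cens) cens_stack else list(cc)
        lapply(base, function(d) d[keep, , drop = FALSE])
      },
      fg_smc = impute_covariates(random_cens, cens_stack_or_cc(), function(d, m) {
        run_smcfcs(d, "fine_gray", covs, xmod, m = m, iterations = scn$iterations)$datasets
      }),
      cs_smc = impute_covariates(random_cens, cens_stack_or_cc(), function(d, m) {
        run_smcfcs(d, "cause_specific", covs, xmod, m = m, iterations = scn$iterations)$datasets
      }),
      fg_approx = impute_covariates(random_cens, cens_stack_or_cc(), function(d, m) {
        impute_approx(d, "fg", covs, xmod, m = m, iterations = 1)$datasets
      }),
      cs_approx = impute_covariates(random_cens, cens_stack_or_cc(), function(d, m) {
        impute_approx(d, "cs", covs, xmod, m = m, iterations = 1)$datasets
      }))
  }
  cens_stack_or_cc <- function() if (random_cens) cens_stack else cc
  impute_covariates <- function(random_cens, base, impute1) {
    if (random_cens) {
      unlist(lapply(base, impute1, m = 1), recursive = FALSE)
    } else {
      impute1(base, m = scn$m)
    }
  }

  out <- purrr::map_dfr(methods, function(method) {
    stack <- complete_stack_for(method)
    res <- if (length(stack) == 1) {
      fit <- fit_ph(stack[[1]], covariates = covs, time = "V", status = "ev1")
      se <- sqrt(diag(as.matrix(fit$vcov)))
      dfc <- nrow(stack[[1]]) - length(covs)
      a <- qt(0.975, dfc)
      tibble::tibble(term = covs, estimate = unname(fit$coefficients), std.error = se,
                     df = dfc, conf.low = estimate - a * se, conf.high = estimate + a * se)
    } else {
      tidy(pool_fg(stack, covs))[c("term", "estimate", "std.error", "df", "conf.low", "conf.high")]
    }
    res$method <- method
    if (cif) {
      fits <- lapply(stack, fit_ph, covariates = covs, time = "V", status = "ev1")
      pooled <- structure(list(fits = fits, m = length(fits)), class = "fgmi_pooled")
      res$cif <- list(lapply(cif_profiles, function(pr) {
        per <- lapply(fits, cif_variance, newdata = pr, times = cif_times)
        Fm <- do.call(rbind, lapply(per, function(d) d$cif))
        Vm <- do.call(rbind, lapply(per, function(d) d$var))
        tidy(pool_cif(Fm, Vm, cif_times, df_com = nrow(stack[[1]]) - length(covs)))
      }))
    }
    res
  })
  out$seed <- seed
  out
}

#' Run a batch of simulation replicates
#'
#' Per-replicate seeds are spawned deterministically from the batch seed, so
#' any replicate can be reproduced in isolation with [run_replicate()].
#' Replicates whose pipeline errors are dropped with a warning; their count
#' is available as `attr(result, "n_failed")`.
#'
#' @inheritParams run_replicate
#' @param nsim Number of replicates.
#' @param seed Batch seed.
#' @return A tibble of stacked [run_replicate()] outputs with a `replicate`
#'   column.
#' @export
run_simulation <- function(scn, methods = fgmi_methods, nsim = 100, seed = 1L,
                           cif = FALSE, cif_times = seq(0, 5, length.out = 21),
                           cif_profiles = list(c(X = 0, Z = 0), c(X = 1, Z = 1))) {
  seeds <- spawn_seeds(seed, nsim)
  res <- vector("list", nsim)
  failed <- 0L
  for (i in seq_len(nsim)) {
    r <- tryCatch(
      suppressWarnings(run_replicate(scn, methods, seed = seeds[i], cif = cif,
                                     cif_times = cif_times, cif_profiles = cif_profiles)),
      error = function(e) e)
    if (inherits(r, "error")) {
      failed <- failed + 1L
      warning(sprintf("replicate %d failed: %s", i, conditionMessage(r)), call. = FALSE)
    } else {
      r$replicate <- i
      res[[i]] <- r
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "n_failed") <- failed
  out
}

#' Monte-Carlo performance summary
#'
#' Bias, relative bias, empirical and average model standard errors, and
#' coverage per method and term, each with its Monte-Carlo standard error
#' (the standard simulation-study formulas: MCSE(bias) = empSE / sqrt(nsim),
#' MCSE(empSE) = empSE / sqrt(2 (nsim - 1)), coverage MCSE from the binomial
#' variance).
#'
#' @param results Output of [run_simulation()].
#' @param truth Named vector of true coefficient values, e.g.
#'   `c(X = 0.75, Z = 0.5)`.
#' @return A tibble, one row per method x term.
#' @export
summarize_performance <- function(results, truth) {
  results %>%
    dplyr::group_by(.data$method, .data$term) %>%
    dplyr::summarise(
      nsim = dplyr::n(),
      true = unname(truth[.data$term[1]]),
      bias = mean(.data$estimate) - .data$true,
      emp_se = sd(.data$estimate),
      bias_mcse = .data$emp_se / sqrt(.data$nsim),
      rel_bias_pct = 100 * .data$bias / .data$true,
      rel_bias_pct_mcse = 100 * .data$bias_mcse / abs(.data$true),
      emp_se_mcse = .data$emp_se / sqrt(2 * (.data$nsim - 1)),
      mod_se = sqrt(mean(.data$std.error^2)),
      coverage = mean(.data$conf.low <= .data$true & .data$true <= .data$conf.high),
      coverage_mcse = sqrt(.data$coverage * (1 - .data$coverage) / .data$nsim),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      .groups = "drop"
    )
}

#' Cumulative-incidence RMSE summary
#'
#' Root-mean-square error of pooled cumulative incidence estimates against a
#' true curve, per method, profile and grid time.
#'
#' @param results [run_simulation()] output with `cif = TRUE`.
#' @param true_curves List (one per profile) of tibbles with columns `time`
#'   and `cif` on the same grid.
#' @return A tibble with columns `method`, `profile`, `time`, `bias`, `rmse`.
#' @export
summarize_cif_performance <- function(results, true_curves) {
  rows <- results %>%
    dplyr::filter(.data$term == .data$term[1]) %>%
    dplyr::select("method", "replicate", "cif")
  purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    purrr::imap_dfr(rows$cif[[i]], function(tab, k) {
      tibble::tibble(method = rows$method[i], replicate = rows$replicate[i],
                     profile = k, time = tab$time,
                     err = tab$estimate - true_curves[[k]]$cif)
    })
  }) %>%
    dplyr::group_by(.data$method, .data$profile, .data$time) %>%
    dplyr::summarise(bias = mean(.data$err), rmse = sqrt(mean(.data$err^2)),
                     .groups = "drop")
}

#' @importFrom dplyr %>%
#' @importFrom rlang .data
NULL
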