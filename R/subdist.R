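#' Attach marginal cause-specific cumulative hazards
#'
#' Adds columns `H1_T` and `H2_T`: the Nelson-Aalen cause-specific cumulative
#' hazards (cause k as event, everything else censored) evaluated at each
#' subject's own observation time. These are the outcome summaries that the
#' cause-specific approximately compatible imputation models require.
#'
#' @param data A data frame with an observation time and an event indicator
#'   coded 0 (censored), 1 (event of interest), 2 (competing event).
#' @param time,status Column names.
#' @return The input data as a tibble with columns `H1_T`, `H2_T` appended.
#' @export
attach_cause_specific_hazards <- function(data, time = "time", status = "status") {
  assert_cols(data, c(time, status), "attach_cause_specific_hazards")
  d <- data[[status]]
  if (!all(d %in% 0:2)) stop_fgmi("status must be coded 0, 1, 2")
  out <- tibble::as_tibble(data)
  for (k in 1:2) {
    tmp <- data.frame(time = data[[time]], status = as.numeric(d == k))
    H <- if (any(tmp$status == 1)) {
      na_curve(tmp)
    } else {
      warning(sprintf("no cause-%d events: H%d_T set to 0", k, k), call. = FALSE)
      fg_stepfun(numeric(0), numeric(0), v0 = 0, type = "cumhaz")
    }
    out[[paste0("H", k, "_T")]] <- step_eval(H, data[[time]])
  }
  out
}

#' Construct fully observed subdistribution times
#'
#' For scenarios without random censoring the subdistribution time
#' V = I(D = 1) T + I(D != 1) C is known for everyone: subjects failing from
#' the competing event keep being "at risk" for the event of interest until
#' their (potential) censoring time. With no censoring at all, V for
#' competing-event failures is set to a common value beyond the largest
#' observed time (max(T) + 1; any value past the last cause-1 event time
#' yields the same partial likelihood). With administrative censoring, V is
#' the known potential censoring time.
#'
#' @param data A data frame with status coded 0/1/2.
#' @param mode `"no_censoring"` or `"administrative"`.
#' @param admin Column name holding the known potential censoring time
#'   (required for `"administrative"`; must be `>= time` for competing-event
#'   failures).
#' @param time,status Column names.
#' @return A tibble with columns `V`, `ev1` and `v_imputed` (all 0) appended.
#' @export
make_subdist_time <- function(data, mode = c("no_censoring", "administrative"),
                              admin = NULL, time = "time", status = "status") {
  mode <- match.arg(mode)
  assert_cols(data, c(time, status), "make_subdist_time")
  d <- data[[status]]; t <- data[[time]]
  out <- tibble::as_tibble(data)
  V <- t
  if (mode == "no_censoring") {
    V[d == 2] <- max(t) + 1
  } else {
    if (is.null(admin)) stop_fgmi("administrative mode requires the `admin` column of known censoring times")
    assert_cols(data, admin, "make_subdist_time")
    C <- data[[admin]]
    if (any(d == 2 & (is.na(C) | C < t))) {
      stop_fgmi("administrative censoring time missing or earlier than the event time for a competing-event failure")
    }
    V[d == 2] <- C[d == 2]
  }
  out$V <- V
  out$ev1 <- as.numeric(d == 1)
  out$v_imputed <- 0
  out
}

#' Censoring-distribution model
#'
#' Estimates the survival function of the censoring times, reversing the
#' roles of events and censorings (status = I(D = 0)); the support includes
#' both random and administrative censoring times. Three forms are
#' supported: a marginal Kaplan-Meier curve, Kaplan-Meier curves stratified
#' by fully observed categorical covariates, and a Cox proportional hazards
#' model in fully observed covariates (for continuous predictors of
#' censoring).
#'
#' @param data A data frame with status coded 0/1/2.
#' @param kind `"marginal_km"`, `"stratified_km"` or `"ph_model"`.
#' @param covariates Fully observed covariate columns (strata for
#'   `"stratified_km"`, regressors for `"ph_model"`).
#' @param time,status Column names.
#' @return An object of class `fgmi_censmod`.
#' @export
fit_censoring_model <- function(data, kind = c("marginal_km", "stratified_km", "ph_model"),
                                covariates = character(), time = "time", status = "status") {
  kind <- match.arg(kind)
  assert_cols(data, c(time, status, covariates), "fit_censoring_model")
  cens <- data.frame(time = data[[time]], status = as.numeric(data[[status]] == 0))
  if (!any(cens$status == 1)) {
    stop_fgmi("no censored observations: use make_subdist_time() for fully observed subdistribution times")
  }
  est <- switch(kind,
    marginal_km = km_curve(cens),
    stratified_km = {
      if (!length(covariates)) stop_fgmi("stratified_km requires at least one stratum variable")
      strat <- interaction(data[covariates], drop = TRUE)
      lapply(split(cens, strat), km_curve)
    },
    ph_model = {
      if (!length(covariates)) stop_fgmi("ph_model requires at least one covariate")
      cens[covariates] <- data[covariates]
      fit_ph(cens, covariates = covariates)
    })
  structure(list(kind = kind, covariates = covariates, estimate = est,
                 time = time, status = status, data = tibble::as_tibble(data)),
            class = "fgmi_censmod")
}

#' @export
print.fgmi_censmod <- function(x, ...) {
  cat(sprintf("<fgmi_censmod: %s%s>\n", x$kind,
              if (length(x$covariates)) paste0(" (", paste(x$covariates, collapse = ", "), ")") else ""))
  invisible(x)
}

# KM jump masses of a survival step function; any defective tail mass is
# lumped onto the largest knot.
km_masses <- function(G) {
  k <- G$knots
  left <- c(G$v0, head(G$values, -1))
  mass <- left - G$values
  if (length(mass)) mass[length(mass)] <- mass[length(mass)] + tail(G$values, 1)
  list(knots = k, mass = mass)
}

#' Multiply impute potential censoring times
#'
#' For each of `m` output datasets, every competing-event failure (D = 2)
#' receives a potential censoring time V drawn from the estimated conditional
#' censoring distribution given C > Ti, i.e. with distribution function
#' 1 - G(t-) / G(Ti-) (per stratum or per covariate profile when the
#' censoring model is stratified or a Cox model). Censored subjects and
#' events of interest keep V = T. Each dataset also gets `ev1`, a
#' `v_imputed` flag and the recomputed marginal cumulative subdistribution
#' hazard column `L1_V` (see [add_subdist_hazard()]).
#'
#' Subjects whose Ti lies beyond the largest censoring-support knot get V at
#' that largest knot, treated as administrative (a warning reports the
#' count). With `bootstrap = TRUE` every dataset uses a censoring
#' distribution re-estimated on an independent bootstrap resample, making the
#' imputation proper; the default is off, matching common practice.
#'
#' @param data A data frame with status coded 0/1/2 (same data the model was
#'   fitted on, or compatible).
#' @param model An [fit_censoring_model()] object; if `NULL`, a marginal
#'   Kaplan-Meier model is fitted to `data`.
#' @param m Number of imputed datasets.
#' @param bootstrap Re-estimate the censoring distribution per dataset on a
#'   bootstrap resample.
#' @param seed Optional integer; one independent sub-stream is spawned per
#'   imputed dataset.
#' @param time,status Column names.
#' @return An object of class `fgmi_stack`: a list with `datasets` (list of
#'   `m` tibbles) and `meta`.
#' @export
impute_censoring_times <- function(data, model = NULL, m = 30, bootstrap = FALSE,
                                   seed = NULL, time = "time", status = "status") {
  if (m < 1) stop_fgmi("m must be >= 1")
  if (is.null(model)) model <- fit_censoring_model(data, "marginal_km", time = time, status = status)
  stopifnot(inherits(model, "fgmi_censmod"))
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, m) else spawn_seeds(seed, m)
  d <- data[[status]]; t <- data[[time]]
  idx2 <- which(d == 2)
  base <- make_skeleton_ccd(data, time, status)
  n_tail <- 0L
  datasets <- vector("list", m)
  for (j in seq_len(m)) {
    set.seed(seeds[j])
    mod <- model
    if (bootstrap) {
      b <- sample.int(nrow(model$data), replace = TRUE)
      mod <- fit_censoring_model(model$data[b, , drop = FALSE], model$kind,
                                 model$covariates, time = time, status = status)
    }
    V <- base$V
    if (length(idx2)) {
      # tail-rule draws may land at the largest knot, which can be <= Ti for
      # the affected subjects; those values are administrative by convention
      draws <- draw_censoring(mod, data, idx2, time)
      n_tail <- n_tail + attr(draws, "n_tail")
      V[idx2] <- draws
    }
    dj <- base
    dj$V <- V
    dj$v_imputed <- as.numeric(seq_len(nrow(dj)) %in% idx2)
    datasets[[j]] <- add_subdist_hazard(dj)
  }
  if (n_tail > 0) {
    warning(sprintf("%d imputed censoring time(s) fell beyond the censoring support; set to the largest support knot (administrative tail rule)", n_tail),
            call. = FALSE)
  }
  new_fgmi_stack(datasets, meta = list(m = m, seeds = seeds, kind = "censoring",
                                       censoring_model = model$kind,
                                       bootstrap = bootstrap, n_tail = n_tail))
}

make_skeleton_ccd <- function(data, time, status) {
  out <- tibble::as_tibble(data)
  out$V <- data[[time]]
  out$ev1 <- as.numeric(data[[status]] == 1)
  out$v_imputed <- 0
  out
}

draw_censoring <- function(model, data, idx2, time) {
  t2 <- data[[time]][idx2]
  out <- numeric(length(idx2))
  n_tail <- 0L
  if (model$kind %in% c("marginal_km", "stratified_km")) {
    if (model$kind == "marginal_km") {
      grp <- rep(1L, length(idx2))
      curves <- list(model$estimate)
    } else {
      strat_all <- interaction(data[model$covariates], drop = TRUE)
      grp <- as.integer(strat_all[idx2])
      curves <- vector("list", nlevels(strat_all))
      curves[match(names(model$estimate), levels(strat_all))] <- model$estimate
    }
    u_all <- runif(length(idx2))
    for (g in unique(grp)) {
      G <- curves[[g]]
      if (is.null(G)) stop_fgmi("no censoring estimate available for a stratum")
      sel <- which(grp == g)
      ti <- t2[sel]
      if (any(step_eval(G, ti, left = TRUE) <= 0)) {
        stop_fgmi("estimated censoring survival is 0 at a competing-event failure time; conditional distribution undefined")
      }
      km <- km_masses(G)
      cm <- cumsum(km$mass)
      tot <- cm[length(cm)]
      # conditional mass lives on knots strictly greater than ti
      lower <- c(0, cm)[findInterval(ti, km$knots) + 1L]
      ok <- lower < tot - 1e-15
      v <- rep(NA_real_, length(sel))
      if (any(ok)) {
        uu <- lower[ok] + u_all[sel][ok] * (tot - lower[ok])
        v[ok] <- km$knots[findInterval(uu, cm, left.open = TRUE) + 1L]
      }
      if (any(!ok)) {
        v[!ok] <- max(km$knots)
        n_tail <- n_tail + sum(!ok)
      }
      out[sel] <- v
    }
  } else {
    fit <- model$estimate
    knots <- fit$baseline$knots
    if (!length(knots)) stop_fgmi("censoring Cox model has no censoring events")
    H0 <- fit$baseline$values
    lp <- drop(as.matrix(data[idx2, model$covariates, drop = FALSE]) %*% unname(fit$coefficients))
    for (i in seq_along(idx2)) {
      S <- exp(-H0 * exp(lp[i]))                 # subject-specific censoring survival at knots
      Sti <- {                                    # S(Ti) conditions on C > Ti (strict)
        k <- findInterval(t2[i], knots)
        if (k == 0) 1 else S[k]
      }
      if (Sti <= 0) stop_fgmi("estimated censoring survival is 0 at a competing-event failure time")
      u <- runif(1, 0, Sti)
      elig <- which(knots > t2[i] & S <= u)
      if (!length(elig)) {
        if (any(knots > t2[i])) {
          out[i] <- max(knots)                   # defective tail: administrative at last knot
          n_tail <- n_tail + 1L
        } else {
          out[i] <- max(knots); n_tail <- n_tail + 1L
        }
      } else {
        out[i] <- knots[min(elig)]
      }
    }
  }
  structure(out, n_tail = n_tail)
}

#' Add the marginal cumulative subdistribution hazard
#'
#' Appends `L1_V`: the Nelson-Aalen estimate based on (V, ev1), evaluated at
#' each subject's own subdistribution time. This is the outcome summary the
#' approximately compatible Fine-Gray imputation model requires; it must be
#' recomputed within each censoring-complete dataset because V differs
#' between them.
#'
#' @param data A data frame containing `V` and `ev1`.
#' @return The input as a tibble with `L1_V` appended.
#' @export
add_subdist_hazard <- function(data) {
  assert_cols(data, c("V", "ev1"), "add_subdist_hazard (run make_subdist_time() or impute_censoring_times() first)")
  out <- tibble::as_tibble(data)
  if (!any(data$ev1 == 1)) {
    warning("no events of interest: L1_V set to 0", call. = FALSE)
    out$L1_V <- 0
    return(out)
  }
  L1 <- na_curve(data.frame(time = data$V, status = data$ev1))
  out$L1_V <- step_eval(L1, data$V)
  out
}

new_fgmi_stack <- function(datasets, meta) {
  structure(list(datasets = datasets, meta = meta), class = "fgmi_stack")
}

#' @export
print.fgmi_stack <- function(x, ...) {
  cat(sprintf("<fgmi_stack: %d dataset(s), kind = %s>\n",
              length(x$datasets), x$meta$kind %||% "?"))
  invisible(x)
}

#' @export
length.fgmi_stack <- function(x) length(x$datasets)
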