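# small in-code fixtures shared across test files

toy_surv <- function() {
  tibble::tibble(time = c(1, 2, 3), status = c(0, 1, 0))
}

# competing risks sample with both causes and censoring, deterministic
toy_cr <- function() {
  tibble::tibble(time = c(1, 2, 3, 0.5, 4),
                 status = c(1, 2, 0, 1, 2),
                 X = c(1, 0, 1, NA, 0),
                 Z = c(0.2, -0.1, 1.3, 0.4, -0.7))
}

# hand-built proportional-hazards fit with a single baseline jump of `jump`
# at time 1 (cumulative hazard = jump from t = 1 on) and one covariate
manual_ph <- function(beta, jump = 1, name = "X") {
  structure(list(
    coefficients = stats::setNames(beta, name),
    vcov = matrix(0, 1, 1),
    baseline = fg_stepfun(1, jump, v0 = 0, type = "cumhaz"),
    baseline_jumps = jump,
    covariate_names = name,
    n_events = 1,
    sample = list(time = 1, status = 1, X = matrix(1, 1, 1, dimnames = list(NULL, name)),
                  weights = 1),
    drawn = FALSE), class = "fgmi_ph")
}

# censoring-complete data from the proportional-subdistribution-hazards
# generator without censoring, with MAR-on-Z missingness in X
fixture_ccd <- function(n = 600, p = 0.15, seed = 99, missing = TRUE) {
  set.seed(seed)
  d <- gen_fg_correct(n, fg_correct_params(p = p))
  if (missing) d <- induce_missingness(d, missingness_spec("mar_z"))
  d <- attach_cause_specific_hazards(d)
  add_subdist_hazard(make_subdist_time(d, "no_censoring"))
}

# Breslow partial log likelihood for a single covariate, written out directly
breslow_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (tt in sort(unique(time[status == 1]))) {
    ev <- which(time == tt & status == 1)
    rs <- which(time >= tt)
    ll <- ll + sum(beta * x[ev]) - length(ev) * log(sum(exp(beta * x[rs])))
  }
  ll
}
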