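test_that("the subdistribution outcome density matches hand evaluation", {
  fit <- manual_ph(beta = log(2), jump = 1)   # Lambda01 jumps to 1 at t = 1
  # censored-type rows before the first jump contribute 1 for every x
  expect_equal(outcome_density_fg(c(0.5, 0.5), c(0, 0), cbind(X = c(0, 1)), fit),
               c(1, 1))
  # null coefficients: factor exp(-Lambda01(V)) independent of x
  fit0 <- manual_ph(beta = 0, jump = 1)
  expect_equal(outcome_density_fg(c(2, 2), c(0, 0), cbind(X = c(0, 1)), fit0),
               rep(exp(-1), 2))
  # event row at Lambda01 = 1 with beta = log 2: f(x=1)/f(x=0) = 2 exp(-2)/exp(-1)
  dens <- outcome_density_fg(c(1, 1), c(1, 1), cbind(X = c(1, 0)), fit)
  expect_equal(dens[1] / dens[2], 2 * exp(-2) / exp(-1), tolerance = 1e-12)
})

test_that("the cause-specific outcome density matches hand evaluation", {
  f1 <- manual_ph(beta = log(2), jump = 1)
  f2 <- manual_ph(beta = 0.3, jump = 0.5)
  # censored row before any jumps: 1 for every x
  expect_equal(outcome_density_cs(0.5, 0, cbind(X = 1), f1, f2), 1)
  # null coefficients in both models: independent of x
  d0 <- outcome_density_cs(c(2, 2), c(0, 0), cbind(X = c(0, 1)),
                           manual_ph(0, 1), manual_ph(0, 0.5))
  expect_equal(d0[1], d0[2])
  # cause-1 event at t = 1: jump1 e^{b1 x} exp(-e^{b1 x} - 0.5 e^{0.3 x})
  hand <- function(x) 1 * 2^x * exp(-(2^x) - 0.5 * exp(0.3 * x))
  dens <- outcome_density_cs(c(1, 1), c(1, 1), cbind(X = c(1, 0)), f1, f2)
  expect_equal(dens[1] / dens[2], hand(1) / hand(0), tolerance = 1e-12)
})

test_that("direct discrete sampling uses the normalized product density", {
  # prior 1/2 and outcome ratio 2/e: P(X = 1) = (2/e) / (1 + 2/e)
  dens <- matrix(c(exp(-1), 2 * exp(-2)), 1)
  prior <- matrix(c(0.5, 0.5), 1)
  s <- smc_sample_discrete(dens, prior, c(0, 1))
  r <- 2 / exp(1)
  expect_equal(s$probs[1, 2], r / (1 + r), tolerance = 1e-12)
  expect_equal(s$probs[1, 2], 0.4239, tolerance = 1e-4)
  # flat outcome density: sampling distribution equals the covariate model
  s2 <- smc_sample_discrete(matrix(1, 3, 2), cbind(c(.2, .5, .9), c(.8, .5, .1)),
                            c(0, 1))
  expect_equal(s2$probs, cbind(c(.2, .5, .9), c(.8, .5, .1)))
  # degenerate prior always imputes the supported level
  set.seed(1)
  s3 <- smc_sample_discrete(matrix(c(.3, .7), 1), matrix(c(0, 1), 1), c(0, 1))
  expect_equal(s3$values, 1)
  expect_error(smc_sample_discrete(matrix(0, 1, 2), matrix(c(.5, .5), 1), c(0, 1)),
               "vanished")
})

test_that("rejection sampling reproduces the quadrature-normalized product density", {
  set.seed(101)
  # proposal N(0,1), outcome factor exp(-e^x) (censored-type row, Lambda = 1)
  propose <- function(idx) rnorm(length(idx))
  density <- function(vals, idx) exp(-exp(vals))
  n <- 10000
  smp <- smc_sample_continuous(propose, density, n)
  expect_equal(smp$n_fallback, 0)
  expect_true(smp$acceptance_rate > 0 && smp$acceptance_rate <= 1)
  grid <- seq(-6, 6, length.out = 4001)
  dens <- stats::dnorm(grid) * exp(-exp(grid))
  cdf <- cumsum(dens) / sum(dens)
  oracle_cdf <- stats::approxfun(grid, cdf, yleft = 0, yright = 1)
  ks <- max(abs(seq_len(n) / n - oracle_cdf(sort(smp$values))))
  expect_lt(ks, 0.02)
  # flat outcome density: the output is distributed exactly as the proposal
  set.seed(102)
  smp2 <- smc_sample_continuous(propose, function(v, i) rep(1, length(v)), n)
  ks2 <- suppressWarnings(stats::ks.test(smp2$values, stats::pnorm))
  expect_gt(ks2$p.value, 0.01)
})

test_that("chained SMC imputation preserves observed data and is reproducible", {
  cc <- fixture_ccd(n = 400)
  xmod <- list(cov_model("X", "logistic", "Z"))
  st <- run_smcfcs(cc, "fine_gray", c("X", "Z"), xmod, m = 3, iterations = 5, seed = 4)
  expect_length(st, 3)
  obs <- !is.na(cc$X)
  for (dd in st$datasets) {
    expect_false(anyNA(dd$X))
    expect_identical(dd$X[obs], cc$X[obs])
    expect_identical(dd[setdiff(names(dd), "X")], cc[setdiff(names(cc), "X")])
    expect_true(all(dd$X[!obs] %in% c(0, 1)))
  }
  st2 <- run_smcfcs(cc, "fine_gray", c("X", "Z"), xmod, m = 3, iterations = 5, seed = 4)
  expect_identical(st$datasets, st2$datasets)
  # no missing cells: identity for any m
  full <- fixture_ccd(n = 200, missing = FALSE)
  st3 <- run_smcfcs(full, "fine_gray", c("X", "Z"), xmod, m = 2, iterations = 3)
  expect_identical(st3$datasets, list(full, full))
})

test_that("cause-specific SMC degenerates to the subdistribution form without competing events", {
  set.seed(52)
  d <- tibble::tibble(time = rexp(300), status = rbinom(300, 1, 0.7),
                      Z = rnorm(300))
  d$X <- rbinom(300, 1, expit(d$Z))
  d$X[sample(300, 100)] <- NA
  cc <- d
  cc$V <- cc$time
  cc$ev1 <- as.numeric(cc$status == 1)
  xmod <- list(cov_model("X", "logistic", "Z"))
  a <- run_smcfcs(cc, "fine_gray", c("X", "Z"), xmod, m = 2, iterations = 4, seed = 9)
  b <- run_smcfcs(cc, "cause_specific", c("X", "Z"), xmod, m = 2, iterations = 4, seed = 9)
  expect_identical(lapply(a$datasets, `[[`, "X"), lapply(b$datasets, `[[`, "X"))
})

test_that("a null substantive coefficient reduces SMC to plain covariate-model imputation", {
  # when the outcome carries no information on X (beta for X = 0 in the DGM,
  # huge sample for the substantive fit), the sampling distribution of imputed
  # X approaches the covariate model f(X | Z)
  set.seed(71)
  d <- gen_fg_correct(3000, fg_correct_params(p = 0.3, beta1 = 0, beta1_star = 0))
  d$X[sample(3000, 1200)] <- NA
  cc <- add_subdist_hazard(make_subdist_time(d, "no_censoring"))
  st <- run_smcfcs(cc, "fine_gray", c("X", "Z"), list(cov_model("X", "logistic", "Z")),
                   m = 1, iterations = 10, seed = 8)
  imp <- st$datasets[[1]]
  mis <- is.na(d$X)
  # compare imputed rate to the true conditional rate expit(Z) on missing rows
  expect_lt(abs(mean(imp$X[mis]) - mean(expit(d$Z[mis]))),
            3 * sqrt(0.25 / sum(mis)) + 0.02)
})
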