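#' @importFrom stats coef vcov rnorm runif rbinom rexp rchisq plogis qlogis
#'   uniroot integrate dnorm glm binomial lm predict quantile sd var qt
#'   pnorm model.matrix setNames complete.cases
#' @importFrom utils head tail
NULL

expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent sub-seeds from one root seed
#'
#' Deterministically spawns `n` seeds (each below 2^31) from a root seed, so
#' that parallel units (imputed datasets, simulation replicates) get
#' reproducible, effectively independent RNG streams.
#'
#' @param seed Integer root seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
spawn_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stop_fgmi <- function(...) stop(..., call. = FALSE)

assert_cols <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop_fgmi(sprintf("column(s) %s required by %s are missing; run the prerequisite step first",
                      paste0("'", miss, "'", collapse = ", "), where))
  }
}

# nearest positive-semidefinite repair by eigenvalue clamping
nearest_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (all(e$values >= -1e-12)) return((V + t(V)) / 2)
  warning("covariance matrix not positive semi-definite; clamping negative eigenvalues", call. = FALSE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (vals * t(e$vectors))
}

mvn_draw <- function(mean, V) {
  if (!length(mean)) return(mean)
  drop(MASS::mvrnorm(1L, mu = mean, Sigma = nearest_psd(V)))
}
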