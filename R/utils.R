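# Internal helpers shared across modules: seed fan-out, argument checks,
# fold assignment, and matrix coercion for the tibble-first user API.

#' Derive a child seed from a master seed and a component name
#'
#' Every stochastic component (generator, fold shuffles, CARS Monte-Carlo
#' draws, MI jitter) draws its own seed from the master seed via a stable
#' string hash, so adding or removing one component never perturbs the
#' random stream of another.
#'
#' @param master Integer master seed.
#' @param name Character scalar naming the component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' fanout_seed(42, "cv_folds")
fanout_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((h + (as.numeric(master) %% m) * 2654435761) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Seeded assignment of n samples to `folds` cross-validation folds of
# near-equal size (shuffled round-robin).
assign_folds <- function(n, folds, seed) {
  stopifnot(n >= folds)
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

check_matrix <- function(X, arg = "X") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) abort(sprintf("`%s` must be a numeric matrix.", arg))
  if (!all(is.finite(X))) abort(sprintf("`%s` contains non-finite values.", arg))
  X
}

# Minimum-norm least-squares solve via SVD pseudoinverse: returns the
# shortest coefficient vector minimizing ||A b - y||. Handles rank-deficient
# and underdetermined systems (p > n).
pinv_solve <- function(A, y, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(rep(0, ncol(A)))
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% y))
}
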