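# Internal helpers shared across modules.

#' @useDynLib brainstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x))
    stopf("`%s` must be a single integer", name)
  if (!is.null(min) && x < min)
    stopf("`%s` must be >= %s (got %s)", name, min, x)
  as.integer(x)
}

# Row-stochastic check used by several preconditions.
check_transition <- function(A, tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A))
    stopf("transition matrix must be a square numeric matrix")
  if (any(!is.finite(A)) || any(A < -tol) || any(A > 1 + tol))
    stopf("transition entries must lie in [0, 1]")
  rs <- rowSums(A)
  if (any(abs(rs - 1) > tol))
    stopf("transition rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1)))
  invisible(A)
}

check_prob_vector <- function(p, tol = 1e-8, name = "probability vector") {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol)
    stopf("`%s` must be non-negative and sum to 1", name)
  invisible(p)
}

# Cholesky with an informative error; used wherever SPD is a precondition.
chol_spd <- function(S, context = "covariance") {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out))
    stopf("%s matrix is not symmetric positive definite", context)
  out
}

log_mvnorm <- function(X, mean, cov) {
  # Rowwise log N(x; mean, cov) for an n x R matrix X.
  U <- chol_spd(cov)
  Xc <- sweep(X, 2L, mean, "-")
  Z <- backsolve(U, t(Xc), transpose = TRUE)  # solves U' z = (x - m)'
  quad <- colSums(Z^2)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(U))) + quad)
}

# log multivariate gamma function, dimension p
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}
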