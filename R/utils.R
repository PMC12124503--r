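#' @import data.table
#' @importFrom stats pnorm qnorm dnorm optimize optim rnorm runif rbinom
#'   pchisq setNames glm binomial coef quantile sd var
#' @importFrom utils modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

#' Check that a matrix is a valid correlation matrix
#'
#' Symmetric, unit diagonal, entries in \[-1, 1\] and positive definite up
#' to `tol`.
#'
#' @param m numeric matrix.
#' @param tol smallest admissible eigenvalue.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @keywords internal
check_corr_matrix <- function(m, tol = 1e-8) {
  name <- deparse(substitute(m))
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("'%s' must be a square matrix", name)
  if (max(abs(m - t(m))) > 1e-10)
    stopf("'%s' must be symmetric", name)
  if (max(abs(diag(m) - 1)) > 1e-10)
    stopf("'%s' must have unit diagonal", name)
  if (any(abs(m) > 1 + 1e-10))
    stopf("'%s' must have entries in [-1, 1]", name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < tol)
    stopf("'%s' is not positive definite (min eigenvalue %.3g)", name, min(ev))
  invisible(TRUE)
}

# Gauss-Legendre nodes/weights on [-1, 1], computed once (Golub-Welsch).
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
    cache[[key]] <<- out
    out
  }
})

#' Standard bivariate normal CDF
#'
#' `pbvn(h, k, rho)` returns `P(X <= h, Y <= k)` for standard bivariate
#' normal `(X, Y)` with correlation `rho`, via the tetrachoric integral
#' `Phi(h)Phi(k) + (2*pi)^-1 * int_0^rho phi2(h, k, r) dr` evaluated with
#' 64-point Gauss-Legendre quadrature.  Vectorised over `rho` (scalar
#' `h`, `k`).
#'
#' @param h,k upper limits.
#' @param rho correlation(s), each in (-1, 1).
#' @return vector of probabilities, same length as `rho`.
#' @examples
#' pbvn(0, 0, 0.6) - (0.25 + asin(0.6) / (2 * pi)) # ~0
#' @export
pbvn <- function(h, k, rho) {
  stopifnot(length(h) == 1L, length(k) == 1L)
  if (any(abs(rho) >= 1)) stopf("'rho' must lie strictly in (-1, 1)")
  gl <- gauss_legendre(64L)
  base <- pnorm(h) * pnorm(k)
  out <- numeric(length(rho))
  for (i in seq_along(rho)) {
    r <- rho[i]
    if (r == 0) { out[i] <- base; next }
    # map [-1,1] -> [0, r]
    t <- r / 2 * (gl$nodes + 1)
    f <- exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) / sqrt(1 - t^2)
    out[i] <- base + (r / 2) * sum(gl$weights * f) / (2 * pi)
  }
  pmin(pmax(out, 0), 1)
}

# nearest-PSD repair by eigenvalue clipping; keeps unit diagonal
psd_repair <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(mat = m, repaired = FALSE))
  v <- pmax(e$values, eps)
  r <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  list(mat = r, repaired = TRUE)
}

# deterministic child seed derived from a user seed, kept < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483647)
}
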