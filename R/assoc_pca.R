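#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate under the bivariate-normal threshold
#' model: the thresholds are fixed at the normal quantiles of the
#' margins and the latent correlation maximises the multinomial
#' likelihood of the four cells, with the bivariate CDF evaluated by
#' [pbvn] and the search bounded in (-0.999, 0.999).
#'
#' @param tab 2x2 matrix of non-negative counts; rows index the first
#'   variable (0 then 1), columns the second.
#' @return the estimate, with attribute `boundary = TRUE` when an empty
#'   cell pushes it to the search bound; `NA` (with a warning) when a
#'   margin is zero.
#' @examples
#' tetrachoric_pair(matrix(c(40, 10, 10, 40), 2)) # strong positive
#' @export
tetrachoric_pair <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0))
    stopf("'tab' must be a 2x2 matrix of non-negative counts")
  n <- sum(tab)
  rm_ <- rowSums(tab); cm_ <- colSums(tab)
  if (any(rm_ == 0) || any(cm_ == 0)) {
    warnf("zero margin: tetrachoric correlation undefined")
    return(NA_real_)
  }
  # thresholds: latent X > h  <=>  x = 1
  h <- qnorm(rm_[1] / n)
  k <- qnorm(cm_[1] / n)
  loglik <- function(rho) {
    p00 <- pbvn(h, k, rho)
    p0x <- pnorm(h); px0 <- pnorm(k)
    p <- c(p00, p0x - p00, px0 - p00, 1 - p0x - px0 + p00)
    p <- pmax(p, 1e-12)
    sum(as.vector(t(tab)) * log(p)) # order: (0,0),(0,1),(1,0),(1,1)
  }
  opt <- optimize(loglik, c(-0.999, 0.999), maximum = TRUE, tol = 1e-7)
  est <- opt$maximum
  if (any(tab == 0) && abs(est) > 0.985) attr(est, "boundary") <- TRUE
  est
}

#' Tetrachoric correlation matrix
#'
#' Pairwise [tetrachoric_pair] over the binary columns of a table, with
#' nearest-positive-semidefinite repair (eigenvalue clipping at 1e-8)
#' when the pairwise matrix is not PSD; the repair is flagged in the
#' `repaired` attribute.
#'
#' @param data data.frame/matrix of 0/1 columns.
#' @return correlation matrix with attributes `method = "tetrachoric"`
#'   and `repaired`.
#' @export
tetrachoric_matrix <- function(data) {
  m <- as.matrix(data)
  if (!all(m %in% c(0, 1, NA)))
    stopf("all columns must be binary (0/1)")
  p <- ncol(m)
  out <- diag(p)
  dimnames(out) <- list(colnames(m), colnames(m))
  if (p > 1) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      tab <- table(factor(m[ok, i], levels = 0:1),
                   factor(m[ok, j], levels = 0:1))
      r <- tetrachoric_pair(tab)
      out[i, j] <- out[j, i] <- as.numeric(r)
    }
  }
  rep_ <- FALSE
  if (!anyNA(out)) {
    fixed <- psd_repair(out)
    out <- fixed$mat
    rep_ <- fixed$repaired
    dimnames(out) <- list(colnames(m), colnames(m))
  }
  attr(out, "method") <- "tetrachoric"
  attr(out, "repaired") <- rep_
  out
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries,
#' where `q` are the anti-image partial correlations computed from the
#' inverse correlation matrix.  Values near 1 indicate the correlation
#' structure is suitable for factoring.
#'
#' @param corr correlation matrix (invertible; apply PSD repair first if
#'   necessary).
#' @return list with `overall` and per-variable `msa` (all in \[0, 1\]).
#' @export
kmo <- function(corr) {
  corr <- as.matrix(corr)
  inv <- tryCatch(solve(corr),
                  error = function(e)
                    stopf("correlation matrix is singular; apply PSD repair"))
  d <- 1 / sqrt(diag(inv))
  q <- -inv * tcrossprod(d)   # partial correlations
  diag(q) <- 0
  r <- corr; diag(r) <- 0
  overall <- sum(r^2) / (sum(r^2) + sum(q^2))
  msa <- colSums(r^2) / (colSums(r^2) + colSums(q^2))
  names(msa) <- colnames(corr)
  list(overall = overall, msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * log det(R)` with `p(p-1)/2` degrees
#' of freedom.
#'
#' @param corr correlation matrix.
#' @param n number of observations (`n > p`).
#' @return list `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(corr, n) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n <= p) stopf("'n' must exceed the number of variables")
  dt <- determinant(corr, logarithm = TRUE)
  if (dt$sign <= 0) stopf("correlation matrix must be positive definite")
  stat <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(dt$modulus)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Principal component analysis of a correlation matrix
#'
#' Eigendecomposition with components ordered by eigenvalue.  Loadings
#' carry the sign convention that the largest-magnitude entry of each
#' eigenvector is positive.  Per-variable contributions to a component
#' are `100 * loading^2` (summing to 100 within each component).  The
#' retained set defaults to the elbow heuristic - the components before
#' the largest successive eigenvalue drop - and can be overridden.
#'
#' @param corr correlation matrix (or binary/numeric data from which a
#'   Pearson correlation is taken).
#' @param n_keep optional number of components to retain.
#' @return object of class `pca_result`: `eigenvalues`, `loadings`,
#'   `percent_variance`, `contributions` (variables x components),
#'   `retained`.
#' @export
pca_corr <- function(corr, n_keep = NULL) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(diag(corr) - 1)) > 1e-8)
    corr <- stats::cor(corr)
  p <- ncol(corr)
  if (is.null(colnames(corr)))
    colnames(corr) <- rownames(corr) <- paste0("V", seq_len(p))
  e <- eigen(corr, symmetric = TRUE)
  vecs <- e$vectors
  for (j in seq_len(p))
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  rownames(vecs) <- colnames(corr)
  colnames(vecs) <- paste0("PC", seq_len(p))
  contrib <- 100 * vecs^2
  if (is.null(n_keep)) {
    n_keep <- if (p == 1) 1L else which.max(-diff(e$values))
  }
  n_keep <- max(1L, min(as.integer(n_keep), p))
  structure(list(
    eigenvalues = e$values, loadings = vecs,
    percent_variance = 100 * e$values / p,
    contributions = contrib, retained = seq_len(n_keep)),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of correlation matrix\n")
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                              collapse = " "), "\n")
  cat("  retained components:", length(x$retained), "\n")
  invisible(x)
}

#' Select variables from a PCA by contribution
#'
#' Default rule: variables whose average contribution across the
#' retained components exceeds the uniform expectation `100 / p`
#' percent, returned in decreasing contribution order.
#'
#' @param pca a [pca_corr] result.
#' @param threshold contribution cutoff in percent (default `100 / p`).
#' @return character vector of selected variables (possibly empty).
#' @export
select_features <- function(pca, threshold = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  p <- length(pca$eigenvalues)
  threshold <- threshold %||% (100 / p)
  avg <- rowMeans(pca$contributions[, pca$retained, drop = FALSE])
  sel <- avg[avg > threshold + 1e-12]
  names(sort(sel, decreasing = TRUE))
}
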