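#' Biweight midcorrelation
#'
#' Robust correlation used throughout the network stage. Each variable is
#' centered at its median and scaled by nine times its (unscaled) median
#' absolute deviation; observations get Tukey biweights
#' `w = (1 - u^2)^2` for `|u| < 1` and 0 beyond. With `max_p_outliers < 1`
#' each side of `u` is rescaled so that at most that fraction of
#' observations per side can receive zero weight (the quantile at
#' `max_p_outliers` is mapped back to +/-1 when it falls outside). A
#' variable with zero MAD falls back to Pearson weighting (mean-centered,
#' unit weights) so the correlation is defined for constant-tailed vectors.
#'
#' `bicor_matrix` computes all pairwise correlations between the rows of a
#' matrix using pairwise-complete observations; entries with fewer than
#' `min_shared` shared observations are set to 0 (no evidence of
#' association). Rows with fewer than 4 observations overall are excluded
#' with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @param matrix Variables x observations numeric matrix (`NA` allowed).
#' @param max_p_outliers Maximum fraction of observations allowed to be
#'   treated as outliers on each side (default 0.05, the network default).
#' @param min_shared Minimum pairwise-complete observations per entry.
#' @return `bicor` returns a scalar in `[-1, 1]`; `bicor_matrix` a symmetric
#'   correlation matrix with unit diagonal.
#' @export
bicor <- function(x, y, max_p_outliers = 1) {
  stopifnot(length(x) == length(y))
  m <- bicor_matrix(rbind(x = x, y = y), max_p_outliers = max_p_outliers,
                    min_shared = 3L)
  m["x", "y"]
}

#' @rdname bicor
#' @export
bicor_matrix <- function(matrix, max_p_outliers = 0.05, min_shared = 4L) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 4 || min_shared < 4)
  n_obs <- rowSums(!is.na(matrix))
  if (any(n_obs < min_shared)) {
    warning(sum(n_obs < min_shared),
            " row(s) with fewer than ", min_shared,
            " observations excluded from bicor matrix")
    matrix <- matrix[n_obs >= min_shared, , drop = FALSE]
  }
  tr <- .transform_rows(matrix, max_p_outliers)
  r <- .weighted_cor(tr$A, tr$A, tr$M, tr$M, min_shared)
  if (any(tr$fallback)) {
    # a zero-MAD row makes its pairs Pearson on both sides
    trp <- .transform_rows(matrix, max_p_outliers, pearson = TRUE)
    rp <- .weighted_cor(trp$A, trp$A, trp$M, trp$M, min_shared)
    fb <- tr$fallback
    r[fb, ] <- rp[fb, ]
    r[, fb] <- rp[, fb]
  }
  diag(r) <- 1
  dimnames(r) <- list(rownames(matrix), rownames(matrix))
  r
}

# Biweight (or Pearson) transform of every row plus the observation mask.
.transform_rows <- function(matrix, max_p_outliers, pearson = FALSE) {
  fallback <- logical(nrow(matrix))
  A <- matrix
  for (i in seq_len(nrow(matrix))) {
    ti <- .bicor_transform(matrix[i, ], max_p_outliers, pearson = pearson)
    A[i, ] <- ti
    fallback[i] <- isTRUE(attr(ti, "fallback"))
  }
  M <- (!is.na(matrix)) * 1
  A[is.na(A)] <- 0
  list(A = A, M = M, fallback = fallback)
}

# Pairwise-complete normalized cross-products of transformed rows.
.weighted_cor <- function(AX, AY, MX, MY, min_shared) {
  num <- AX %*% t(AY)
  dx <- (AX^2) %*% t(MY)
  dy <- MX %*% t(AY^2)
  r <- num / sqrt(dx * dy)
  r[!is.finite(r)] <- 0
  shared <- MX %*% t(MY)
  r[shared < min_shared] <- 0
  pmin(pmax(r, -1), 1)
}

# Median/MAD biweight transform of one variable; Pearson fallback at MAD 0.
.bicor_transform <- function(x, max_p_outliers, pearson = FALSE) {
  obs <- !is.na(x)
  v <- x[obs]
  med <- stats::median(v)
  madv <- stats::mad(v, constant = 1)
  out <- rep(NA_real_, length(x))
  if (madv == 0 || pearson) {
    out[obs] <- v - mean(v)
    attr(out, "fallback") <- madv == 0
    return(out)
  }
  u <- (v - med) / (9 * madv)
  if (max_p_outliers < 0.5) {
    ql <- stats::quantile(u, probs = max_p_outliers, names = FALSE)
    qu <- stats::quantile(u, probs = 1 - max_p_outliers, names = FALSE)
    if (ql < -1) u[u < 0] <- u[u < 0] / abs(ql)
    if (qu > 1) u[u > 0] <- u[u > 0] / qu
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  out[obs] <- (v - med) * w
  out
}

#' @rdname bicor
#' @param X,Y Matrices with variables in rows and the same observation
#'   columns; `bicor_cross` returns the `nrow(X) x nrow(Y)` matrix of
#'   pairwise biweight midcorrelations.
#' @export
bicor_cross <- function(X, Y, max_p_outliers = 0.05, min_shared = 4L) {
  stopifnot(ncol(X) == ncol(Y))
  tx <- .transform_rows(X, max_p_outliers)
  ty <- .transform_rows(Y, max_p_outliers)
  r <- .weighted_cor(tx$A, ty$A, tx$M, ty$M, min_shared)
  if (any(tx$fallback) || any(ty$fallback)) {
    txp <- .transform_rows(X, max_p_outliers, pearson = TRUE)
    typ <- .transform_rows(Y, max_p_outliers, pearson = TRUE)
    rp <- .weighted_cor(txp$A, typ$A, txp$M, typ$M, min_shared)
    r[tx$fallback, ] <- rp[tx$fallback, ]
    r[, ty$fallback] <- rp[, ty$fallback]
  }
  dimnames(r) <- list(rownames(X), rownames(Y))
  r
}

#' Correlation p-value by the Student-t transform
#'
#' Two-sided p-value for a correlation `r` on `n` observations via
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param r Correlation value(s).
#' @param n Number of observations.
#' @return Two-sided p-value(s).
#' @export
cor_p_value <- function(r, n) {
  if (any(n < 3)) return(rep(NA_real_, length(r)))
  r2 <- pmin(r^2, 1 - 1e-15)
  t_stat <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
}
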