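#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-aware Spearman correlation: the Pearson correlation of mid-ranks,
#' with a two-sided p-value from the t-approximation on `n - 2` degrees
#' of freedom. The t-approximation (rather than exact permutation) is the
#' standard choice at the cohort sizes this package targets (n around
#' 120); mid-ranks are essential because fiber counts contain many tied
#' zeros. A constant input yields an undefined correlation (`NA`);
#' screening treats such edges as unselected.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with missing
#'   values are dropped.
#' @return list with `rho`, `p` and `n` (pairs used); `rho` and `p` are
#'   `NA` when either input is constant.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  list(rho = rho, p = spearman_t_pvalue(rho, n), n = n)
}

# two-sided p for Spearman rho via the t-approximation, n - 2 df
spearman_t_pvalue <- function(rho, n) {
  r2 <- pmin(1, rho^2)
  tval <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  ifelse(r2 >= 1, 0, 2 * pt(tval, df = n - 2, lower.tail = FALSE))
}

# critical |rho| such that the two-sided t-approximation p equals alpha;
# p < alpha is equivalent to |rho| > this threshold (strict on both sides)
spearman_rho_crit <- function(n, alpha) {
  df <- n - 2
  tc <- qt(1 - alpha / 2, df)
  tc / sqrt(df + tc^2)
}

# mid-ranks of every column of a matrix, vectorized via one radix sort
col_midranks <- function(X) {
  n <- nrow(X); p <- ncol(X)
  colid <- rep(seq_len(p), each = n)
  o <- order(colid, X, method = "radix")
  xs <- X[o]
  np <- n * p
  new_run <- c(TRUE, xs[-1L] != xs[-np]) | c(TRUE, diff(colid) > 0L)
  idx <- which(new_run)
  runlen <- diff(c(idx, np + 1L))
  pos_sorted <- rep(seq_len(n), p)
  mid <- pos_sorted[idx] + (runlen - 1) / 2
  R <- numeric(np)
  R[o] <- rep(mid, runlen)
  dim(R) <- c(n, p)
  R
}

# Spearman rho of one score vector (or several columns) against every
# column of an edge matrix; returns a (score columns) x (edges) matrix.
# Edge columns with constant values give NA.
spearman_rho_matrix <- function(edge_ranks, score_matrix) {
  n <- nrow(edge_ranks)
  rbar <- (n + 1) / 2
  ss <- colSums(edge_ranks^2) - n * rbar^2
  sd_e <- sqrt(ss / (n - 1))
  SY <- apply(score_matrix, 2, rank)
  SY <- scale(SY)                      # constant scores -> NaN column
  # SY columns have mean 0, so centering the edge ranks is unnecessary
  rho <- crossprod(SY, edge_ranks) / (n - 1)
  rho <- sweep(rho, 2, sd_e, "/")
  rho[, sd_e == 0] <- NA_real_
  rho
}
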