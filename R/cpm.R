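#' Edge-wise Spearman screening
#'
#' Step (i) of the CPM protocol: every unique edge's fiber counts are
#' correlated with the cognitive score using tie-aware Spearman
#' correlation, and edges with a two-sided p below `alpha` are selected.
#' Selection signs are defined relative to *performance*: for
#' `lower_better` (time-scored) tests the raw correlation sign is
#' flipped, so "positively associated" edges are always those where more
#' fibers mean better performance.
#'
#' @param edge_table subjects x unique-edges numeric matrix (see
#'   [vectorize_edges()]).
#' @param scores numeric score vector (native units), one per subject;
#'   subjects with missing scores are dropped pairwise.
#' @param spec a one-row TestSpec (see [test_spec()]); its `direction`
#'   drives the performance-sign adjustment.
#' @param alpha selection threshold on the two-sided p-value (default
#'   0.001).
#' @return an `edge_screen` object: per-edge `rho` and `p`, logical
#'   `pos_mask` / `neg_mask` (performance-positive / -negative selected
#'   edges), `alpha`, and `n_used`.
#' @export
screen_edges <- function(edge_table, scores, spec, alpha = 0.001) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  ok <- is.finite(scores)
  X <- edge_table[ok, , drop = FALSE]
  y <- scores[ok]
  n <- length(y)
  if (n < 10L) {
    stop("need at least 10 subjects with non-missing scores, got ", n,
         call. = FALSE)
  }
  R <- col_midranks(X)
  rho <- drop(spearman_rho_matrix(R, matrix(y, ncol = 1)))
  pval <- spearman_t_pvalue(rho, n)
  perf <- direction_sign(spec) * rho
  sel <- !is.na(pval) & pval < alpha
  pos <- sel & perf > 0
  neg <- sel & perf < 0
  if (all(is.na(rho))) {
    warning("all edges are constant; no edges selected", call. = FALSE)
  }
  structure(list(test_id = spec$test_id, rho = rho, p = pval,
                 pos_mask = pos, neg_mask = neg, alpha = alpha,
                 n_used = n, direction = spec$direction),
            class = "edge_screen")
}

#' @export
print.edge_screen <- function(x, ...) {
  cat("Edge screen for '", x$test_id, "' (alpha = ", x$alpha, ", n = ",
      x$n_used, "): ", sum(x$pos_mask), " positive / ", sum(x$neg_mask),
      " negative of ", length(x$rho), " unique edges\n", sep = "")
  invisible(x)
}

#' Summary connectivity value
#'
#' Step (ii) of the CPM protocol: the per-subject sum of fiber counts
#' over a selected edge set. An empty mask returns 0 flagged with
#' attribute `no_edges`, signalling downstream model fitting to degrade
#' to an intercept-only prediction.
#'
#' @param subject_edges numeric vector of one subject's unique-edge fiber
#'   counts.
#' @param mask logical vector of the same length selecting edges.
#' @return the summed fiber count (attribute `no_edges = TRUE` when the
#'   mask is empty).
#' @export
summary_value <- function(subject_edges, mask) {
  if (length(mask) != length(subject_edges)) {
    stop("mask length ", length(mask), " does not match edge vector ",
         length(subject_edges), call. = FALSE)
  }
  out <- sum(subject_edges[mask])
  if (!any(mask)) attr(out, "no_edges") <- TRUE
  out
}

#' Ordinary least-squares model between scores and summary connectivity
#'
#' Step (iii) of the CPM protocol: a linear regression of the cognitive
#' scores on the summary connectivity value, optionally with covariate
#' terms.
#'
#' @param summary numeric vector of summary connectivity values.
#' @param scores numeric score vector.
#' @param covariates optional numeric matrix / data frame of additional
#'   regressors.
#' @return a `cpm_fit` list: `coefficients`, `r_squared`, `residual_sd`,
#'   `p_values` (per term), `n_used`.
#' @export
fit_linear <- function(summary, scores, covariates = NULL) {
  df <- data.frame(score = scores, connectivity = summary)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  n_terms <- ncol(df)                      # intercept + slopes
  if (nrow(df) <= n_terms) {
    stop("need more than ", n_terms, " complete observations, got ",
         nrow(df), call. = FALSE)
  }
  fit <- lm(score ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(coefficients = coef(fit),
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 p_values = sm$coefficients[, "Pr(>|t|)"],
                 n_used = nrow(df)),
            class = "cpm_fit")
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat("CPM linear model (n = ", x$n_used, "): R^2 = ",
      round(x$r_squared, 3), ", connectivity slope = ",
      signif(x$coefficients["connectivity"], 4), "\n", sep = "")
  invisible(x)
}

# permutation columns: column 1 is the observed score vector, columns
# 2..(n_perm + 1) are independent permutations of it
build_score_columns <- function(y, n_perm) {
  Y <- matrix(y, nrow = length(y), ncol = 1 + n_perm)
  if (n_perm > 0) {
    for (j in seq_len(n_perm) + 1L) Y[, j] <- sample(y)
  }
  Y
}

# Leave-one-out CPM core, fully vectorized across edges and across the
# observed + permuted score columns. For each fold the mid-ranks of the
# training edge table are derived from one precomputed radix sort of the
# full table: dropping a subject shifts within-column rank positions by
# run-length arithmetic instead of re-sorting (edge ranks must be
# recomputed per fold because they change when a subject is dropped).
loocv_core <- function(X, Y, sign_adj, alpha) {
  n <- nrow(X); p <- ncol(X); np <- n * p
  m <- ncol(Y)
  colid <- rep(seq_len(p), each = n)
  o <- order(colid, X, method = "radix")
  xs <- X[o]
  rows_sorted <- ((o - 1L) %% n) + 1L
  new_run <- c(TRUE, xs[-1L] != xs[-np]) | c(TRUE, diff(colid) > 0L)
  idx <- which(new_run)
  runlen <- diff(c(idx, np + 1L))
  ends <- c(idx[-1L] - 1L, np)
  prev_ends <- c(0L, ends[-length(ends)])
  no <- n - 1L
  rcrit <- spearman_rho_crit(no, alpha)
  rbar <- (no + 1) / 2
  pred <- matrix(NA_real_, n, m)
  fold_mask <- matrix(FALSE, p, n)
  n_edges <- integer(n)
  for (k in seq_len(n)) {
    keep <- rows_sorted != k
    cs <- cumsum(keep)
    pos <- (cs - (colid - 1L) * no) * keep
    cw <- cumsum(pos)
    gsum <- cw[ends] - c(0, cw[prev_ends])
    gn <- cs[ends] - c(0, cs[prev_ends])
    mid <- gsum / gn                      # NaN only for fully-removed runs
    Rfull <- numeric(np)
    Rfull[o] <- rep(mid, runlen)
    dim(Rfull) <- c(n, p)
    Rf <- Rfull[-k, , drop = FALSE]
    ss <- colSums(Rf * Rf) - no * rbar^2
    sd_e <- sqrt(pmax(ss, 0) / (no - 1))
    Yf <- Y[-k, , drop = FALSE]
    SY <- scale(apply(Yf, 2, rank))
    rho_raw <- crossprod(SY, Rf) / (no - 1)     # m x p, not yet / sd_e
    POS <- sweep(sign_adj * rho_raw, 2, rcrit * sd_e, ">")
    POS[, sd_e == 0] <- FALSE
    POS[is.na(POS)] <- FALSE
    M <- t(POS) + 0
    Xtr <- X[-k, , drop = FALSE]
    Str <- Xtr %*% M
    ste <- drop(X[k, ] %*% M)
    ybar <- colMeans(Yf); sbar <- colMeans(Str)
    sxy <- colSums(Str * Yf) - no * sbar * ybar
    sxx <- colSums(Str * Str) - no * sbar^2
    b <- ifelse(sxx > 1e-10, sxy / sxx, 0)
    pred[k, ] <- (ybar - b * sbar) + b * ste
    fold_mask[, k] <- POS[1L, ]
    n_edges[k] <- sum(POS[1L, ])
  }
  list(pred = pred, fold_mask = fold_mask, n_edges = n_edges)
}

# slower covariate-adjusted fold loop: small per-fold OLS with the
# summary value plus covariate columns
loocv_core_covariates <- function(X, Y, sign_adj, alpha, C) {
  n <- nrow(X); m <- ncol(Y)
  pred <- matrix(NA_real_, n, m)
  fold_mask <- matrix(FALSE, ncol(X), n)
  n_edges <- integer(n)
  no <- n - 1L
  rcrit <- spearman_rho_crit(no, alpha)
  for (k in seq_len(n)) {
    Xtr <- X[-k, , drop = FALSE]
    Rf <- col_midranks(Xtr)
    rho <- spearman_rho_matrix(Rf, Y[-k, , drop = FALSE])
    POS <- sign_adj * rho > rcrit
    POS[is.na(POS)] <- FALSE
    for (j in seq_len(m)) {
      mask <- POS[j, ]
      s_tr <- as.numeric(Xtr %*% mask)
      s_te <- sum(X[k, mask])
      if (any(mask)) {
        D <- cbind(1, s_tr, C[-k, , drop = FALSE])
        dte <- c(1, s_te, C[k, ])
      } else {
        D <- cbind(1, C[-k, , drop = FALSE])
        dte <- c(1, C[k, ])
      }
      beta <- qr.coef(qr(D), Y[-k, j])
      beta[is.na(beta)] <- 0
      pred[k, j] <- sum(dte * beta)
    }
    fold_mask[, k] <- POS[1L, ]
    n_edges[k] <- sum(POS[1L, ])
  }
  list(pred = pred, fold_mask = fold_mask, n_edges = n_edges)
}

#' Leave-one-out cross-validated CPM prediction
#'
#' Step (iv) of the CPM protocol. For every subject `s`, edges are
#' screened on all subjects except `s` ([screen_edges()] semantics), the
#' positively associated edges are summed into summary connectivity
#' values, a linear model is fitted on the training subjects, and
#' subject `s`'s score is predicted. Only performance-positive edges
#' enter the prediction model. Folds whose screening selects no edge
#' degrade to an intercept (plus covariates) prediction and are counted.
#'
#' With `n_perm > 0` the full fold-wise procedure is additionally rerun
#' on `n_perm` permutations of the score vector (feature selection
#' re-done inside every fold), yielding an empirical null for the
#' cross-validated correlation and a permutation p-value with the
#' add-one convention (see [perm_pvalue()]).
#'
#' @param x a subjects x edges matrix, or a `synth_cohort`.
#' @param scores score vector (matrix interface) or a `test_id` string
#'   (cohort interface).
#' @param spec one-row TestSpec; taken from the cohort's battery in the
#'   cohort interface.
#' @param alpha edge-selection threshold (default 0.001).
#' @param covariates optional numeric matrix of confounding covariates
#'   included in every fold's linear model.
#' @param n_perm number of score permutations (0 = no permutation test).
#' @param seed integer seed for the permutation stream.
#' @param ... passed between methods.
#' @return a `cpm_cv` object: out-of-fold `predicted` scores, observed
#'   Pearson `r`, `rmse`, `permutation_p` (when `n_perm > 0`),
#'   `permuted_r`, per-fold edge masks (`fold_masks`, edges x folds),
#'   `avg_edges_included` in directed-entry units, `n_empty_folds`,
#'   `n_used`, and bookkeeping fields.
#' @export
loocv_predict <- function(x, ...) UseMethod("loocv_predict")

#' @rdname loocv_predict
#' @export
loocv_predict.synth_cohort <- function(x, scores, ..., covariates = NULL) {
  test_id <- scores
  spec <- test_spec(test_id, x$battery)
  loocv_predict(x$edges, x$scores[[test_id]], spec, ...,
                covariates = covariates)
}

#' @rdname loocv_predict
#' @export
loocv_predict.default <- function(x, scores, spec, alpha = 0.001,
                                  covariates = NULL, n_perm = 0L,
                                  seed = NULL, ...) {
  X <- as.matrix(x)
  ok <- is.finite(scores)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
  }
  X <- X[ok, , drop = FALSE]
  y <- scores[ok]
  n <- length(y)
  if (n < 20L) {
    stop("need at least 20 subjects with non-missing scores, got ", n,
         call. = FALSE)
  }
  if (n_perm > 0 && !is.null(seed)) set.seed(seed)
  Y <- build_score_columns(y, n_perm)
  sign_adj <- direction_sign(spec)
  res <- if (is.null(covariates)) {
    loocv_core(X, Y, sign_adj, alpha)
  } else {
    loocv_core_covariates(X, Y, sign_adj, alpha,
                          covariates[ok, , drop = FALSE])
  }
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  r_obs <- safe_cor(res$pred[, 1L], y)
  rmse <- sqrt(mean((res$pred[, 1L] - y)^2))
  r_perm <- if (n_perm > 0) {
    vapply(seq_len(n_perm) + 1L,
           function(j) safe_cor(res$pred[, j], Y[, j]), 0)
  } else numeric(0)
  structure(list(
    test_id = spec$test_id,
    predicted = setNames(res$pred[, 1L], rownames(X)),
    observed = setNames(y, rownames(X)),
    r = r_obs, rmse = rmse,
    permutation_p = if (n_perm > 0) perm_pvalue(r_obs, r_perm) else NA_real_,
    permuted_r = r_perm, n_perm = n_perm,
    fold_masks = res$fold_mask,
    avg_edges_included = 2 * mean(res$n_edges),
    n_empty_folds = sum(res$n_edges == 0),
    alpha = alpha, n_used = n, seed = seed,
    direction = spec$direction), class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat("CPM leave-one-out cross-validation for '", x$test_id, "' (n = ",
      x$n_used, ", alpha = ", x$alpha, ")\n", sep = "")
  cat("  r = ", round(x$r, 3), ", RMSE = ", round(x$rmse, 2),
      ", avg edges included = ", round(x$avg_edges_included, 1),
      " (directed entries)\n", sep = "")
  if (x$n_perm > 0) {
    cat("  permutation p = ", format(round(x$permutation_p, 2), nsmall = 2),
        " (", x$n_perm, " iterations)\n", sep = "")
  }
  if (x$n_empty_folds > 0) {
    cat("  ", x$n_empty_folds, "fold(s) had no selected edges",
        "(intercept-only prediction)\n")
  }
  invisible(x)
}

#' Permutation p-value with the add-one convention
#'
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`. With 100 iterations the
#' smallest reportable value is 1/101, which rounds to the conventional
#' 0.01 floor at 2-decimal reporting.
#'
#' @param r_observed observed cross-validated correlation.
#' @param r_permuted vector of permuted correlations.
#' @return the permutation p-value.
#' @export
perm_pvalue <- function(r_observed, r_permuted) {
  (1 + sum(r_permuted >= r_observed)) / (1 + length(r_permuted))
}

#' Permutation test of the cross-validated CPM model
#'
#' Shuffles the score vector across subjects `n_perm` times, reruns the
#' complete fold-wise screening + prediction pipeline for every
#' permutation, and compares the observed cross-validated Pearson
#' correlation with the permuted ones.
#'
#' @inheritParams loocv_predict
#' @param n_perm number of permutations (default 100).
#' @return a `cpm_cv` object including `permutation_p` and `permuted_r`.
#' @export
permutation_test <- function(x, scores, spec = NULL, n_perm = 100L,
                             seed = NULL, alpha = 0.001,
                             covariates = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (inherits(x, "synth_cohort")) {
    loocv_predict(x, scores, alpha = alpha, n_perm = n_perm, seed = seed,
                  covariates = covariates)
  } else {
    loocv_predict(x, scores, spec, alpha = alpha, n_perm = n_perm,
                  seed = seed, covariates = covariates)
  }
}
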