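#' Covariate classes used for screening
#'
#' Maps covariate names to statistic families: continuous/ordinal
#' covariates are screened with Spearman rank correlation, binary ones
#' with the Mann-Whitney U test, multi-level categorical ones with the
#' Kruskal-Wallis test. Unknown columns are classified by type (numeric
#' -> spearman, two levels -> mann_whitney_u, otherwise kruskal_wallis).
#'
#' @param covariates covariate data frame.
#' @return named character vector of statistic families per covariate
#'   column (excluding `subject_id`).
#' @export
covariate_classes <- function(covariates) {
  known <- c(age = "spearman", education = "spearman",
             interval_months = "spearman", n_surgery = "spearman",
             n_radiotherapy = "spearman", n_chemotherapy = "spearman",
             vol_cavity = "spearman", vol_t1ce = "spearman",
             vol_flair = "spearman", vol_pet = "spearman",
             sex = "mann_whitney_u", idh = "mann_whitney_u",
             grade = "mann_whitney_u", recurrence = "mann_whitney_u",
             location = "kruskal_wallis")
  cols <- setdiff(names(covariates), c("subject_id", "lesion_side"))
  out <- character(0)
  for (cn in cols) {
    out[cn] <- if (cn %in% names(known)) {
      known[[cn]]
    } else if (is.numeric(covariates[[cn]]) &&
               length(unique(covariates[[cn]])) > 2) {
      "spearman"
    } else if (length(unique(stats::na.omit(covariates[[cn]]))) == 2) {
      "mann_whitney_u"
    } else "kruskal_wallis"
  }
  out
}

#' Nonparametric covariate screening
#'
#' Relates every covariate to every cognitive score with the statistic
#' family appropriate to its class: Spearman rank correlation for
#' continuous/ordinal covariates (age, education, interval since
#' treatment, intervention counts, lesion volumes), Mann-Whitney U for
#' binary ones (sex, IDH status, grade 3 vs 4, recurrence), and
#' Kruskal-Wallis for multi-level categorical ones (tumor location).
#' Normal/chi-square approximations with tie correction are used
#' throughout, appropriate at the cohort sizes targeted here.
#'
#' @param scores score data frame (first column `subject_id`).
#' @param covariates covariate data frame (first column `subject_id`).
#' @param alpha significance flag threshold (default 0.01).
#' @return a `screening_report` data frame with one row per
#'   (covariate, test): `covariate`, `test_id`, `method`, `statistic`,
#'   `p`, `significant`.
#' @export
screen_covariates <- function(scores, covariates, alpha = 0.01) {
  stopifnot(identical(scores$subject_id, covariates$subject_id))
  classes <- covariate_classes(covariates)
  tests <- setdiff(names(scores), "subject_id")
  rows <- list()
  for (cn in names(classes)) {
    cov <- covariates[[cn]]
    for (tn in tests) {
      y <- scores[[tn]]
      ok <- !is.na(y) & !is.na(cov)
      if (sum(ok) < 10) {
        stop("fewer than 10 complete subjects for (", cn, ", ", tn, ")",
             call. = FALSE)
      }
      yv <- y[ok]; cv <- cov[ok]
      method <- classes[[cn]]
      if (method != "spearman") {
        lev <- unique(cv)
        if (length(lev) < 2) {
          warning("covariate '", cn, "' has a single level; skipped",
                  call. = FALSE)
          next
        }
        if (min(table(cv)) < 2) {
          warning("covariate '", cn, "' has a level with < 2 subjects",
                  call. = FALSE)
        }
      }
      res <- switch(method,
        spearman = {
          ct <- suppressWarnings(
            cor.test(cv, yv, method = "spearman", exact = FALSE))
          c(statistic = unname(ct$estimate), p = ct$p.value)
        },
        mann_whitney_u = {
          f <- factor(cv)
          wt <- suppressWarnings(
            wilcox.test(yv[f == levels(f)[1]], yv[f == levels(f)[2]],
                        exact = FALSE))
          c(statistic = unname(wt$statistic), p = wt$p.value)
        },
        kruskal_wallis = {
          if (length(unique(yv)) == 1) {
            # all scores tied: no rank variance, H = 0 by convention
            c(statistic = 0, p = 1)
          } else {
            kt <- kruskal.test(yv, factor(cv))
            c(statistic = unname(kt$statistic), p = kt$p.value)
          }
        })
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cn, test_id = tn, method = method,
        statistic = res[["statistic"]], p = res[["p"]],
        significant = is.finite(res[["p"]]) && res[["p"]] < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(covariate = character(0), test_id = character(0),
               method = character(0), statistic = numeric(0),
               p = numeric(0), significant = logical(0))
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_report", "data.frame")
  out
}

# full-cohort positive summary connectivity values per test
connectivity_summaries <- function(edge_table, scores, battery,
                                   alpha = 0.001) {
  tests <- setdiff(names(scores), "subject_id")
  out <- list()
  for (tn in tests) {
    spec <- test_spec(tn, battery)
    scr <- screen_edges(edge_table, scores[[tn]], spec, alpha)
    out[[tn]] <- as.numeric(edge_table %*% scr$pos_mask)
  }
  out
}

#' Compare covariate model families
#'
#' Fits, per test, full-cohort ordinary least-squares models from several
#' regressor families - pure connectivity (the positive summary
#' connectivity value from full-cohort screening), demographic (age +
#' education), tumor-related (recurrence + lesion volumes + location),
#' and the combined demographic+connectivity and tumor+connectivity
#' models - and compares the per-test coefficients of determination
#' across families with paired t-tests. These are full-sample model fits,
#' deliberately distinct from the cross-validated correlations of
#' [loocv_predict()].
#'
#' @param edge_table subjects x edges matrix.
#' @param scores score data frame (first column `subject_id`).
#' @param covariates covariate data frame aligned with `scores`.
#' @param battery test battery table.
#' @param alpha edge-screening threshold for the connectivity summary
#'   (default 0.001).
#' @param families character vector of family names to fit.
#' @return a `family_comparison` list: `r_squared` (tests x families
#'   matrix), `mean_r2` / `sd_r2` per family, `paired_tests` (data frame
#'   of family contrasts with mean differences and p-values),
#'   `delta_r2_connectivity` (mean R^2 gain from adding connectivity to
#'   each base family), and `connectivity_p` (per-test p-value of the
#'   connectivity term in the combined models).
#' @export
compare_families <- function(edge_table, scores, covariates, battery,
                             alpha = 0.001,
                             families = c("connectivity", "demographic",
                                          "tumor",
                                          "demographic_connectivity",
                                          "tumor_connectivity")) {
  tests <- setdiff(names(scores), "subject_id")
  conn <- connectivity_summaries(edge_table, scores, battery, alpha)
  needed <- function(fam) switch(fam,
    connectivity = character(0),
    demographic = c("age", "education"),
    tumor = c("recurrence", "vol_cavity", "vol_t1ce", "vol_flair",
              "vol_pet", "location"),
    demographic_connectivity = c("age", "education"),
    tumor_connectivity = c("recurrence", "vol_cavity", "vol_t1ce",
                           "vol_flair", "vol_pet", "location"),
    stop("unknown family '", fam, "'", call. = FALSE))
  for (fam in families) {
    miss <- setdiff(needed(fam), names(covariates))
    if (length(miss)) {
      stop("family '", fam, "' needs unavailable covariate(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  design <- function(fam, tn) {
    base <- needed(fam)
    df <- if (length(base)) covariates[, base, drop = FALSE]
          else data.frame(row.names = seq_len(nrow(scores)))
    for (cn in names(df)) {
      if (!is.numeric(df[[cn]])) df[[cn]] <- factor(df[[cn]])
    }
    if (grepl("connectivity", fam)) df$connectivity <- conn[[tn]]
    df
  }
  r2 <- matrix(NA_real_, length(tests), length(families),
               dimnames = list(tests, families))
  conn_p <- list()
  for (tn in tests) {
    y <- scores[[tn]]
    for (fam in families) {
      df <- design(fam, tn)
      df$score <- y
      df <- df[complete.cases(df), , drop = FALSE]
      fit <- lm(score ~ ., data = df)
      r2[tn, fam] <- summary(fit)$r.squared
      if (grepl("_connectivity", fam)) {
        pv <- summary(fit)$coefficients
        # a constant summary (no selected edges) drops to an NA term
        conn_p[[paste(tn, fam, sep = ".")]] <-
          if ("connectivity" %in% rownames(pv)) {
            pv["connectivity", "Pr(>|t|)"]
          } else NA_real_
      }
    }
  }
  paired <- list()
  contrast <- function(a, b) {
    if (!all(c(a, b) %in% families)) return(NULL)
    d <- r2[, a] - r2[, b]
    pt_res <- if (sd(d) == 0) {
      list(p.value = if (all(d == 0)) 1 else NA_real_, statistic = NA_real_)
    } else t.test(r2[, a], r2[, b], paired = TRUE)
    data.frame(family_a = a, family_b = b, mean_delta = mean(d),
               statistic = unname(pt_res$statistic), p = pt_res$p.value,
               stringsAsFactors = FALSE)
  }
  paired <- do.call(rbind, Filter(Negate(is.null), list(
    contrast("connectivity", "demographic"),
    contrast("connectivity", "tumor"),
    contrast("demographic_connectivity", "demographic"),
    contrast("tumor_connectivity", "tumor"))))
  delta <- c(
    demographic = if (all(c("demographic_connectivity", "demographic")
                          %in% families)) {
      mean(r2[, "demographic_connectivity"] - r2[, "demographic"])
    } else NA_real_,
    tumor = if (all(c("tumor_connectivity", "tumor") %in% families)) {
      mean(r2[, "tumor_connectivity"] - r2[, "tumor"])
    } else NA_real_)
  structure(list(r_squared = r2,
                 mean_r2 = colMeans(r2), sd_r2 = apply(r2, 2, sd),
                 paired_tests = paired,
                 delta_r2_connectivity = delta,
                 connectivity_p = unlist(conn_p)),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("Model family comparison over", nrow(x$r_squared), "tests:\n")
  for (fam in colnames(x$r_squared)) {
    cat(sprintf("  %-26s R^2 = %.3f +/- %.3f\n", fam,
                x$mean_r2[fam], x$sd_r2[fam]))
  }
  invisible(x)
}
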