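#' Percentage of possible edges
#'
#' Expresses a directed-entry edge count as a percentage of the
#' `N * (N - 1)` edge universe, rounded for display (1 decimal by
#' default, matching the summary-table convention).
#'
#' @param count directed-entry edge count.
#' @param denominator number of possible directed entries.
#' @param digits decimals for display rounding.
#' @return rounded percentage.
#' @export
pct_of_possible <- function(count, denominator, digits = 1) {
  round(100 * count / denominator, digits)
}

#' Aggregate per-test cross-validation results into a summary table
#'
#' Builds the per-test results table: average number of edges included
#' per fold (directed-entry units and % of the `N(N-1)` universe), RMSE,
#' cross-validated Pearson r, permutation p (rounded to 2 decimals for
#' display), and the validated intra-/inter-network/total edge counts.
#' Tests failing the permutation test contribute "CV not passed" rows
#' (NA counts).
#'
#' @param cv_results list of `cpm_cv` objects, one per test.
#' @param maps list of `validated_edge_map` objects aligned with
#'   `cv_results`.
#' @param parcellation the `parcellation` used.
#' @return a `cpm_summary` data frame, one row per test, with attribute
#'   `aggregates` (see [summarize_cv_table()]).
#' @export
aggregate_results <- function(cv_results, maps, parcellation) {
  ids <- vapply(cv_results, function(cv) cv$test_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate test ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  denom <- count_valid_entries(parcellation)
  rows <- lapply(seq_along(cv_results), function(k) {
    cv <- cv_results[[k]]
    map <- maps[[k]]
    cls <- if (map$cv_passed) classify_edges(map, parcellation)
           else list(intra = NA_integer_, inter = NA_integer_,
                     total = NA_integer_)
    data.frame(
      test_id = cv$test_id,
      avg_edges_included = cv$avg_edges_included,
      avg_edges_pct = pct_of_possible(cv$avg_edges_included, denom),
      rmse = cv$rmse, r = cv$r,
      p_perm = cv$permutation_p,
      cv_passed = map$cv_passed,
      intra_network = cls$intra, inter_network = cls$inter,
      total_validated = cls$total,
      total_validated_pct = if (map$cv_passed) {
        pct_of_possible(cls$total, denom)
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "denominator") <- denom
  attr(out, "aggregates") <- summarize_cv_table(out)
  class(out) <- c("cpm_summary", "data.frame")
  out
}

#' Aggregate statistics of a per-test cross-validation table
#'
#' Recomputes the headline aggregates from any per-test results table
#' (they are never cached independently): the number of tests with
#' significant predictive power, the median and range of their
#' cross-validated correlations (midpoint convention for even counts),
#' and the overall share of inter-network edges among all validated
#' edges.
#'
#' @param tab data frame with columns `r`, `p_perm` and (optionally)
#'   `intra_network`, `inter_network`; typically an [aggregate_results()]
#'   table or a published per-test results table.
#' @param model_alpha threshold on the permutation p (default 0.05).
#' @return list with `n_tests`, `n_predicted`, `median_r`, `min_r`,
#'   `max_r` (over predicted tests, 2-decimal display rounding),
#'   `inter_network_share_pct` and the underlying `inter_total` /
#'   `validated_total` counts.
#' @export
summarize_cv_table <- function(tab, model_alpha = 0.05) {
  passed <- !is.na(tab$p_perm) & tab$p_perm < model_alpha
  r_pass <- tab$r[passed]
  inter_total <- sum(tab$inter_network[passed], na.rm = TRUE)
  intra_total <- sum(tab$intra_network[passed], na.rm = TRUE)
  validated_total <- inter_total + intra_total
  list(n_tests = nrow(tab),
       n_predicted = sum(passed),
       median_r = if (length(r_pass)) round(median(r_pass), 2)
                  else NA_real_,
       min_r = if (length(r_pass)) round(min(r_pass), 2) else NA_real_,
       max_r = if (length(r_pass)) round(max(r_pass), 2) else NA_real_,
       inter_total = inter_total,
       validated_total = validated_total,
       inter_network_share_pct =
         if (validated_total > 0) 100 * inter_total / validated_total
         else NA_real_)
}

#' @export
print.cpm_summary <- function(x, ...) {
  df <- as.data.frame(x)
  df$r <- round(df$r, 3)
  df$p_perm <- round(df$p_perm, 2)
  df$rmse <- round(df$rmse, 2)
  print(df, row.names = FALSE)
  ag <- attr(x, "aggregates")
  cat(sprintf("\n%d/%d tests predicted (median r %.2f; range %.2f-%.2f);",
              ag$n_predicted, ag$n_tests, ag$median_r, ag$min_r, ag$max_r))
  if (is.finite(ag$inter_network_share_pct)) {
    cat(sprintf(" %d/%d = %.0f%% inter-network validated edges\n",
                ag$inter_total, ag$validated_total,
                ag$inter_network_share_pct))
  } else cat("\n")
  invisible(x)
}

#' Run the full CPM analysis pipeline
#'
#' Orchestrates, for every test of the battery: full-cohort edge
#' screening, leave-one-out cross-validation with a permutation test,
#' validated-edge mapping, and node-degree criticality; then normative
#' deficit classification, covariate screening, model-family comparison,
#' and the aggregated summary table. All randomness derives from `seed`
#' (per-test permutation streams are derived deterministically), so
#' identical inputs and seed reproduce identical outputs.
#'
#' @param cohort a `synth_cohort`, or a list with elements `edges`,
#'   `scores`, `covariates`, `controls`, `parcellation`, `battery`.
#' @param alpha edge-selection threshold (default 0.001).
#' @param n_perm permutation iterations (default 100; must be >= 1).
#' @param fold_threshold validated-edge fold share (default 0.90).
#' @param model_alpha permutation significance threshold (default 0.05).
#' @param screening_alpha covariate screening threshold (default 0.01).
#' @param seed root integer seed (mandatory).
#' @param tests test ids to analyze (default: all in the battery).
#' @param out_dir optional directory; when given, per-test predictions,
#'   edge lists, node degrees, the summary table, norms, and a JSON run
#'   summary are written there as TSV/JSON.
#' @return a `cpm_pipeline` list: `cv_results`, `maps`, `degrees`,
#'   `summary`, `norms`, `covariate_screening`, `family_comparison`,
#'   `degree_heatmap`, `seed`.
#' @export
run_pipeline <- function(cohort, alpha = 0.001, n_perm = 100L,
                         fold_threshold = 0.90, model_alpha = 0.05,
                         screening_alpha = 0.01, seed, tests = NULL,
                         out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  for (thr in c(alpha, fold_threshold, model_alpha, screening_alpha)) {
    if (thr <= 0 || thr >= 1) {
      stop("thresholds must lie in (0, 1)", call. = FALSE)
    }
  }
  battery <- cohort$battery
  if (is.null(tests)) tests <- intersect(battery$test_id,
                                         names(cohort$scores))
  cv_results <- list(); maps <- list(); degrees <- list()
  for (i in seq_along(tests)) {
    tn <- tests[i]
    spec <- test_spec(tn, battery)
    test_seed <- (seed + 7919L * i) %% .Machine$integer.max
    cv <- loocv_predict(cohort$edges, cohort$scores[[tn]], spec,
                        alpha = alpha, n_perm = n_perm, seed = test_seed)
    map <- validated_edges(cv, fold_threshold, model_alpha)
    cv_results[[tn]] <- cv
    maps[[tn]] <- map
    degrees[[tn]] <- node_degrees(map, cohort$parcellation)
  }
  summary_tab <- aggregate_results(cv_results, maps, cohort$parcellation)
  norms <- deficit_classify(cohort$scores, cohort$controls, battery)
  cov_screen <- screen_covariates(cohort$scores, cohort$covariates,
                                  alpha = screening_alpha)
  fam <- compare_families(cohort$edges, cohort$scores, cohort$covariates,
                          battery, alpha = alpha)
  heat <- degree_table(degrees)
  out <- structure(list(cv_results = cv_results, maps = maps,
                        degrees = degrees, summary = summary_tab,
                        norms = norms, covariate_screening = cov_screen,
                        family_comparison = fam, degree_heatmap = heat,
                        seed = seed),
                   class = "cpm_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, cohort, out_dir)
  out
}

write_pipeline_outputs <- function(pipe, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eu <- edge_universe(nrow(cohort$parcellation))
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (tn in names(pipe$cv_results)) {
    cv <- pipe$cv_results[[tn]]
    tsv(data.frame(subject_id = names(cv$predicted),
                   predicted = cv$predicted, actual = cv$observed),
        paste0("predicted_", tn, ".tsv"))
    map <- pipe$maps[[tn]]
    if (isTRUE(map$cv_passed) && any(map$mask)) {
      sel <- which(map$mask)
      tsv(data.frame(
        node_i = eu$pairs[sel, "i"], node_j = eu$pairs[sel, "j"],
        network_i = cohort$parcellation$network[eu$pairs[sel, "i"]],
        network_j = cohort$parcellation$network[eu$pairs[sel, "j"]],
        fold_fraction = map$fold_fraction[sel]),
        paste0("validated_edges_", tn, ".tsv"))
    }
    tsv(pipe$degrees[[tn]]$degree, paste0("node_degree_", tn, ".tsv"))
  }
  tsv(as.data.frame(pipe$summary), "summary_table.tsv")
  tsv(as.data.frame(pipe$norms), "norms.tsv")
  tsv(as.data.frame(pipe$covariate_screening), "covariate_screening.tsv")
  tsv(pipe$degree_heatmap, "degree_heatmap.tsv")
  ag <- attr(pipe$summary, "aggregates")
  jsonlite::write_json(
    list(seed = pipe$seed, aggregates = ag,
         family_mean_r2 = as.list(pipe$family_comparison$mean_r2)),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cpm_pipeline <- function(x, ...) {
  cat("CPM pipeline run (seed ", x$seed, ")\n\n", sep = "")
  print(x$summary)
  invisible(x)
}
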