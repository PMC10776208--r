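#' Cross-validated (validated) predictive edges
#'
#' An edge is a *validated predictive edge* when it was selected in at
#' least `fold_threshold` (default 90%, inclusive) of the leave-one-out
#' folds of a model with significant predictive power (permutation
#' p < `model_alpha`). When the model fails the permutation test the map
#' is empty and flagged "CV not passed".
#'
#' @param cv a `cpm_cv` object carrying per-fold edge masks and a
#'   permutation p-value.
#' @param fold_threshold minimum share of folds in which an edge must be
#'   selected (inclusive, default 0.90).
#' @param model_alpha significance threshold on the permutation p-value
#'   (default 0.05).
#' @return a `validated_edge_map`: logical unique-edge `mask`,
#'   `fold_fraction` per edge, `cv_passed` flag, `test_id` and the
#'   thresholds used.
#' @export
validated_edges <- function(cv, fold_threshold = 0.90,
                            model_alpha = 0.05) {
  stopifnot(inherits(cv, "cpm_cv"))
  if (is.null(cv$fold_masks)) {
    stop("CVResult carries no per-fold masks", call. = FALSE)
  }
  if (is.na(cv$permutation_p)) {
    stop("no permutation p-value; run the cross-validation with ",
         "n_perm > 0", call. = FALSE)
  }
  fold_fraction <- rowMeans(cv$fold_masks)
  cv_passed <- cv$permutation_p < model_alpha
  mask <- if (cv_passed) fold_fraction >= fold_threshold
          else rep(FALSE, length(fold_fraction))
  structure(list(test_id = cv$test_id, mask = mask,
                 fold_fraction = fold_fraction, cv_passed = cv_passed,
                 permutation_p = cv$permutation_p,
                 fold_threshold = fold_threshold,
                 model_alpha = model_alpha),
            class = "validated_edge_map")
}

#' @export
print.validated_edge_map <- function(x, ...) {
  if (!x$cv_passed) {
    cat("Validated edge map for '", x$test_id, "': CV not passed ",
        "(permutation p = ", round(x$permutation_p, 2), ")\n", sep = "")
  } else {
    cat("Validated edge map for '", x$test_id, "': ", sum(x$mask),
        " unique edges (", 2 * sum(x$mask), " directed entries) at ",
        "fold threshold ", x$fold_threshold, "\n", sep = "")
  }
  invisible(x)
}

#' Classify validated edges as within- or between-network
#'
#' An edge is *intra-network* iff both endpoint nodes carry the same
#' network label (hemisphere ignored), *inter-network* otherwise. Counts
#' are reported in directed-entry units (each unique edge counts twice),
#' matching the convention of the `N * (N - 1)` edge universe.
#'
#' @param map a `validated_edge_map`.
#' @param parcellation the `parcellation` the map refers to.
#' @return list with `intra`, `inter`, `total` directed-entry counts.
#' @export
classify_edges <- function(map, parcellation) {
  stopifnot(inherits(map, "validated_edge_map"))
  eu <- edge_universe(nrow(parcellation))
  if (length(map$mask) != eu$unique_edge_count) {
    stop("map has ", length(map$mask), " edges but parcellation implies ",
         eu$unique_edge_count, call. = FALSE)
  }
  sel <- which(map$mask)
  net_i <- parcellation$network[eu$pairs[sel, "i"]]
  net_j <- parcellation$network[eu$pairs[sel, "j"]]
  intra <- 2L * sum(net_i == net_j)
  total <- 2L * length(sel)
  list(intra = intra, inter = total - intra, total = total)
}

#' Node degrees and critical-node sets of a validated edge map
#'
#' The degree of a node is the number of unique validated edges incident
#' to it. Criticality thresholds are derived from the degree distribution
#' of the nodes with nonzero degree: critical nodes have degree >=
#' `floor(mean + 1 * SD)`, highly critical nodes degree >=
#' `floor(mean + 2 * SD)` (sample SD; thresholds floored to integers so
#' that e.g. a nonzero-degree mean of 5.4 and SD of 5.2 yield the
#' conventional cutoff of 10).
#'
#' @param map a `validated_edge_map`.
#' @param parcellation the `parcellation` the map refers to.
#' @param multipliers numeric length-2 vector of SD multipliers for the
#'   critical / highly critical thresholds.
#' @return a `node_degree_map`: per-node `degree` data frame (node_id,
#'   hemisphere, network, degree), `mean_nonzero`, `sd_nonzero`,
#'   `threshold_critical`, `threshold_highly_critical`, and the
#'   `critical` / `highly_critical` node tables.
#' @export
node_degrees <- function(map, parcellation, multipliers = c(1, 2)) {
  stopifnot(inherits(map, "validated_edge_map"), length(multipliers) == 2)
  eu <- edge_universe(nrow(parcellation))
  deg <- integer(eu$n_nodes)
  sel <- which(map$mask)
  if (length(sel)) {
    tab <- table(factor(c(eu$pairs[sel, "i"], eu$pairs[sel, "j"]),
                        levels = seq_len(eu$n_nodes)))
    deg <- as.integer(tab)
  }
  degree <- data.frame(node_id = parcellation$node_id,
                       hemisphere = parcellation$hemisphere,
                       network = parcellation$network,
                       label = parcellation$label,
                       degree = deg, stringsAsFactors = FALSE)
  nz <- deg[deg > 0]
  if (length(nz) >= 1) {
    m <- mean(nz)
    s <- if (length(nz) > 1) sd(nz) else 0
    thr1 <- floor(m + multipliers[1] * s)
    thr2 <- floor(m + multipliers[2] * s)
    critical <- degree[deg >= thr1, , drop = FALSE]
    highly <- degree[deg >= thr2, , drop = FALSE]
  } else {
    m <- s <- NA_real_; thr1 <- thr2 <- NA_real_
    critical <- highly <- degree[0, , drop = FALSE]
  }
  structure(list(test_id = map$test_id, degree = degree,
                 mean_nonzero = m, sd_nonzero = s,
                 threshold_critical = thr1,
                 threshold_highly_critical = thr2,
                 critical = critical, highly_critical = highly),
            class = "node_degree_map")
}

#' @export
print.node_degree_map <- function(x, ...) {
  cat("Node degrees for '", x$test_id, "': ",
      sum(x$degree$degree > 0), " nonzero-degree nodes (mean ",
      round(x$mean_nonzero, 1), " +/- ", round(x$sd_nonzero, 1),
      ")\n", sep = "")
  if (!is.na(x$threshold_critical)) {
    cat("  critical (degree >= ", x$threshold_critical, "): ",
        nrow(x$critical), " nodes; highly critical (degree >= ",
        x$threshold_highly_critical, "): ", nrow(x$highly_critical),
        " nodes\n", sep = "")
  }
  invisible(x)
}

#' Network-by-test degree table
#'
#' Sums validated-edge node degrees within each (hemisphere, network)
#' cell for every test, the tabular analogue of a degree heatmap.
#'
#' @param degree_maps list of `node_degree_map` objects (one per test).
#' @return data frame with `hemisphere`, `network`, and one column per
#'   test holding the summed node degree.
#' @export
degree_table <- function(degree_maps) {
  stopifnot(length(degree_maps) >= 1)
  base <- degree_maps[[1]]$degree
  key <- unique(base[, c("hemisphere", "network")])
  key <- key[order(key$hemisphere, key$network), ]
  out <- key
  for (dm in degree_maps) {
    agg <- tapply(dm$degree$degree,
                  list(dm$degree$hemisphere, dm$degree$network), sum)
    out[[dm$test_id]] <- mapply(function(h, n) agg[h, n],
                                key$hemisphere, key$network)
  }
  rownames(out) <- NULL
  out
}

#' Descriptive map of performance-negative edges
#'
#' Edges whose fiber counts are negatively associated with performance
#' are screened on the full cohort and reported descriptively (they are
#' never cross-validated or used for prediction, since final models are
#' built from positively associated edges only).
#'
#' @param edge_table subjects x edges matrix.
#' @param scores score vector.
#' @param spec one-row TestSpec.
#' @param alpha selection threshold (default 0.001).
#' @return a `validated_edge_map`-like object whose `mask` holds the
#'   full-cohort negative edges (`cv_passed` is `NA`).
#' @export
negative_edge_map <- function(edge_table, scores, spec, alpha = 0.001) {
  scr <- screen_edges(edge_table, scores, spec, alpha)
  structure(list(test_id = spec$test_id, mask = scr$neg_mask,
                 fold_fraction = as.numeric(scr$neg_mask),
                 cv_passed = NA, permutation_p = NA_real_,
                 fold_threshold = NA_real_, model_alpha = NA_real_),
            class = "validated_edge_map")
}
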