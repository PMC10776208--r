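# Shared synthetic fixtures, built once per test run.

# small, fast cohort: 30-node parcellation, 60 patients
small_config <- function(...) {
  synth_config(n_patients = 60L, n_controls = 60L,
               parcellation = synthetic_parcellation(15L),
               n_planted = 10L, seed = 101L, ...)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_cohort <- function() memo("small", generate_cohort(small_config()))

# full study-scale cohort (121 patients, 100 nodes), default conditions
default_cohort <- function() memo("default",
                                  generate_cohort(synth_config(seed = 7L)))

# hand-made minimal parcellation (no per-hemisphere completeness needed)
toy_parcellation <- function(n = 5L) {
  df <- data.frame(
    node_id = seq_len(n),
    hemisphere = rep(c("L", "R"), length.out = n),
    network = rep(c("visual", "default_mode", "control"), length.out = n),
    label = paste0("n", seq_len(n)),
    stringsAsFactors = FALSE)
  structcpm:::validate_parcellation(df)
}

# fabricate a cpm_cv carrying the given fold masks and permutation p
fake_cv <- function(fold_masks, permutation_p, test_id = "toy") {
  structure(list(test_id = test_id, fold_masks = fold_masks,
                 permutation_p = permutation_p, n_perm = 100L,
                 r = 0.5, rmse = 1, avg_edges_included = 0,
                 n_empty_folds = 0L, alpha = 0.001,
                 n_used = ncol(fold_masks)),
            class = "cpm_cv")
}

# validated map from an explicit unique-edge mask
fake_map <- function(mask, test_id = "toy") {
  structure(list(test_id = test_id, mask = mask,
                 fold_fraction = as.numeric(mask), cv_passed = TRUE,
                 permutation_p = 0.01, fold_threshold = 0.9,
                 model_alpha = 0.05),
            class = "validated_edge_map")
}

reference_cv_table <- function() {
  read.delim(system.file("extdata", "reference_cv_table.tsv",
                         package = "structcpm"))
}
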