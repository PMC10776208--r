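test_that("identical config and seed reproduce the cohort bit-identically", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$edges, b$edges)
  expect_identical(a$scores, b$scores)
  expect_identical(a$controls, b$controls)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth$planted_edges, b$truth$planted_edges)
})

test_that("noiseless scores equal the recorded linear model exactly", {
  cfg <- small_config(effect_tests = "word_list_immediate",
                      planted_edges = list(word_list_immediate = 17L),
                      edge_weights = c(word_list_immediate = 0.5),
                      noise_sd = c(word_list_immediate = 0))
  coh <- generate_cohort(cfg)
  mod <- coh$truth$models$word_list_immediate
  e <- coh$truth$planted_edges$word_list_immediate
  recomputed <- mod$intercept +
    unname(drop(coh$edges[, e, drop = FALSE] %*% mod$edge_weights)) +
    mod$beta_age * coh$covariates$age +
    mod$beta_edu * coh$covariates$education
  expect_equal(coh$scores$word_list_immediate, recomputed,
               tolerance = 1e-10)

  # with covariate shares zeroed, the planted summary explains everything
  cfg2 <- small_config(effect_tests = "tmt_a", r2_age = 0,
                       r2_education = 0, noise_sd = c(tmt_a = 0))
  coh2 <- generate_cohort(cfg2)
  s <- rowSums(coh2$edges[, coh2$truth$planted_edges$tmt_a, drop = FALSE])
  fit <- fit_linear(s, coh2$scores$tmt_a)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$coefficients["connectivity"], 0)  # time-scored test
})

test_that("ipsilesional nodal fiber loss matches the configured 17.5%", {
  stats <- nodal_fiber_stats(default_cohort())
  expect_equal(stats$lesion_summary$ratio, 0.825, tolerance = 0.04 / 0.825)
  expect_true(stats$lesion_summary$percent_loss > 13.5 &&
                stats$lesion_summary$percent_loss < 21.5)
})

test_that("fiber count marginals follow the configured class means and ordering", {
  # law-of-large-numbers check on the count machinery (no between-edge
  # spread, no lesions, no planted effects)
  cfg <- synth_config(n_patients = 100L, n_controls = 10L,
                      parcellation = synthetic_parcellation(15L),
                      edge_log_sd = 0, lesion_fraction = c(none = 1),
                      effect_tests = character(0), seed = 55L)
  coh <- generate_cohort(cfg)
  cls <- structcpm:::edge_classes(coh$parcellation)
  for (cn in c("intra_network", "intra_hemisphere", "inter_hemisphere")) {
    realized <- mean(coh$edges[, cls$class == cn])
    expect_equal(realized, unname(cfg$mean_fiber[cn]),
                 tolerance = 0.05)
  }
  # default cohort keeps the qualitative block structure
  coh2 <- default_cohort()
  cls2 <- structcpm:::edge_classes(coh2$parcellation)
  m <- vapply(c("intra_network", "intra_hemisphere", "inter_hemisphere"),
              function(cn) mean(coh2$edges[, cls2$class == cn]), 0)
  expect_true(m["intra_network"] > m["intra_hemisphere"])
  expect_true(m["intra_hemisphere"] > m["inter_hemisphere"])
})

test_that("nodal fiber stats match brute-force row sums", {
  parc <- toy_parcellation(4L)
  zero <- connectivity_matrix(matrix(0, 4, 4), "z")
  s0 <- nodal_fiber_stats(list(zero), parc)
  expect_equal(s0$hemisphere_summary$median_total, c(0, 0))
  expect_equal(s0$hemisphere_summary$max_total, c(0, 0))

  v <- matrix(c(0, 2, 3, 1,
                2, 0, 4, 0,
                3, 4, 0, 5,
                1, 0, 5, 0), 4, 4)
  m <- connectivity_matrix(v, "s", lesion_side = "L")
  st <- nodal_fiber_stats(list(m), parc)
  # brute-force totals: rowSums; hemispheres alternate L,R,L,R
  totals <- rowSums(v)
  expect_equal(st$hemisphere_summary$median_total,
               c(median(totals[c(1, 3)]), median(totals[c(2, 4)])))
  ipsi <- c(sum(v[1, c(1, 3)]), sum(v[2, c(2, 4)]),
            sum(v[3, c(1, 3)]), sum(v[4, c(2, 4)]))
  expect_equal(st$lesion_summary$ipsilesional_median,
               median(ipsi[c(1, 3)]))
  expect_equal(st$lesion_summary$contralesional_median,
               median(ipsi[c(2, 4)]))
})

test_that("degenerate configs are rejected", {
  expect_error(synth_config(lesion_loss = 1), "lesion_loss")
  expect_error(synth_config(lesion_fraction = c(L = 0.5, R = 0.2)),
               "sum to 1")
  expect_error(synth_config(planted_edges = list(tmt_a = 10^7)),
               "out of range")
  battery <- cognitive_battery()
  zero_noise <- setNames(rep(0, nrow(battery)), battery$test_id)
  # no connectivity, no covariates, no noise -> constant scores
  cfg <- small_config(effect_tests = character(0), r2_age = 0,
                      r2_education = 0, noise_sd = zero_noise,
                      patient_shift = setNames(rep(0, nrow(battery)),
                                               battery$test_id))
  expect_error(generate_cohort(cfg), "zero variance")
})
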