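test_that("statistic family is a pure function of covariate class", {
  cov <- data.frame(subject_id = letters[1:12], age = rnorm(12),
                    sex = rep(c("M", "F"), 6),
                    location = rep(c("a", "b", "c"), 4),
                    custom_score = rnorm(12),
                    custom_flag = rep(c("x", "y"), 6))
  cls <- covariate_classes(cov)
  expect_equal(unname(cls[c("age", "sex", "location")]),
               c("spearman", "mann_whitney_u", "kruskal_wallis"))
  expect_equal(unname(cls["custom_score"]), "spearman")
  expect_equal(unname(cls["custom_flag"]), "mann_whitney_u")
})

test_that("degenerate group comparisons follow the mid-rank conventions", {
  n <- 12L
  scores <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       testA = rep(c(1, 2, 3), 4),
                       testB = rep(5, n))
  cov <- data.frame(subject_id = scores$subject_id,
                    grp = rep(c("g1", "g2"), each = n / 2),
                    loc = rep(c("a", "b", "c"), 4),
                    stringsAsFactors = FALSE)
  rep_tab <- screen_covariates(scores, cov, alpha = 0.01)
  # two groups with identical score distributions -> U = n1*n2/2, p ~ 1
  row_u <- rep_tab[rep_tab$covariate == "grp" & rep_tab$test_id == "testA", ]
  expect_equal(row_u$statistic, 6 * 6 / 2)
  expect_gt(row_u$p, 0.9)
  # three groups over constant scores -> H = 0
  row_k <- rep_tab[rep_tab$covariate == "loc" & rep_tab$test_id == "testB", ]
  expect_equal(row_k$statistic, 0)
  expect_equal(row_k$p, 1)
})

test_that("Mann-Whitney U equals the brute-force count of pairwise wins", {
  set.seed(41)
  n <- 12L
  y <- sample(seq(1, 100, by = 3), n)          # no ties
  grp <- rep(c("g1", "g2"), each = n / 2)
  scores <- data.frame(subject_id = sprintf("s%02d", 1:n), t1 = y)
  cov <- data.frame(subject_id = scores$subject_id, grp = grp,
                    stringsAsFactors = FALSE)
  rep_tab <- screen_covariates(scores, cov)
  u <- rep_tab$statistic[rep_tab$covariate == "grp"]
  wins <- 0
  for (a in y[grp == "g1"]) for (b in y[grp == "g2"]) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  expect_equal(u, wins)
})

test_that("single-level categorical covariates are skipped with a warning", {
  scores <- data.frame(subject_id = sprintf("s%02d", 1:12),
                       t1 = rnorm(12))
  cov <- data.frame(subject_id = scores$subject_id,
                    recurrence = rep("no", 12), stringsAsFactors = FALSE)
  expect_warning(rep_tab <- screen_covariates(scores, cov),
                 "single level")
  expect_equal(nrow(rep_tab), 0L)
})

test_that("screening the synthetic cohort flags the planted covariate effects", {
  coh <- default_cohort()
  rep_tab <- screen_covariates(coh$scores, coh$covariates, alpha = 0.01)
  sig_age <- sum(rep_tab$significant[rep_tab$covariate == "age"])
  expect_gte(sig_age, 5)                       # age affects every score
  expect_true(all(rep_tab$method[rep_tab$covariate == "idh"] ==
                    "mann_whitney_u"))
  expect_true(all(rep_tab$method[rep_tab$covariate == "location"] ==
                    "kruskal_wallis"))
})

test_that("family comparison is nested and favors connectivity on planted cohorts", {
  coh <- small_cohort()
  fam <- compare_families(coh$edges, coh$scores, coh$covariates,
                          coh$battery)
  r2 <- fam$r_squared
  # nestedness on identical subject sets
  expect_true(all(r2[, "demographic_connectivity"] >=
                    r2[, "demographic"] - 1e-12))
  expect_true(all(r2[, "tumor_connectivity"] >= r2[, "tumor"] - 1e-12))
  # planted connectivity beats weak demographic effects
  expect_gt(fam$mean_r2["connectivity"], fam$mean_r2["demographic"])
  ct <- fam$paired_tests
  p_conn_dem <- ct$p[ct$family_a == "connectivity" &
                       ct$family_b == "demographic"]
  expect_lt(p_conn_dem, 0.05)
  # paired t statistic matches the closed form on the R^2 vectors
  d <- r2[, "connectivity"] - r2[, "demographic"]
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  t_pkg <- ct$statistic[ct$family_a == "connectivity" &
                          ct$family_b == "demographic"]
  expect_equal(t_pkg, t_hand, tolerance = 1e-10)
  # delta R^2 from adding connectivity is the plain column difference
  expect_equal(unname(fam$delta_r2_connectivity["demographic"]),
               mean(d * 0 + r2[, "demographic_connectivity"] -
                      r2[, "demographic"]))
  expect_error(compare_families(coh$edges, coh$scores,
                                coh$covariates[, 1:3], coh$battery),
               "unavailable")
})
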