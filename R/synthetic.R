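#' Configuration for the synthetic cohort generator
#'
#' Collects every parameter of the synthetic patient/control cohort in one
#' validated object. Fiber counts are drawn per unique edge from a
#' negative binomial (Poisson-gamma) distribution whose mean depends on
#' the edge class - intra-network and intra-hemisphere edges carry more
#' fibers than inter-hemispheric ones - with a lognormal spread of
#' baseline means across edges producing the long right tail seen in
#' tractography fiber counts. Lesioned patients lose a fixed proportion of
#' fibers on every edge incident to an ipsilesional node. Each test with a
#' planted effect has a disjoint set of edges whose counts are coupled,
#' through a per-subject latent ability factor, to that test's score.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param parcellation a `parcellation`; default the bundled 100-node
#'   fixture.
#' @param mean_fiber named vector of mean fiber counts per edge class
#'   (`intra_network`, `intra_hemisphere`, `inter_hemisphere`).
#' @param edge_log_sd lognormal SD (log scale) of baseline means across
#'   edges within a class.
#' @param dispersion negative binomial size parameter (per-edge,
#'   per-subject overdispersion).
#' @param lesion_fraction named proportions of patients per lesion side
#'   (`L`, `R`, optionally `bilateral`, `none`); must sum to 1.
#' @param lesion_loss proportion of fibers lost on edges incident to
#'   ipsilesional nodes, in `[0, 1)`.
#' @param ability_sdlog lognormal SD (log scale) of the latent ability
#'   factor scaling a test's planted edges across subjects.
#' @param ability_deficit mean proportional reduction of the patients'
#'   latent ability factor relative to controls, in `[0, 1)`.
#' @param n_planted number of planted edges per effect test.
#' @param r2_connectivity,r2_age,r2_education target population variance
#'   shares of the connectivity, age, and education terms in each score.
#' @param battery test battery table (see [cognitive_battery()]).
#' @param effect_tests test_ids that receive a planted connectivity
#'   effect; the remainder are pure covariate + noise scores.
#' @param planted_edges optional named list (per effect test) of flat
#'   unique-edge indices, overriding the random disjoint default.
#' @param edge_weights optional named numeric vector of fixed
#'   performance-scale weights per planted edge set; when `NULL` the
#'   weight is calibrated so the connectivity term attains
#'   `r2_connectivity`.
#' @param noise_sd optional named numeric vector of residual SDs per test
#'   (native units); `NULL` derives them from the variance shares.
#' @param patient_shift optional named numeric vector of additional mean
#'   performance deficits of patients (native units, performance scale);
#'   default 0 for effect tests and `0.45 * control_sd` for pure-noise
#'   tests, so every test shows some patient impairment.
#' @param seed integer seed; identical configs with identical seeds
#'   reproduce the cohort bit-identically.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_patients = 121L, n_controls = 121L,
                         parcellation = synthetic_parcellation(),
                         mean_fiber = c(intra_network = 160,
                                        intra_hemisphere = 80,
                                        inter_hemisphere = 25),
                         edge_log_sd = 1.0,
                         dispersion = 8,
                         lesion_fraction = c(L = 0.45, R = 0.45,
                                             none = 0.10),
                         lesion_loss = 0.175,
                         ability_sdlog = 0.45,
                         ability_deficit = 0.30,
                         n_planted = 30L,
                         r2_connectivity = 0.40,
                         r2_age = 0.06,
                         r2_education = 0.04,
                         battery = cognitive_battery(),
                         effect_tests = c("tmt_a", "tmt_b", "shopping_tour",
                                          "number_transcoding", "corsi_bw",
                                          "word_list_immediate",
                                          "word_list_delayed"),
                         planted_edges = NULL,
                         edge_weights = NULL,
                         noise_sd = NULL,
                         patient_shift = NULL,
                         seed = 1L) {
  stopifnot(n_patients >= 2, n_controls >= 2,
            inherits(parcellation, "parcellation"),
            all(c("intra_network", "intra_hemisphere", "inter_hemisphere")
                %in% names(mean_fiber)),
            all(mean_fiber > 0), dispersion > 0, edge_log_sd >= 0)
  if (lesion_loss < 0 || lesion_loss >= 1) {
    stop("lesion_loss must be in [0, 1)", call. = FALSE)
  }
  if (ability_deficit < 0 || ability_deficit >= 1) {
    stop("ability_deficit must be in [0, 1)", call. = FALSE)
  }
  if (any(lesion_fraction < 0) || abs(sum(lesion_fraction) - 1) > 1e-8) {
    stop("lesion_fraction must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!all(names(lesion_fraction) %in% c("L", "R", "bilateral", "none"))) {
    stop("lesion_fraction names must be among L, R, bilateral, none",
         call. = FALSE)
  }
  if (r2_connectivity + r2_age + r2_education >= 1) {
    stop("variance shares must sum to < 1", call. = FALSE)
  }
  if (!all(effect_tests %in% battery$test_id)) {
    stop("unknown effect test(s): ",
         paste(setdiff(effect_tests, battery$test_id), collapse = ", "),
         call. = FALSE)
  }
  eu <- edge_universe(nrow(parcellation))
  if (!is.null(planted_edges)) {
    idx <- unlist(planted_edges)
    if (any(idx < 1 | idx > eu$unique_edge_count)) {
      stop("planted edge indices out of range 1..", eu$unique_edge_count,
           call. = FALSE)
    }
    if (anyDuplicated(idx)) {
      stop("planted edge sets must be disjoint across tests", call. = FALSE)
    }
    if (!all(names(planted_edges) %in% effect_tests)) {
      stop("planted_edges names must be effect tests", call. = FALSE)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    parcellation = parcellation, mean_fiber = mean_fiber,
    edge_log_sd = edge_log_sd, dispersion = dispersion,
    lesion_fraction = lesion_fraction, lesion_loss = lesion_loss,
    ability_sdlog = ability_sdlog, ability_deficit = ability_deficit,
    n_planted = as.integer(n_planted),
    r2_connectivity = r2_connectivity, r2_age = r2_age,
    r2_education = r2_education, battery = battery,
    effect_tests = effect_tests, planted_edges = planted_edges,
    edge_weights = edge_weights, noise_sd = noise_sd,
    patient_shift = patient_shift, seed = as.integer(seed)),
    class = "synth_config")
}

# edge class of every unique edge: intra_network / intra_hemisphere /
# inter_hemisphere, from the parcellation's hemisphere + network labels
edge_classes <- function(parcellation) {
  eu <- edge_universe(nrow(parcellation))
  hi <- parcellation$hemisphere[eu$pairs[, "i"]]
  hj <- parcellation$hemisphere[eu$pairs[, "j"]]
  ni <- parcellation$network[eu$pairs[, "i"]]
  nj <- parcellation$network[eu$pairs[, "j"]]
  cls <- ifelse(hi != hj, "inter_hemisphere",
                ifelse(ni == nj, "intra_network", "intra_hemisphere"))
  list(universe = eu, class = cls,
       incident_L = hi == "L" | hj == "L",
       incident_R = hi == "R" | hj == "R")
}

#' Generate a synthetic patient + control cohort
#'
#' Draws fiber-count connectivity matrices, cognitive scores, covariates,
#' and matched control scores according to a [synth_config()], and records
#' the full generative ground truth (planted edge sets, native-scale model
#' coefficients, latent abilities) so recovery can be tested.
#'
#' The score model per test is linear in the realized fiber counts:
#' `score_i = intercept + sum_e w_e * fiber_ie + beta_age * age_i +
#' beta_edu * edu_i + eps_i`, with `eps ~ Normal(0, noise_sd)`. All
#' coefficients are reported on the native score scale (for time-scored
#' tests the performance model is sign-flipped into native units, so
#' `w_e` is negative there). Controls follow the same score model with no
#' lesion and no ability deficit; their fiber draws enter only through the
#' planted-edge sums.
#'
#' @param config a `synth_config`.
#' @return a `synth_cohort` list with elements `matrices` (list of
#'   [connectivity_matrix()]), `edges` (patients x unique-edges count
#'   matrix), `scores`, `covariates`, `controls` (score table),
#'   `parcellation`, `battery`, `truth`, and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  parc <- config$parcellation
  ec <- edge_classes(parc)
  eu <- ec$universe
  p <- eu$unique_edge_count
  n <- config$n_patients
  nc <- config$n_controls
  battery <- config$battery
  tests <- battery$test_id

  # baseline per-edge means: class mean x mean-preserving lognormal spread
  mu_e <- config$mean_fiber[ec$class] *
    rlnorm(p, meanlog = -config$edge_log_sd^2 / 2,
           sdlog = config$edge_log_sd)

  # planted edge sets, disjoint across effect tests
  planted <- config$planted_edges
  if (is.null(planted)) {
    pool <- sample.int(p)
    planted <- list()
    off <- 0L
    for (t in config$effect_tests) {
      planted[[t]] <- sort(pool[(off + 1L):(off + config$n_planted)])
      off <- off + config$n_planted
    }
  }

  # patient covariates
  age <- round(pmin(80, pmax(22, rnorm(n, 52, 11.6))))
  education <- pmin(10L, pmax(3L, round(rnorm(n, 7, 2))))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
  lesion_side <- sample(names(config$lesion_fraction), n, replace = TRUE,
                        prob = config$lesion_fraction)
  covariates <- data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    age = age, education = education, sex = sex,
    lesion_side = lesion_side,
    interval_months = round(rlnorm(n, log(14), 0.9)),
    n_surgery = 1L + rbinom(n, 1, 0.2),
    n_radiotherapy = sample(0:2, n, replace = TRUE,
                            prob = c(0.17, 0.71, 0.12)),
    n_chemotherapy = pmin(6L, stats::rpois(n, 1.6)),
    vol_cavity = round(rlnorm(n, log(15), 0.9), 1),
    vol_t1ce = round(rlnorm(n, log(3), 1.1), 1),
    vol_flair = round(rlnorm(n, log(40), 0.8), 1),
    vol_pet = round(rlnorm(n, log(2), 1.2), 1),
    idh = sample(c("wildtype", "mutant"), n, replace = TRUE,
                 prob = c(0.65, 0.35)),
    grade = sample(c(3L, 4L), n, replace = TRUE, prob = c(0.35, 0.65)),
    recurrence = sample(c("yes", "no"), n, replace = TRUE,
                        prob = c(0.48, 0.52)),
    location = sample(c("frontal", "temporal", "parietal", "occipital",
                        "other"), n, replace = TRUE,
                      prob = c(0.35, 0.30, 0.15, 0.05, 0.15)),
    stringsAsFactors = FALSE)

  # latent ability factors (mean 1), one per subject x test
  n_tests <- length(tests)
  g_pat <- matrix(rlnorm(n * n_tests, -config$ability_sdlog^2 / 2,
                         config$ability_sdlog), n, n_tests,
                  dimnames = list(NULL, tests))
  g_ctrl <- matrix(rlnorm(nc * n_tests, -config$ability_sdlog^2 / 2,
                          config$ability_sdlog), nc, n_tests,
                   dimnames = list(NULL, tests))

  # patient fiber counts (subjects x unique edges)
  MU <- matrix(mu_e, n, p, byrow = TRUE)
  for (t in names(planted)) {
    MU[, planted[[t]]] <- MU[, planted[[t]]] *
      (g_pat[, t] * (1 - config$ability_deficit))
  }
  X <- matrix(rnbinom(n * p, size = config$dispersion, mu = MU), n, p)

  # multiplicative fiber loss on edges incident to ipsilesional nodes
  keep <- 1 - config$lesion_loss
  scale_rows <- function(X, rows, cols) {
    if (length(rows)) X[rows, cols] <- round(X[rows, cols] * keep)
    X
  }
  X <- scale_rows(X, which(lesion_side == "L"), ec$incident_L)
  X <- scale_rows(X, which(lesion_side == "R"), ec$incident_R)
  X <- scale_rows(X, which(lesion_side == "bilateral"), seq_len(p))
  storage.mode(X) <- "integer"
  rownames(X) <- covariates$subject_id
  colnames(X) <- paste(eu$pairs[, "i"], eu$pairs[, "j"], sep = "_")

  # control covariates (matched design: same marginals, no tumor)
  age_c <- round(pmin(80, pmax(22, rnorm(nc, 52, 11.6))))
  edu_c <- pmin(10L, pmax(3L, round(rnorm(nc, 7, 2))))

  # control planted-edge fiber draws (no lesion, no ability deficit)
  s_ctrl <- matrix(0, nc, n_tests, dimnames = list(NULL, tests))
  s_pat <- matrix(0, n, n_tests, dimnames = list(NULL, tests))
  for (t in names(planted)) {
    e <- planted[[t]]
    MUc <- matrix(mu_e[e], nc, length(e), byrow = TRUE) * g_ctrl[, t]
    Xc <- matrix(rnbinom(nc * length(e), size = config$dispersion,
                         mu = MUc), nc, length(e))
    s_ctrl[, t] <- rowSums(Xc)
    s_pat[, t] <- rowSums(X[, e, drop = FALSE])
  }

  # score model per test
  age_ref <- 52; edu_ref <- 7
  age_sd_ref <- 11.6; edu_sd_ref <- 2
  scores <- data.frame(subject_id = covariates$subject_id,
                       stringsAsFactors = FALSE)
  controls <- data.frame(subject_id = sprintf("C%03d", seq_len(nc)),
                         age = age_c, education = edu_c,
                         stringsAsFactors = FALSE)
  truth_models <- list()
  for (k in seq_len(n_tests)) {
    t <- tests[k]
    spec <- battery[k, ]
    sgn <- direction_sign(spec)
    sigma <- spec$control_sd
    mu0 <- spec$control_mean
    is_effect <- t %in% names(planted)
    if (is_effect) {
      # center on the control mean (controls sit at the test's normative
      # mean); calibrate the weight on the patient summary SD so the
      # connectivity variance share is attained in the patient cohort
      center <- mean(s_ctrl[, t])
      scl <- sd(s_pat[, t])
      if (!is.finite(scl) || scl == 0) {
        stop("degenerate config: planted summary for '", t,
             "' has zero variance", call. = FALSE)
      }
      w_perf <- if (!is.null(config$edge_weights) &&
                    t %in% names(config$edge_weights)) {
        config$edge_weights[[t]]
      } else sqrt(config$r2_connectivity) * sigma / scl
      conn_pat <- w_perf * (s_pat[, t] - center)
      conn_ctrl <- w_perf * (s_ctrl[, t] - center)
    } else {
      center <- 0; w_perf <- 0
      conn_pat <- rep(0, n); conn_ctrl <- rep(0, nc)
    }
    beta_age <- -sqrt(config$r2_age) * sigma / age_sd_ref
    beta_edu <- sqrt(config$r2_education) * sigma / edu_sd_ref
    nsd <- if (!is.null(config$noise_sd) && t %in% names(config$noise_sd)) {
      config$noise_sd[[t]]
    } else {
      sigma * sqrt(max(0, 1 - is_effect * config$r2_connectivity -
                         config$r2_age - config$r2_education))
    }
    shift <- if (!is.null(config$patient_shift) &&
                 t %in% names(config$patient_shift)) {
      config$patient_shift[[t]]
    } else if (is_effect) 0 else 0.45 * sigma
    perf_pat <- conn_pat + beta_age * (age - age_ref) +
      beta_edu * (education - edu_ref) - shift + rnorm(n, 0, nsd)
    perf_ctrl <- conn_ctrl + beta_age * (age_c - age_ref) +
      beta_edu * (edu_c - edu_ref) + rnorm(nc, 0, nsd)
    scores[[t]] <- mu0 + sgn * perf_pat
    controls[[t]] <- mu0 + sgn * perf_ctrl
    if (sd(scores[[t]]) == 0) {
      stop("degenerate config: scores for '", t, "' have zero variance",
           call. = FALSE)
    }
    edge_w <- if (is_effect) setNames(rep(sgn * w_perf,
                                          length(planted[[t]])),
                                      planted[[t]]) else numeric(0)
    truth_models[[t]] <- list(
      intercept = mu0 + sgn * (-w_perf * center - beta_age * age_ref -
                                 beta_edu * edu_ref - shift),
      edge_weights = edge_w,
      beta_age = sgn * beta_age, beta_edu = sgn * beta_edu,
      noise_sd = nsd, patient_shift = shift, direction = spec$direction)
  }

  matrices <- lapply(seq_len(n), function(s) {
    connectivity_matrix(unvectorize_edges(X[s, ], eu$n_nodes),
                        subject_id = covariates$subject_id[s],
                        lesion_side = lesion_side[s],
                        parcellation = parc)
  })

  structure(list(
    matrices = matrices, edges = structure(X, edge_universe = eu),
    scores = scores, covariates = covariates,
    controls = controls[, c("subject_id", tests)],
    control_covariates = controls[, c("subject_id", "age", "education")],
    parcellation = parc, battery = battery,
    truth = list(planted_edges = planted, models = truth_models,
                 ability_patients = g_pat, ability_controls = g_ctrl,
                 effect_tests = names(planted)),
    config = config), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$edges), "patients,",
      nrow(x$controls), "controls,", nrow(x$parcellation), "nodes,",
      ncol(x$edges), "unique edges\n")
  cat("  planted effects in", length(x$truth$planted_edges), "of",
      nrow(x$battery), "tests\n")
  invisible(x)
}

#' Nodal fiber-count summaries
#'
#' Per-node fiber totals (to ipsilateral nodes and to all nodes) pooled
#' over subjects, summarized as median and range by hemisphere, plus an
#' ipsi- versus contralesional comparison of intra-hemispheric nodal
#' fiber counts for lesioned subjects (median counts, their ratio, and
#' the implied percent fiber loss).
#'
#' @param x a `synth_cohort`, a list of `connectivity_matrix` objects, or
#'   a single matrix.
#' @param parcellation required when `x` is not a `synth_cohort`.
#' @return list with `hemisphere_summary` (data frame of median/min/max
#'   nodal fiber totals by hemisphere, all-node and ipsilateral) and
#'   `lesion_summary` (medians, ratio, percent loss, number of lesioned
#'   subjects; `NULL` when no unilateral lesions are present).
#' @export
nodal_fiber_stats <- function(x, parcellation = NULL) {
  if (inherits(x, "synth_cohort")) {
    parcellation <- x$parcellation
    matrices <- x$matrices
  } else if (inherits(x, "connectivity_matrix") || is.matrix(x)) {
    matrices <- list(x)
  } else {
    matrices <- x
  }
  if (is.null(parcellation)) {
    stop("a parcellation is required", call. = FALSE)
  }
  hemi <- parcellation$hemisphere
  n_nodes <- nrow(parcellation)
  tot <- sapply(matrices, function(m) {
    rowSums(if (is.matrix(m)) unclass(m) else connectivity_values(m))
  })                                           # nodes x subjects
  ipsi <- sapply(matrices, function(m) {
    v <- if (is.matrix(m)) unclass(m) else connectivity_values(m)
    vapply(seq_len(n_nodes),
           function(i) sum(v[i, hemi == hemi[i]]), 0)
  })
  tot <- matrix(tot, nrow = n_nodes); ipsi <- matrix(ipsi, nrow = n_nodes)
  hemisphere_summary <- do.call(rbind, lapply(c("L", "R"), function(h) {
    rows <- hemi == h
    data.frame(hemisphere = h,
               median_total = median(tot[rows, ]),
               min_total = min(tot[rows, ]), max_total = max(tot[rows, ]),
               median_ipsilateral = median(ipsi[rows, ]),
               min_ipsilateral = min(ipsi[rows, ]),
               max_ipsilateral = max(ipsi[rows, ]))
  }))
  sides <- vapply(matrices, function(m) {
    s <- attr(m, "lesion_side")
    if (is.null(s) || is.na(s)) "none" else s
  }, "")
  lesioned <- which(sides %in% c("L", "R"))
  lesion_summary <- NULL
  if (length(lesioned)) {
    ipsi_vals <- unlist(lapply(lesioned, function(s) {
      ipsi[hemi == sides[s], s]
    }))
    contra_vals <- unlist(lapply(lesioned, function(s) {
      ipsi[hemi != sides[s], s]
    }))
    m_ipsi <- median(ipsi_vals); m_contra <- median(contra_vals)
    lesion_summary <- list(
      ipsilesional_median = m_ipsi, contralesional_median = m_contra,
      ratio = m_ipsi / m_contra,
      percent_loss = 100 * (1 - m_ipsi / m_contra),
      n_lesioned = length(lesioned))
  }
  list(hemisphere_summary = hemisphere_summary,
       lesion_summary = lesion_summary)
}
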