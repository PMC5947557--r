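test_that("landscape covariates match the stated moments and ranges", {
  cfg <- scenario_config(n_valley = 5000, n_andes = 5000)
  s <- generate_landscape_covariates(cfg, 123)
  expect_equal(nrow(s), 10000)
  expect_true(all(s$forest >= 1.8 & s$forest <= 76))
  expect_equal(mean(s$forest), 27.5, tolerance = 1.0)
  expect_true(all(s$shrub >= 9.1 & s$shrub <= 53.1))
  expect_equal(mean(s$shrub), 26, tolerance = 0.5)
  expect_true(all(s$patch_no >= 14 & s$patch_no <= 163))
  expect_equal(mean(s$patch_no), 52.9, tolerance = 1.5)
  expect_true(all(s$subdivision >= 1 & s$subdivision <= 314))
  expect_equal(mean(s$subdivision), 41.3, tolerance = 2.0)
  expect_true(all(s$patch_shape >= 1.3 & s$patch_shape <= 7.8))
  expect_true(all(s$edge >= 4755 & s$edge <= 48000))
  # redundant fragmentation metrics are strongly collinear by design
  expect_gt(abs(cor(s$forest, s$coh)), 0.7)
  expect_gt(abs(cor(s$patch_no, s$lsi)), 0.7)
  # infeasible truncation is refused
  expect_error(sociocc:::rtruncnorm(5, mean = 200, sd = 1, 0, 100),
               "does not contain")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- scenario_config()
  s1 <- generate_landscape_covariates(cfg, 7)
  s2 <- generate_landscape_covariates(cfg, 7)
  expect_identical(s1, s2)
  d1 <- generate_detection_data(cfg, s1, 8)
  d2 <- generate_detection_data(cfg, s1, 8)
  expect_identical(d1$data$y, d2$data$y)
  q1 <- generate_questionnaire(cfg, s1, 9)
  q2 <- generate_questionnaire(cfg, s1, 9)
  expect_identical(q1, q2)
})

test_that("detection generator honours degenerate truths", {
  cfg0 <- scenario_config(n_valley = 0, n_andes = 40,
                          truth_spec = occu_spec("markov_constant",
                                                 p = character()),
                          truth_params = c(8, -8, -8, -30),  # psi~1, p~0
                          miss_rate = 0)
  s <- generate_landscape_covariates(cfg0, 1)
  d0 <- generate_detection_data(cfg0, s, 2)
  expect_true(all(d0$data$y == 0, na.rm = TRUE))
  expect_true(all(d0$latent == 1))
  cfg1 <- scenario_config(n_valley = 0, n_andes = 40,
                          truth_spec = occu_spec("markov_constant",
                                                 p = character()),
                          truth_params = c(8, -8, -8, 30),  # psi~1, p~1
                          miss_rate = 0)
  d1 <- generate_detection_data(cfg1, s, 3)
  expect_true(all(d1$data$y[!is.na(d1$data$y)] == 1))
})

test_that("study shape: valley sites miss season 1, occasions in range", {
  b <- simulate_study(scenario_config(), seed = 33)
  expect_equal(dim(b$detections)[1], 145)
  valley <- b$sites$zone == "valley"
  expect_true(all(is.na(b$detections$y[valley, 1, ])))
  expect_false(all(is.na(b$detections$y[!valley, 1, ])))
  expect_true(all(b$detections$occasions_per_season %in% 10:12))
  expect_equal(nrow(b$questionnaire), 233)
  # every respondent's site exists
  expect_true(all(b$questionnaire$site_id %in% b$sites$site_id))
  # bundle writes and reads back
  dir <- withr::local_tempdir()
  write_study_bundle(b, dir)
  back <- read_detection_csv(file.path(dir, "detections.csv"))
  expect_equal(back$y, b$detections$y)
})

test_that("realised occupancy matches the generating model at scale", {
  cfg <- scenario_config(n_valley = 0, n_andes = 10000)
  s <- generate_landscape_covariates(cfg, 11)
  d <- generate_detection_data(cfg, s, 12)
  pr <- d$probabilities
  expect_equal(mean(d$latent[, 1]), mean(pr$psi), tolerance = 0.01)
  # one-step Markov update for season 2
  psi2 <- pr$psi * (1 - pr$eps[, 1]) + (1 - pr$psi) * pr$gamma[, 1]
  expect_equal(mean(d$latent[, 2]), mean(psi2), tolerance = 0.01)
})

test_that("questionnaire marginals and the RRT yes-rate are as designed", {
  cfg <- scenario_config(n_respondents = 50000)
  s <- generate_landscape_covariates(cfg, 3)
  q <- generate_questionnaire(cfg, s, 21)
  expect_equal(mean(q$true_kill), 0.10, tolerance = 0.01)
  # yes-proportion = p_fy + (1 - p_fy - p_fn) E[pi], within +/- 0.005
  expect_lt(abs(mean(q$rrt_answer) - (1/6 + (2/3) * 0.10)), 0.005)
  # encounter marginals: 49% ever saw the species, 21% within the decade
  expect_equal(mean(q$fq_encounter > 0), 0.49, tolerance = 0.02)
  expect_equal(mean(q$fq_encounter >= 2), 0.21, tolerance = 0.02)
  expect_equal(median(q$age), 55, tolerance = 1)
  # the signal-present diagnostic: yes-rate exceeds the forcing floor
  # whenever prevalence is positive
  expect_gt(mean(q$rrt_answer), 1/6)
  cfg0 <- scenario_config(prevalence = 0, design = rrt_design(0, 0),
                          n_respondents = 500)
  q0 <- generate_questionnaire(cfg0, s, 5)
  expect_true(all(q0$rrt_answer == 0))
})

test_that("a generated bundle runs the whole analysis pipeline", {
  b <- simulate_study(scenario_config(), seed = 61)
  cov_std <- standardise_covariates(b$sites,
                                    exclude = c("forest", "shrub", "x", "y"))
  fit <- fit_occupancy(b$detections, b$config$truth_spec, cov_std,
                       n_starts = 3, seed = 1)
  expect_true(fit$converged)
  g <- mb_gof(fit, n_boot = 20, seed = 2)
  expect_true(g$p_global >= 0 && g$p_global <= 1)
  pts <- detection_rates(b$detections, b$sites)
  m <- moran_test(pts[pts$season == "season_2", ], band = 3000,
                  n_perm = 99, seed = 3)
  expect_true(is.finite(m$I))
  q <- b$questionnaire
  prev <- rrt_prevalence(sum(q$rrt_answer), nrow(q), b$config$design)
  expect_true(is.finite(prev$estimate))
  ci <- rrt_bootstrap_ci(q$rrt_answer, b$config$design, n_boot = 200,
                         seed = 4)
  expect_true(ci$lower <= ci$upper)
})
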