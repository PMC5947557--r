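#' Scenario configuration for the study-shaped synthetic data generator
#'
#' Defaults reproduce the shape of a two-zone camera-trap and questionnaire
#' study: 145 sample units of 4 km^2 (73 in an intensively farmed central
#' valley surveyed in seasons 2-4 only, 72 in Andean valleys surveyed in all
#' 4 seasons), 10-12 two-day occasions per unit per season from pooled
#' camera pairs with a small malfunction/theft missingness rate, 233
#' questionnaire respondents (one household per unit plus a second where
#' needed), and a symmetric forced-response design with forcing probability
#' 1/6. The generating occupancy truth follows the final-model structure of
#' the study system: initial occupancy declining weakly with forest cover
#' (on the raw percentage scale), season-specific extinction decreasing with
#' patch number and increasing with land subdivision (z-score scales),
#' season-specific colonisation, and detection increasing with understorey
#' density.
#'
#' @param n_valley,n_andes Number of sample units per zone.
#' @param n_seasons Number of survey seasons (valley units miss season 1).
#' @param occasion_range Integer vector of possible occasions per
#'   site-season.
#' @param miss_rate Probability an individual scheduled occasion is missing
#'   (camera malfunction or theft).
#' @param truth_spec,truth_params Generating model and coefficient vector
#'   (on the logit scale, covariates standardised except percentages).
#' @param n_respondents Questionnaire sample size.
#' @param prevalence True prevalence of the sensitive behaviour.
#' @param design An [rrt_design()].
#' @param encounter_log_or Log-odds-ratio linking the (z-scored) encounter
#'   frequency to the latent behaviour; set 0 for no dependence.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_valley = 73, n_andes = 72, n_seasons = 4,
                            occasion_range = 10:12, miss_rate = 0.03,
                            truth_spec = NULL, truth_params = NULL,
                            n_respondents = 233, prevalence = 0.10,
                            design = rrt_design(),
                            encounter_log_or = 0.85) {
  if (is.null(truth_spec)) {
    truth_spec <- occu_spec("markov_seasonal", psi1 = "forest",
                            eps = c("season", "patch_no", "subdivision"),
                            gamma = "season",
                            p = c("season", "understorey"))
  }
  if (is.null(truth_params)) {
    Tm1 <- n_seasons - 1
    truth_params <- c(
      # psi1: ~0.78 at the mean forest cover of 27.5%, slope per % point
      2.26, -0.0363,
      # eps: season intercepts at ~0.2, patch-number and subdivision slopes
      rep(logit(0.2), Tm1), -0.90, 0.944,
      # gamma: season intercepts at ~0.4
      rep(logit(0.4), Tm1),
      # p: season intercepts at ~0.15 over 2 nights, understorey slope
      rep(logit(0.15), n_seasons), 0.343
    )
  }
  stopifnot(prevalence >= 0, prevalence <= 1,
            length(truth_params) == count_parameters(truth_spec, n_seasons))
  structure(list(
    n_valley = n_valley, n_andes = n_andes, n_sites = n_valley + n_andes,
    n_seasons = n_seasons, occasion_range = occasion_range,
    miss_rate = miss_rate, truth_spec = truth_spec,
    truth_params = truth_params, n_respondents = n_respondents,
    prevalence = prevalence, design = design,
    encounter_log_or = encounter_log_or
  ), class = "scenario_config")
}

# Percentage-scale covariates exempt from z-scoring throughout.
percentage_covariates <- function() c("forest", "shrub")

#' Generate landscape/social covariates and site coordinates
#'
#' Continuous covariates are drawn from truncated normals matching reported
#' landscape moments (forest 27.5 +/- 18.9% in [1.8, 76]; shrub 26 +/- 8.3%
#' in [9.1, 53.1]; patch number 52.9 +/- 25.7 in [14, 163]; patch shape
#' 3.13 +/- 1.3 in [1.3, 7.8]; edge in [4755, 48000] m; subdivision
#' 41.3 +/- 37.2 in [1, 314] properties); counts are rounded to integers.
#' Redundant fragmentation metrics (weighted patch area, gyration, cohesion
#' tracking forest cover; landscape shape index tracking patch number) are
#' generated collinear with their parent metric so the collinearity screen
#' has realistic work to do. Sites sit on a 2 x 2 km grid, one block per
#' zone.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per site: `site_id`, `zone`, `x`, `y`,
#'   habitat-configuration and human-predator covariates, and detection
#'   level survey covariates (ordinal scales documented in the package
#'   vignette).
#' @export
generate_landscape_covariates <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- config$n_sites
  # 2-km grid, valley block west, Andes block 30 km further east
  cols <- ceiling(sqrt(config$n_valley))
  vx <- (seq_len(config$n_valley) - 1) %% cols
  vy <- (seq_len(config$n_valley) - 1) %/% cols
  cols_a <- ceiling(sqrt(config$n_andes))
  ax <- (seq_len(config$n_andes) - 1) %% cols_a
  ay <- (seq_len(config$n_andes) - 1) %/% cols_a
  forest <- rtruncnorm(n, 27.5, 18.9, 1.8, 76)
  patch_no <- round(rtruncnorm(n, 52.9, 25.7, 14, 163))
  zf <- as.vector(scale(forest)); zp <- as.vector(scale(patch_no))
  ord <- function(n, probs) {
    sample(seq_along(probs) - 1L, n, replace = TRUE, prob = probs)
  }
  tibble::tibble(
    site_id = sprintf("su_%03d", seq_len(n)),
    zone = c(rep("valley", config$n_valley), rep("andes", config$n_andes)),
    x = c(vx * 2000, 30000 + ax * 2000),
    y = c(vy * 2000, ay * 2000),
    forest = forest,
    shrub = rtruncnorm(n, 26, 8.3, 9.1, 53.1),
    patch_no = patch_no,
    patch_shape = rtruncnorm(n, 3.13, 1.3, 1.3, 7.8),
    edge = rtruncnorm(n, 20000, 9000, 4755, 48000),
    patch_area_w = pmax(2 + 3 * zf + stats::rnorm(n, 0, 1.2), 0.2),
    gyration = pmax(150 + 70 * zf + stats::rnorm(n, 0, 30), 10),
    coh = pmin(pmax(85 + 8 * zf + stats::rnorm(n, 0, 3.5), 40), 100),
    lsi = pmax(8 + 2.5 * zp + stats::rnorm(n, 0, 1), 1),
    subdivision = round(rtruncnorm(n, 41.3, 37.2, 1, 314)),
    dogs = stats::rpois(n, 2),
    predation = stats::rbinom(n, 1, 0.16),
    fq_predation = ord(n, c(0.84, 0.09, 0.05, 0.02)),
    fq_encounter = ord(n, c(0.51, 0.28, 0.11, 0.10)),
    intent = ord(n, c(0.35, 0.27, 0.38)),
    understorey = ord(n, c(0.15, 0.3, 0.35, 0.2)) + 1L,
    bamboo = ord(n, c(0.3, 0.3, 0.25, 0.15)) + 1L,
    livestock = ord(n, c(0.3, 0.3, 0.25, 0.15)),
    logging = ord(n, c(0.5, 0.25, 0.15, 0.1)),
    water = ord(n, c(0.25, 0.35, 0.25, 0.15)),
    rotation = sample(1:4, n, replace = TRUE)
  )
}

# Standardise the covariates a truth spec references, leaving percentages
# on their natural scale (matching the analysis convention).
standardise_for_truth <- function(covariates, spec) {
  used <- setdiff(unique(c(spec$psi1, spec$eps, spec$gamma, spec$p)), "season")
  to_z <- setdiff(used, percentage_covariates())
  out <- covariates
  for (cv in to_z) out[[cv]] <- as.vector(scale(out[[cv]]))
  out
}

#' Generate detection histories under a known occupancy truth
#'
#' Latent occupancy is drawn from the generating initial-occupancy model and
#' propagated through the seasonal Markov dynamics; detections are Bernoulli
#' trials with the generating detection probability where the site is
#' occupied and structural zeros elsewhere. Central-valley sites have their
#' entire first season missing; each remaining scheduled occasion is
#' independently missing with `config$miss_rate`.
#'
#' @param config A [scenario_config()].
#' @param covariates Output of [generate_landscape_covariates()].
#' @param seed Integer seed.
#' @return A list with `data` (a [detection_array()]), `latent` (site x
#'   season 0/1 matrix of true occupancy), and `probabilities` (the
#'   generating psi/eps/gamma/p components).
#' @export
generate_detection_data <- function(config, covariates, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- nrow(covariates); T <- config$n_seasons
  J <- max(config$occasion_range)
  cov_std <- standardise_for_truth(covariates, config$truth_spec)
  pr <- spec_probabilities(config$truth_spec, config$truth_params, cov_std, T)
  occ_pool <- config$occasion_range
  occ_count <- matrix(occ_pool[sample.int(length(occ_pool), n * T,
                                          replace = TRUE)], n, T)
  observed <- array(FALSE, dim = c(n, T, J))
  for (t in seq_len(T)) {
    for (j in seq_len(J)) observed[, t, j] <- j <= occ_count[, t]
  }
  observed[covariates$zone == "valley", 1, ] <- FALSE
  drop <- array(stats::runif(n * T * J) < config$miss_rate, dim = c(n, T, J))
  observed <- observed & !drop
  # every site must retain at least one observed occasion
  none <- apply(observed, 1, function(m) !any(m))
  if (any(none)) {
    first_season <- ifelse(covariates$zone[none] == "valley", 2L, 1L)
    for (k in seq_along(which(none))) {
      observed[which(none)[k], first_season[k], 1] <- TRUE
    }
  }
  sim <- simulate_detections_from_probs(pr, observed,
                                        apply(occ_count, 2, max))
  data <- detection_array(sim$y, site_ids = covariates$site_id,
                          season_labels = sprintf("season_%d", seq_len(T)),
                          occasions_per_season = apply(occ_count, 2, max))
  list(data = data, latent = sim$z, probabilities = pr)
}

#' Generate questionnaire records with forced-response RRT answers
#'
#' Respondents are attached to sample units (one household per unit, a
#' second household where needed to reach `n_respondents`). Socio-demographic
#' marginals emulate the study population (median age 55, IQR ~46-67;
#' encounter-frequency distribution with 49% lifetime, 21% decade, 10%
#' recent sightings; 16% lifetime predation reports). The latent sensitive
#' behaviour is Bernoulli with probability following a logistic model in the
#' z-scored encounter frequency (log-OR `config$encounter_log_or`), with the
#' intercept calibrated so the population mean equals `config$prevalence`.
#' The recorded answer is forced "yes" or "no" with the design's forcing
#' probabilities and truthful otherwise.
#'
#' @param config A [scenario_config()].
#' @param covariates Output of [generate_landscape_covariates()].
#' @param seed Integer seed.
#' @return A tibble with one row per respondent: identifiers, predictors,
#'   the latent `true_kill` status (synthetic truth, retained for
#'   validation) and the recorded `rrt_answer`.
#' @export
generate_questionnaire <- function(config, covariates, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n_sites <- nrow(covariates)
  n <- config$n_respondents
  site_idx <- if (n <= n_sites) {
    sample.int(n_sites, n)
  } else if (n <= 2 * n_sites) {
    c(seq_len(n_sites), sample.int(n_sites, n - n_sites))
  } else {
    # oversized validation runs: spread the surplus at random
    c(rep(seq_len(n_sites), 2),
      sample.int(n_sites, n - 2 * n_sites, replace = TRUE))
  }
  fq <- sample(0:3, n, replace = TRUE, prob = c(0.51, 0.28, 0.11, 0.10))
  z_fq <- as.vector(scale(fq))
  b_or <- config$encounter_log_or
  pi_of <- function(b0) mean(inv_logit(b0 + b_or * z_fq))
  b0 <- if (config$prevalence == 0) -Inf else if (config$prevalence == 1) Inf
    else stats::uniroot(function(b0) pi_of(b0) - config$prevalence,
                        c(-30, 30))$root
  pi_i <- if (is.finite(b0)) inv_logit(b0 + b_or * z_fq)
    else rep(config$prevalence, n)
  kill <- stats::rbinom(n, 1, pi_i)
  u <- stats::runif(n)
  ans <- ifelse(u < config$design$p_forced_yes, 1L,
                ifelse(u < config$design$p_forced_yes +
                         config$design$p_forced_no, 0L, kill))
  tibble::tibble(
    respondent_id = sprintf("r_%03d", seq_len(n)),
    site_id = covariates$site_id[site_idx],
    age = round(rtruncnorm(n, 55, 15.6, 18, 92)),
    income = round(stats::rlnorm(n, log(400), 0.9)),
    dependency = sample(1:3, n, replace = TRUE, prob = c(0.35, 0.4, 0.25)),
    chickens = stats::rpois(n, 12),
    knowledge = sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
    intent = sample(0:2, n, replace = TRUE, prob = c(0.35, 0.27, 0.38)),
    fq_encounter = fq,
    true_kill = kill,
    rrt_answer = as.integer(ans)
  )
}

#' Generate a complete study-shaped dataset
#'
#' Convenience wrapper running the three generators with seeds derived from
#' one root seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer root seed.
#' @return A list of class `study_bundle` with `sites`, `detections`,
#'   `latent`, `questionnaire` and `config`.
#' @export
simulate_study <- function(config = scenario_config(), seed = 1L) {
  sites <- generate_landscape_covariates(config, derive_seed(seed, 1))
  det <- generate_detection_data(config, sites, derive_seed(seed, 2))
  quest <- generate_questionnaire(config, sites, derive_seed(seed, 3))
  structure(list(sites = sites, detections = det$data, latent = det$latent,
                 questionnaire = quest, config = config),
            class = "study_bundle")
}

#' Write a study bundle as plain-text CSV files
#'
#' Writes `detections.csv` (wide layout), `sites.csv` and
#' `questionnaire.csv` under `dir`.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_detection_csv(bundle$detections, file.path(dir, "detections.csv"))
  readr::write_csv(bundle$sites, file.path(dir, "sites.csv"), na = "NA")
  readr::write_csv(bundle$questionnaire,
                   file.path(dir, "questionnaire.csv"), na = "NA")
  invisible(dir)
}
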