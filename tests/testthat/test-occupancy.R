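test_that("parameter counts follow the block rules", {
  expect_equal(count_parameters(occu_spec("markov_constant", p = character()), 4), 4)
  expect_equal(count_parameters(occu_spec("markov_constant", p = "season"), 4), 7)
  expect_equal(count_parameters(occu_spec("markov_seasonal", p = "season"), 4), 11)
  expect_equal(count_parameters(occu_spec("equilibrium", p = "season"), 4), 6)
  expect_equal(count_parameters(occu_spec("random_changes", p = "season"), 4), 6)
  expect_equal(
    count_parameters(occu_spec("random_changes", gamma = "season",
                               p = "season"), 4), 8)
  # static: one occupancy intercept plus seasonal detection
  expect_equal(count_parameters(occu_spec("static", p = "season"), 4), 5)
  expect_equal(
    count_parameters(occu_spec("markov_seasonal",
                               p = c("season", "understorey")), 4), 12)
  expect_equal(
    count_parameters(occu_spec("markov_seasonal", psi1 = "forest",
                               eps = c("season", "patch_no", "subdivision"),
                               gamma = "season",
                               p = c("season", "understorey")), 4), 15)
  expect_error(spec_blocks(occu_spec("static"), 1), "n_seasons")
})

test_that("hand-checkable likelihood values are exact", {
  # one site, one season observed, one occasion, y = 1, psi = 1, p = 0.5
  y <- array(NA_real_, dim = c(1, 2, 1)); y[1, 1, 1] <- 1
  da <- detection_array(y)
  spec <- occu_spec("static", p = character())
  # params: psi intercept, p intercept (logit scale); push psi ~ 1
  nll <- occu_nll(c(30, 0), spec, da, tibble::tibble(.rows = 1))
  expect_equal(nll, -log(0.5), tolerance = 1e-9)

  # all-zero site with the second season fully missing:
  # L = psi (1-p)^J + (1-psi), independent of the dynamics
  J <- 3
  y2 <- array(NA_real_, dim = c(1, 2, J)); y2[1, 1, ] <- 0
  da2 <- detection_array(y2)
  spec2 <- occu_spec("markov_constant", p = character())
  th <- c(0.3, -0.2, 0.1, -0.4)  # psi1, eps, gamma, p
  psi <- plogis(0.3); p <- plogis(-0.4)
  expect_equal(occu_nll(th, spec2, da2, tibble::tibble(.rows = 1)),
               -log(psi * (1 - p)^J + (1 - psi)), tolerance = 1e-10)
})

test_that("forward recursion equals latent-sequence enumeration", {
  set.seed(101)
  for (r in 1:20) {
    T <- sample(2:6, 1)
    n <- sample(3:8, 1)
    J <- sample(2:4, 1)
    da <- random_instance(n, T, J)
    spec <- occu_spec("markov_seasonal", p = "season")
    th <- rnorm(count_parameters(spec, T))
    got <- occu_nll(th, spec, da, tibble::tibble(.rows = n))
    want <- enumerate_nll(da$y, plogis(th[1]), plogis(th[2:T]),
                          plogis(th[(T + 1):(2 * T - 1)]),
                          plogis(th[(2 * T):(3 * T - 1)]))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to permuting occasions within a season", {
  set.seed(21)
  da <- random_instance(15, 3, 5)
  spec <- occu_spec("markov_seasonal", p = "season")
  th <- rnorm(count_parameters(spec, 3))
  base <- occu_nll(th, spec, da, tibble::tibble(.rows = 15))
  y2 <- da$y
  for (t in 1:3) y2[, t, ] <- y2[, t, sample(5)]
  da2 <- detection_array(y2)
  expect_equal(occu_nll(th, spec, da2, tibble::tibble(.rows = 15)), base,
               tolerance = 1e-12)
})

test_that("analytic gradient matches finite differences for every dynamics", {
  set.seed(77)
  da <- random_instance(25, 4, 4)
  st <- sociocc:::detection_stats(da)
  cov <- tibble::tibble(a = rnorm(25), b = rnorm(25))
  specs <- list(
    occu_spec("markov_seasonal", psi1 = "a", eps = c("season", "b"),
              gamma = "season", p = c("season", "a")),
    occu_spec("markov_constant", psi1 = "a", eps = "b", p = "season"),
    occu_spec("equilibrium", psi1 = "a", gamma = "b", p = "season"),
    occu_spec("random_changes", psi1 = "a", gamma = c("season", "b"),
              p = "season"),
    occu_spec("static", psi1 = "a", p = c("season", "b"))
  )
  for (sp in specs) {
    mf <- sociocc:::build_model_frame(sp, cov, 4)
    th <- rnorm(count_parameters(sp, 4), 0, 0.6)
    if (sp$dynamics == "equilibrium") th[3:4] <- c(-1.5, -1.5)
    got <- sociocc:::nll_with_grad(th, mf, st)
    fd <- vapply(seq_along(th), function(i) {
      h <- 1e-6
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      (sociocc:::nll_core(tp, mf, st) - sociocc:::nll_core(tm, mf, st)) /
        (2 * h)
    }, numeric(1))
    expect_equal(got$grad, fd, tolerance = 1e-5)
    expect_equal(got$value, sociocc:::nll_core(th, mf, st))
  }
})

test_that("static fit matches a direct grid-search single-season MLE", {
  set.seed(55)
  n <- 120; J <- 5
  z <- rbinom(n, 1, 0.6)
  y <- array(NA_real_, dim = c(n, 2, J))
  y[, 1, ] <- rbinom(n * J, 1, 0.45) * z
  y[, 2, 1] <- y[, 1, 1]  # static world: second season replicates state
  da <- detection_array(y)
  st <- sociocc:::detection_stats(da)
  fit <- fit_occupancy(da, occu_spec("static", p = character()),
                       n_starts = 3, seed = 1)
  oracle <- grid_search_single_season(st$d[, 1] + st$d[, 2],
                                      st$nn[, 1] + st$nn[, 2])
  expect_true(fit$converged)
  expect_equal(plogis(fit$coefficients[["psi1_(Intercept)"]]), oracle$psi,
               tolerance = 1e-2)
  expect_equal(plogis(fit$coefficients[["p_(Intercept)"]]), oracle$p,
               tolerance = 1e-2)
  expect_equal(fit$neg2loglik, 2 * oracle$nll, tolerance = 1e-4 * oracle$nll)
})

test_that("refit is invariant to site order and AIC identity holds", {
  set.seed(66)
  cfg <- scenario_config(n_valley = 0, n_andes = 120,
                         truth_spec = occu_spec("markov_constant",
                                                psi1 = "forest",
                                                p = "season"),
                         truth_params = c(1.2, -0.03, qlogis(0.2),
                                          qlogis(0.3), rep(qlogis(0.4), 4)),
                         miss_rate = 0.05)
  sites <- generate_landscape_covariates(cfg, 21)
  da <- generate_detection_data(cfg, sites, 22)$data
  cov <- tibble::tibble(a = sites$forest)
  spec <- occu_spec("markov_constant", psi1 = "a", p = "season")
  f1 <- fit_occupancy(da, spec, cov, n_starts = 2, seed = 9)
  perm <- sample(120)
  da2 <- detection_array(da$y[perm, , ], da$site_ids[perm],
                         da$season_labels, da$occasions_per_season)
  f2 <- fit_occupancy(da2, spec, cov[perm, ], n_starts = 2, seed = 9)
  expect_equal(f1$neg2loglik, f2$neg2loglik, tolerance = 1e-8)
  expect_equal(f1$aic, f1$neg2loglik + 2 * f1$K, tolerance = 1e-9)
  expect_true(all(f1$se >= 0, na.rm = TRUE))
})

test_that("derived occupancy obeys the dynamics algebra", {
  # fit each constrained structure to data generated from its own world so
  # the estimates stay interior
  world <- function(spec, params, seed) {
    cfg <- scenario_config(n_valley = 0, n_andes = 150, truth_spec = spec,
                           truth_params = params, miss_rate = 0)
    sites <- generate_landscape_covariates(cfg, seed)
    generate_detection_data(cfg, sites, seed + 1)$data
  }
  # static: psi constant across seasons
  sp_s <- occu_spec("static", p = character())
  f_static <- fit_occupancy(world(sp_s, c(0.4, 0), 301), sp_s,
                            n_starts = 2, seed = 2)
  d_static <- derived_occupancy(f_static)
  expect_equal(d_static$psi, rep(d_static$psi[1], 4), tolerance = 1e-12)
  # random changes: psi_{t+1} = gamma_t regardless of psi_t
  sp_r <- occu_spec("random_changes", p = character())
  f_rand <- fit_occupancy(world(sp_r, c(0.2, -0.4, 0), 303), sp_r,
                          n_starts = 2, seed = 2)
  d_rand <- derived_occupancy(f_rand)
  gam <- plogis(f_rand$coefficients[["gamma_(Intercept)"]])
  expect_equal(d_rand$psi[-1], rep(gam, 3), tolerance = 1e-10)
  # equilibrium: constant by construction
  sp_e <- occu_spec("equilibrium", p = character())
  f_eq <- fit_occupancy(world(sp_e, c(0.8, -1.2, 0), 305), sp_e,
                        n_starts = 2, seed = 2)
  d_eq <- derived_occupancy(f_eq)
  expect_equal(d_eq$psi, rep(d_eq$psi[1], 4), tolerance = 1e-10)
})

test_that("prediction curves respect link monotonicity and CI arithmetic", {
  set.seed(14)
  cfg <- scenario_config(n_valley = 0, n_andes = 150)
  sites <- generate_landscape_covariates(cfg, 4)
  det <- generate_detection_data(cfg, sites, 5)
  cov_std <- standardise_covariates(sites,
                                    exclude = c("forest", "shrub", "x", "y"))
  spec <- occu_spec("markov_seasonal", psi1 = "forest", gamma = "season",
                    p = c("season", "understorey"))
  fit <- fit_occupancy(det$data, spec, cov_std, n_starts = 2, seed = 8)
  pred <- predict_parameter(fit, "p", "understorey")
  beta <- fit$coefficients[["p_understorey"]]
  expect_true(all(diff(pred$estimate) * sign(beta) >= 0))
  expect_true(all(pred$lower <= pred$estimate & pred$estimate <= pred$upper))
  # shrinking vcov by 4 halves the linear-scale CI width
  fit2 <- fit
  fit2$vcov <- fit$vcov / 4
  pred2 <- predict_parameter(fit2, "p", "understorey")
  w1 <- qlogis(pred$upper) - qlogis(pred$lower)
  w2 <- qlogis(pred2$upper) - qlogis(pred2$lower)
  expect_equal(w2, w1 / 2, tolerance = 1e-9)
  expect_error(predict_parameter(fit, "p", "bamboo"), "not in the p formula")
})
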