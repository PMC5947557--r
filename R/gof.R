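# Goodness-of-fit on detection-history frequencies.
#
# For each season, sites are grouped into cohorts sharing a missingness
# pattern. Within a cohort the expected count of an observed history h is
# the sum over sites of
#   P_i(h) = psi_it * p_it^d (1 - p_it)^(J - d) + (1 - psi_it) * 1{d = 0},
# where psi_it is the marginal occupancy of site i in season t obtained by
# propagating initial occupancy through the fitted dynamics, d the number of
# detections in h and J the number of observed occasions. Unobserved
# histories are absorbed into a catch-all cell (O = 0, E = cohort size minus
# the expected mass of observed histories); observed cells with E < 0.5 are
# pooled into the catch-all, standard sparse-cell practice. The season
# statistic is Pearson's X^2 over the resulting cells; the global statistic
# sums the seasons.

season_statistic <- function(y_season, psi_t, p_t, pool_threshold = 0.5) {
  J_all <- ncol(y_season)
  obs_mask <- !is.na(y_season)
  J_i <- rowSums(obs_mask)
  use <- J_i > 0  # sites with the season fully missing are excluded
  if (!any(use)) return(0)
  pattern <- apply(obs_mask[use, , drop = FALSE], 1, paste, collapse = "")
  hist_str <- apply(y_season[use, , drop = FALSE], 1, function(v) {
    paste(ifelse(is.na(v), "-", v), collapse = "")
  })
  d_i <- rowSums(y_season[use, , drop = FALSE] == 1, na.rm = TRUE)
  psi_u <- psi_t[use]; p_u <- p_t[use]; J_u <- J_i[use]
  x2 <- 0
  for (pat in unique(pattern)) {
    in_c <- pattern == pat
    hs <- hist_str[in_c]
    tab <- table(hs)
    # probability of each distinct observed history for each cohort site
    d_of <- vapply(names(tab), function(h) {
      sum(strsplit(h, "")[[1]] == "1")
    }, numeric(1))
    idx <- which(in_c)
    E <- vapply(seq_along(tab), function(k) {
      dk <- d_of[k]
      sum(psi_u[idx] * p_u[idx]^dk * (1 - p_u[idx])^(J_u[idx] - dk) +
            (1 - psi_u[idx]) * (dk == 0))
    }, numeric(1))
    O <- as.numeric(tab)
    e_other <- max(sum(in_c) - sum(E), 0)
    small <- E < pool_threshold
    if (any(small)) {
      e_other <- e_other + sum(E[small])
      o_other <- sum(O[small])
      E <- E[!small]; O <- O[!small]
    } else {
      o_other <- 0
    }
    if (length(E)) x2 <- x2 + sum((O - E)^2 / E)
    if (e_other > 1e-12) x2 <- x2 + (o_other - e_other)^2 / e_other
  }
  x2
}

#' Detection-history fit statistic
#'
#' Pearson chi-square statistic comparing observed and model-expected
#' frequencies of detection histories, computed per season (conditioning on
#' each site's missingness cohort, with seasons-after-the-first using the
#' marginal occupancy implied by the fitted dynamics) and summed into a
#' global statistic.
#'
#' @param fit A converged `occu_fit`.
#' @param data Optional [detection_array()] (defaults to the fit's data;
#'   supplied explicitly for bootstrap replicates).
#' @return A list with `global` (numeric) and `per_season` (numeric vector).
#' @export
mb_statistic <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  data <- data %||% fit$data
  T <- fit$n_seasons
  psi_mat <- occupancy_trajectory(fit$coefficients, fit$spec,
                                  fit$covariates, T)
  pr <- spec_probabilities(fit$spec, fit$coefficients, fit$covariates, T)
  per_season <- vapply(seq_len(T), function(t) {
    season_statistic(data$y[, t, , drop = TRUE], psi_mat[, t], pr$p[, t])
  }, numeric(1))
  list(global = sum(per_season), per_season = per_season)
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates `n_boot` datasets from the fitted model (preserving the
#' observed missingness pattern), refits the model to each and recomputes
#' the detection-history statistic. The p-value is the proportion of
#' bootstrap statistics greater than or equal to the observed one
#' (inclusive); `c_hat` is the observed statistic divided by the mean
#' bootstrap statistic, an overdispersion gauge.
#'
#' @param fit A converged `occu_fit`.
#' @param n_boot Number of bootstrap iterations (5000 for production use;
#'   reduce for exploratory runs).
#' @param seed Integer seed.
#' @return An object of class `occu_gof`: observed global and per-season
#'   statistics, bootstrap p-values, `c_hat`, `n_boot`, and the count of
#'   non-convergent refits (a warning is recorded when they exceed 10%).
#' @export
mb_gof <- function(fit, n_boot = 5000, seed = 1L) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!fit$converged) stop("goodness-of-fit requires a converged fit",
                           call. = FALSE)
  obs <- mb_statistic(fit)
  T <- fit$n_seasons
  observed_mask <- !is.na(fit$data$y)
  pr <- spec_probabilities(fit$spec, fit$coefficients, fit$covariates, T)
  boot_global <- rep(NA_real_, n_boot)
  boot_season <- matrix(NA_real_, n_boot, T)
  n_fail <- 0L
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    sim <- simulate_detections_from_probs(pr, observed_mask,
                                          fit$data$occasions_per_season)
    sim_data <- tryCatch(
      detection_array(sim$y, fit$data$site_ids, fit$data$season_labels,
                      fit$data$occasions_per_season),
      error = function(e) NULL
    )
    refit <- if (is.null(sim_data)) NULL else tryCatch(
      suppressWarnings(
        fit_occupancy(sim_data, fit$spec, fit$covariates, n_starts = 1,
                      init = unname(fit$coefficients))),
      error = function(e) NULL
    )
    if (is.null(refit) || !refit$converged) {
      n_fail <- n_fail + 1L
      # fall back to the generating parameters so the replicate still
      # contributes a statistic rather than biasing the null sample
      if (is.null(sim_data)) next
      refit <- fit
      st <- mb_statistic(refit, data = sim_data)
    } else {
      st <- mb_statistic(refit, data = sim_data)
    }
    boot_global[b] <- st$global
    boot_season[b, ] <- st$per_season
  }
  ok <- !is.na(boot_global)
  warn <- NULL
  if (n_fail > 0.1 * n_boot) {
    warn <- sprintf("%d of %d bootstrap refits failed to converge",
                    n_fail, n_boot)
    warning(warn)
  }
  structure(list(
    observed_global = obs$global,
    observed_per_season = obs$per_season,
    p_global = mean(boot_global[ok] >= obs$global),
    p_per_season = vapply(seq_len(T), function(t) {
      mean(boot_season[ok, t] >= obs$per_season[t])
    }, numeric(1)),
    c_hat = obs$global / mean(boot_global[ok]),
    n_boot = n_boot, n_failed_refits = n_fail, warning = warn,
    season_labels = fit$data$season_labels
  ), class = "occu_gof")
}

#' @export
print.occu_gof <- function(x, ...) {
  cat("<occu_gof> parametric bootstrap, ", x$n_boot, " iterations\n", sep = "")
  cat(sprintf("  global: X2 = %.2f, p = %.3f, c-hat = %.2f\n",
              x$observed_global, x$p_global, x$c_hat))
  for (t in seq_along(x$observed_per_season)) {
    cat(sprintf("  %s: X2 = %.2f, p = %.3f\n", x$season_labels[t],
                x$observed_per_season[t], x$p_per_season[t]))
  }
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.occu_gof <- function(x, ...) {
  tibble::tibble(
    scope = c("global", x$season_labels),
    statistic = c(x$observed_global, x$observed_per_season),
    p.value = c(x$p_global, x$p_per_season)
  )
}

#' @export
glance.occu_gof <- function(x, ...) {
  tibble::tibble(statistic = x$observed_global, p.value = x$p_global,
                 c_hat = x$c_hat, n_boot = x$n_boot,
                 n_failed_refits = x$n_failed_refits)
}
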