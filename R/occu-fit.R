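#' Fit a multiseason occupancy model by maximum likelihood
#'
#' Minimises the forward-recursion negative log-likelihood with quasi-Newton
#' (BFGS) optimisation from multiple jittered starts. The first start is a
#' deterministic naive initialisation (logits of raw occupancy/detection
#' rates, zero covariate slopes); the remaining starts add N(0, 1) jitter.
#' Standard errors come from the inverse of a central-difference Hessian at
#' the optimum; a singular Hessian or optimiser failure propagates
#' `converged = FALSE`.
#'
#' @param data A [detection_array()], or a wide detection tibble accepted by
#'   [as_detection_array()].
#' @param spec An [occu_spec()].
#' @param covariates Data frame with one row per site holding every covariate
#'   the model specification references (typically pre-standardised with
#'   [standardise_covariates()]).
#' @param n_starts Number of optimisation starts (default 10).
#' @param seed Optional integer seed controlling start jitter.
#' @param init Optional full-length start vector used as the first start
#'   (e.g. warm starts during model selection).
#' @return An object of class `occu_fit` with elements `spec`, `coefficients`
#'   (named), `neg2loglik`, `K`, `aic`, `se`, `vcov`, `converged`,
#'   `n_starts_used`, plus the data and covariates for downstream methods.
#' @export
fit_occupancy <- function(data, spec, covariates = NULL, n_starts = 10,
                          seed = NULL, init = NULL) {
  if (!inherits(data, "detection_array")) data <- as_detection_array(data)
  stopifnot(inherits(spec, "occu_spec"))
  stats_ <- detection_stats(data)
  T <- stats_$n_seasons
  if (T < 2) stop("multiseason model needs at least 2 seasons", call. = FALSE)
  covariates <- covariates %||% tibble::tibble(.rows = stats_$n_sites)
  if (nrow(covariates) != stats_$n_sites) {
    stop("covariates must have one row per site", call. = FALSE)
  }
  empty_season <- colSums(stats_$nn) == 0
  if (any(empty_season)) {
    warning("season(s) with no non-missing occasions at any site: ",
            paste(which(empty_season), collapse = ", "))
  }
  nms <- coef_names(spec, T)
  K <- length(nms)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  base_start <- init %||% naive_start(spec, stats_, T)
  stopifnot(length(base_start) == K)
  mf <- build_model_frame(spec, covariates, T)
  fn <- function(par) nll_core(par, mf, stats_)
  # fn/gr pair sharing one forward-backward evaluation per parameter value
  cache_par <- NULL; cache <- NULL
  refresh <- function(par) {
    if (is.null(cache_par) || !identical(par, cache_par)) {
      cache <<- nll_with_grad(par, mf, stats_)
      cache_par <<- par
    }
  }
  fn_c <- function(par) { refresh(par); cache$value }
  gr_c <- function(par) { refresh(par); cache$grad }
  best <- NULL
  n_ok <- 0L
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1L) base_start else base_start + stats::rnorm(K)
    res <- tryCatch(
      stats::optim(par0, fn_c, gr_c, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all ", n_starts, " optimisation starts failed for model ",
         spec_label(spec), call. = FALSE)
  }
  # Newton polish with the analytic gradient: BFGS stops within line-search
  # tolerance of the optimum, which leaves the reported -2 loglik dependent
  # on summation order; a few damped Newton steps converge quadratically to
  # reporting precision
  H <- num_hessian(fn, best$par)
  par_pre <- best$par
  polish_ok <- TRUE
  for (it in 1:8) {
    g <- gr_c(best$par)
    if (max(abs(g)) < 1e-9 * max(1, abs(best$value))) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) { polish_ok <- FALSE; break }
    lam <- 1
    improved <- FALSE
    for (half in 1:6) {
      cand <- best$par - lam * step
      v <- fn_c(cand)
      if (is.finite(v) && v <= best$value) {
        best$par <- cand; best$value <- v; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  converged <- best$convergence == 0
  if (polish_ok && max(abs(best$par - par_pre)) > 1e-3) {
    H <- num_hessian(fn, best$par)
  }
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  se <- rep(NA_real_, K)
  if (!is.null(vcov)) {
    dg <- diag(vcov)
    se <- ifelse(dg >= 0, sqrt(pmax(dg, 0)), NA_real_)
    if (any(dg < 0)) converged <- FALSE
  } else {
    converged <- FALSE
    vcov <- matrix(NA_real_, K, K)
  }
  coefs <- stats::setNames(best$par, nms)
  dimnames(vcov) <- list(nms, nms)
  structure(list(
    spec = spec, coefficients = coefs, neg2loglik = 2 * best$value,
    K = K, aic = 2 * best$value + 2 * K, se = stats::setNames(se, nms),
    vcov = vcov, converged = converged, n_starts_used = n_ok,
    n_seasons = T, data = data, covariates = tibble::as_tibble(covariates)
  ), class = "occu_fit")
}

# Deterministic naive start: logit of crude occupancy/detection summaries.
naive_start <- function(spec, stats_, T) {
  seen1 <- stats_$d[, 1] > 0
  has1 <- stats_$nn[, 1] > 0
  naive_psi <- if (any(has1)) mean(seen1[has1]) else 0.5
  det_rate <- sum(stats_$d) / max(sum(stats_$nn), 1)
  blocks <- spec_blocks(spec, T)
  vals <- list(psi1 = logit(min(max(naive_psi, 0.05), 0.95)),
               eps = logit(0.2), gamma = logit(0.3),
               p = logit(min(max(det_rate, 0.02), 0.98)))
  unlist(purrr::imap(blocks, function(b, nm) {
    c(rep(vals[[nm]], b$n_int), rep(0, length(b$covs)))
  }), use.names = FALSE)
}

#' Flag implausible coefficient estimates
#'
#' Model-selection practice drops candidate fits with very large estimates
#' and standard errors on the logit scale (typically symptoms of boundary or
#' separation problems). The thresholds are configurable; defaults flag
#' |beta| > 15 or SE > 25.
#'
#' @param fit An `occu_fit`.
#' @param beta_max,se_max Thresholds on the logit scale.
#' @return Logical scalar: `TRUE` when the fit should be dropped.
#' @export
is_implausible <- function(fit, beta_max = 15, se_max = 25) {
  any(abs(fit$coefficients) > beta_max) ||
    any(!is.na(fit$se) & fit$se > se_max) || anyNA(fit$se)
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", spec_label(x$spec), "\n", sep = "")
  cat("  K = ", x$K, ", -2 loglik = ", formatC(x$neg2loglik, format = "f",
      digits = 2), ", AIC = ", formatC(x$aic, format = "f", digits = 2),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(tidy.occu_fit(x), n = Inf)
  invisible(x)
}

#' Tidy coefficient table of an occupancy fit
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (Wald, on the logit scale).
#' @export
tidy.occu_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' One-line model summary
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `K`, `neg2loglik`, `aic`, `converged`,
#'   `n_sites`, `n_seasons`.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(K = x$K, neg2loglik = x$neg2loglik, aic = x$aic,
                 converged = x$converged, n_sites = dim(x$data)[1],
                 n_seasons = x$n_seasons)
}

# Marginal occupancy trajectory for given parameters: psi_{t+1} =
# psi_t (1 - eps_t) + (1 - psi_t) gamma_t, per site, then site-averaged.
occupancy_trajectory <- function(params, spec, covariates, n_seasons) {
  pr <- spec_probabilities(spec, params, covariates, n_seasons)
  psi_t <- matrix(NA_real_, length(pr$psi), n_seasons)
  psi_t[, 1] <- pr$psi
  for (t in seq_len(n_seasons)[-1]) {
    psi_t[, t] <- psi_t[, t - 1] * (1 - pr$eps[, t - 1]) +
      (1 - psi_t[, t - 1]) * pr$gamma[, t - 1]
  }
  psi_t
}

#' Derived per-season occupancy estimates
#'
#' Occupancy after the first season is not a free parameter of the model; it
#' is derived by propagating initial occupancy through the seasonal
#' extinction/colonisation dynamics, averaged over the observed covariate
#' values. Standard errors use the delta method on the fit's coefficient
#' covariance.
#'
#' @param fit A converged `occu_fit`.
#' @return A tibble with columns `season`, `psi`, `se`, `lower`, `upper`
#'   (normal-approximation 95% interval truncated to \code{[0, 1]}).
#' @export
derived_occupancy <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!fit$converged) {
    stop("derived occupancy requires a converged fit", call. = FALSE)
  }
  T <- fit$n_seasons
  f <- function(par) colMeans(occupancy_trajectory(par, fit$spec,
                                                   fit$covariates, T))
  est <- f(fit$coefficients)
  J <- num_jacobian(f, fit$coefficients)
  se <- sqrt(pmax(diag(J %*% fit$vcov %*% t(J)), 0))
  tibble::tibble(
    season = fit$data$season_labels,
    psi = est, se = se,
    lower = pmax(est - 1.96 * se, 0),
    upper = pmin(est + 1.96 * se, 1)
  )
}

#' Predicted response curve for one model parameter
#'
#' Evaluates the fitted relationship between a covariate and one of the model
#' probabilities over a grid, holding other covariates at their observed
#' means. The 95% interval is computed on the linear (logit) scale by the
#' delta method and back-transformed, so it respects the \code{[0, 1]} range.
#'
#' @param fit A converged `occu_fit`.
#' @param target One of `"psi1"`, `"eps"`, `"gamma"`, `"p"`.
#' @param covariate Name of a covariate in the target's formula.
#' @param grid Numeric grid of covariate values (default: 50 points over the
#'   observed range).
#' @param season Season (for `p`) or between-season interval (for
#'   `eps`/`gamma`) whose intercept is used; default 1.
#' @return A tibble with columns `covariate`, `value`, `estimate`, `lower`,
#'   `upper`.
#' @export
predict_parameter <- function(fit, target = c("psi1", "eps", "gamma", "p"),
                              covariate, grid = NULL, season = 1L) {
  target <- match.arg(target)
  stopifnot(inherits(fit, "occu_fit"))
  T <- fit$n_seasons
  blocks <- spec_blocks(fit$spec, T)
  b <- blocks[[target]]
  if (is.null(b)) {
    stop("parameter '", target, "' is not free under dynamics '",
         fit$spec$dynamics, "'", call. = FALSE)
  }
  if (!(covariate %in% b$covs)) {
    stop("covariate '", covariate, "' is not in the ", target, " formula",
         call. = FALSE)
  }
  if (season > b$n_int) stop("season index exceeds intercepts", call. = FALSE)
  grid <- grid %||% seq(min(fit$covariates[[covariate]]),
                        max(fit$covariates[[covariate]]), length.out = 50)
  # build rows of the full-coefficient design for eta(target)
  nms <- names(fit$coefficients)
  offsets <- cumsum(c(0, head(vapply(blocks, block_size, integer(1)), -1)))
  names(offsets) <- names(blocks)
  row0 <- rep(0, length(nms))
  row0[offsets[target] + season] <- 1  # chosen intercept
  for (cv in b$covs) {
    pos <- offsets[target] + b$n_int + match(cv, b$covs)
    row0[pos] <- if (cv == covariate) NA else mean(fit$covariates[[cv]])
  }
  var_pos <- which(is.na(row0))
  eta <- vapply(grid, function(g) {
    r <- row0; r[var_pos] <- g
    sum(r * fit$coefficients)
  }, numeric(1))
  se_eta <- vapply(grid, function(g) {
    r <- row0; r[var_pos] <- g
    sqrt(max(drop(t(r) %*% fit$vcov %*% r), 0))
  }, numeric(1))
  tibble::tibble(
    covariate = covariate, value = grid,
    estimate = inv_logit(eta),
    lower = inv_logit(eta - 1.96 * se_eta),
    upper = inv_logit(eta + 1.96 * se_eta)
  )
}

#' Plot a fitted covariate relationship
#'
#' @param object A converged `occu_fit`.
#' @inheritParams predict_parameter
#' @param ... Passed to [predict_parameter()].
#' @return A ggplot object: predicted probability with a 95% confidence band.
#' @export
autoplot.occu_fit <- function(object, target = "p", covariate, ...) {
  pred <- predict_parameter(object, target = target, covariate = covariate, ...)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$value, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = covariate, y = paste("estimated", target)) +
    ggplot2::theme_minimal()
}

#' Plot derived seasonal occupancy
#'
#' @param fit A converged `occu_fit`.
#' @return A ggplot object: derived occupancy per season with 95% intervals.
#' @export
plot_occupancy_trajectory <- function(fit) {
  d <- derived_occupancy(fit)
  d$season <- factor(d$season, levels = d$season)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$season, y = .data$psi, group = 1)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "derived occupancy") +
    ggplot2::theme_minimal()
}
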