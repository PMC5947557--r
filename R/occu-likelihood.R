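# Multiseason occupancy likelihood.
#
# The model is a two-state hidden Markov chain per site: latent occupancy
# z_{i1} ~ Bernoulli(psi1_i), transitions
#   P(z=1 -> 1) = 1 - eps_t,  P(z=0 -> 1) = gamma_t,
# and, within season t, detections on non-missing occasions are iid
# Bernoulli(p_{it}) given z_{it} = 1 and structural zeros given z_{it} = 0.
# Because p is constant across occasions within a site-season, the
# per-season emission depends on the data only through the number of
# detections d and the number of non-missing occasions J:
#   log e_occ = d log p + (J - d) log(1 - p);   log e_unocc = 0 if d = 0 else -Inf.
# A season with every occasion missing has J = 0 and contributes emission 1
# in both states, dropping out of the likelihood.

# Sufficient statistics: detections and non-missing occasion counts per
# site x season, plus the all-zero indicator used by the unoccupied-state
# emission.
detection_stats <- function(data) {
  stopifnot(inherits(data, "detection_array"))
  d <- apply(data$y, c(1, 2), function(v) sum(v == 1, na.rm = TRUE))
  nn <- apply(data$y, c(1, 2), function(v) sum(!is.na(v)))
  list(d = d, nn = nn, zerodet = d == 0,
       n_sites = dim(data$y)[1], n_seasons = dim(data$y)[2])
}

# Core negative log-likelihood on precomputed sufficient statistics and a
# compiled model frame. The forward pass runs in linear space with
# per-season scaling: each season's emissions are divided by their maximum
# over the two latent states (which is exp(log_e_occ) when detections force
# the occupied state, 1 otherwise) and the forward vector is renormalised,
# with the log normalisers accumulated. Vectorised across sites; the
# explicit loop runs over seasons only.
nll_core <- function(params, mf, stats) {
  T <- stats$n_seasons
  pr <- probs_from_frame(mf, params)
  d <- stats$d; nn <- stats$nn; zd <- stats$zerodet
  log_e_occ <- d * log(pr$p) + (nn - d) * log1p(-pr$p)
  # scaled emissions: occupied state gets exp(log_e_occ) when d = 0 (scale
  # 1), 1 when d > 0 (scale exp(log_e_occ)); unoccupied state 1 or 0.
  e_occ <- ifelse(zd, exp(log_e_occ), 1)
  e_un <- zd * 1
  acc <- ifelse(zd[, 1], 0, log_e_occ[, 1])
  a_occ <- pr$psi * e_occ[, 1]
  a_un <- (1 - pr$psi) * e_un[, 1]
  s <- a_occ + a_un
  acc <- acc + log(s); a_occ <- a_occ / s; a_un <- a_un / s
  for (t in seq_len(T)[-1]) {
    e <- pr$eps[, t - 1]; g <- pr$gamma[, t - 1]
    new_occ <- (a_occ * (1 - e) + a_un * g) * e_occ[, t]
    new_un <- (a_occ * e + a_un * (1 - g)) * e_un[, t]
    acc <- acc + ifelse(zd[, t], 0, log_e_occ[, t])
    s <- new_occ + new_un
    acc <- acc + log(s)
    a_occ <- new_occ / s; a_un <- new_un / s
  }
  if (any(!is.finite(acc))) return(.Machine$double.xmax / 1e6)
  -sum(acc)
}

#' Negative log-likelihood of a multiseason occupancy model
#'
#' Evaluates minus the log-likelihood by a two-state forward recursion over
#' latent occupancy, marginalising seasons whose occasions are all missing.
#'
#' @param params Numeric coefficient vector on the logit scale, blocked as
#'   psi1 | eps | gamma | p (see [count_parameters()] for block sizes).
#' @param spec An [occu_spec()].
#' @param data A [detection_array()].
#' @param covariates Data frame of per-site covariates (one row per site,
#'   aligned with `data`).
#' @return A finite numeric scalar.
#' @export
occu_nll <- function(params, spec, data, covariates) {
  stats <- detection_stats(data)
  if (nrow(covariates) != stats$n_sites) {
    stop("covariates must have one row per site", call. = FALSE)
  }
  mf <- build_model_frame(spec, covariates, stats$n_seasons)
  nll_core(params, mf, stats)
}

# Joint negative log-likelihood and analytic gradient via scaled
# forward-backward recursions. Writing a-hat and b-hat for the forward and
# backward vectors scaled by the per-season normalisers c_t, the posterior
# state weights are post_t = a-hat_t * b-hat_t and the score contributions
# of the probability components are
#   d l / d p_t    = post_t(occ) * (d_t - J_t p_t) / (p_t (1 - p_t))
#   d l / d eps_t  = a-hat_t(occ) * (u_t(un) - u_t(occ))
#   d l / d gamma_t= a-hat_t(un)  * (u_t(occ) - u_t(un))
#   d l / d psi    = (e_1(occ) b-hat_1(occ) - e_1(un) b-hat_1(un)) / c_1
# with u_t(k) = e_{t+1}(k) b-hat_{t+1}(k) / c_{t+1}; the logit link and any
# dynamics constraint (derived eps) enter by the chain rule. Per-season
# emission scaling cancels in every ratio.
nll_with_grad <- function(params, mf, stats) {
  T <- stats$n_seasons
  n <- mf$n
  pr <- probs_from_frame(mf, params)
  d <- stats$d; nn <- stats$nn; zd <- stats$zerodet
  log_e_occ <- d * log(pr$p) + (nn - d) * log1p(-pr$p)
  e_occ <- exp(log_e_occ); e_occ[!zd] <- 1
  lo <- log_e_occ; lo[zd] <- 0
  e_un <- zd * 1
  A_occ <- A_un <- Cm <- matrix(NA_real_, n, T)
  a_occ <- pr$psi * e_occ[, 1]
  a_un <- (1 - pr$psi) * e_un[, 1]
  s <- a_occ + a_un
  acc <- lo[, 1] + log(s)
  A_occ[, 1] <- a_occ / s; A_un[, 1] <- a_un / s; Cm[, 1] <- s
  for (t in seq_len(T)[-1]) {
    e <- pr$eps[, t - 1]; g <- pr$gamma[, t - 1]
    new_occ <- (A_occ[, t - 1] * (1 - e) + A_un[, t - 1] * g) * e_occ[, t]
    new_un <- (A_occ[, t - 1] * e + A_un[, t - 1] * (1 - g)) * e_un[, t]
    s <- new_occ + new_un
    acc <- acc + lo[, t] + log(s)
    A_occ[, t] <- new_occ / s; A_un[, t] <- new_un / s; Cm[, t] <- s
  }
  if (any(!is.finite(acc))) {
    return(list(value = .Machine$double.xmax / 1e6,
                grad = rep(0, length(params))))
  }
  # backward pass, accumulating score pieces; post_occ already folds in the
  # logit-link factor for p (post * (d - J p) = dl/deta_p)
  b_occ <- b_un <- rep(1, n)
  dP_eta <- matrix(0, n, T)    # d l / d eta_p, season t
  dE <- dG <- matrix(0, n, T - 1)
  dP_eta[, T] <- A_occ[, T] * b_occ * (d[, T] - nn[, T] * pr$p[, T])
  for (t in rev(seq_len(T - 1))) {
    e <- pr$eps[, t]; g <- pr$gamma[, t]
    u_occ <- e_occ[, t + 1] * b_occ / Cm[, t + 1]
    u_un <- e_un[, t + 1] * b_un / Cm[, t + 1]
    dE[, t] <- A_occ[, t] * (u_un - u_occ)
    dG[, t] <- A_un[, t] * (u_occ - u_un)
    b_occ_new <- (1 - e) * u_occ + e * u_un
    b_un_new <- g * u_occ + (1 - g) * u_un
    b_occ <- b_occ_new; b_un <- b_un_new
    dP_eta[, t] <- A_occ[, t] * b_occ * (d[, t] - nn[, t] * pr$p[, t])
  }
  dPsi <- (e_occ[, 1] * b_occ - e_un[, 1] * b_un) / Cm[, 1]
  # chain rule through the dynamics constraints
  psi <- pr$psi
  eq_int <- attr(pr$eps, "interior")
  dPsi_eta <- switch(mf$dynamics,
    equilibrium = {
      extra <- rowSums(dE * eq_int * (-pr$gamma / psi^2))
      (dPsi + extra) * psi * (1 - psi)
    },
    dPsi * psi * (1 - psi)
  )
  dG_eta <- NULL
  if (!is.null(mf$blocks$gamma)) {
    dG_free <- switch(mf$dynamics,
      equilibrium = dG + dE * eq_int * ((1 - psi) / psi),
      random_changes = dG - dE,
      dG
    )
    dG_eta <- dG_free * pr$gamma * (1 - pr$gamma)
  }
  dE_eta <- if (!is.null(mf$blocks$eps)) dE * pr$eps * (1 - pr$eps)
  grad <- numeric(length(params))
  add_block <- function(b, deta) {
    if (is.null(b)) return()
    if (b$n_int == 1L) {
      grad[b$idx_int] <<- sum(deta)
    } else {
      grad[b$idx_int] <<- colSums(deta)
    }
    if (length(b$idx_slope)) {
      grad[b$idx_slope] <<- as.vector(crossprod(b$X, rowSums(deta)))
    }
  }
  add_block(mf$blocks$psi1, matrix(dPsi_eta, n, 1))
  add_block(mf$blocks$eps, dE_eta)
  add_block(mf$blocks$gamma, dG_eta)
  add_block(mf$blocks$p, dP_eta)
  list(value = -sum(acc), grad = -grad)
}

# Simulate latent states and detections given probability components and a
# missingness template (logical array: TRUE where an occasion is observed).
simulate_detections_from_probs <- function(pr, observed, occasions_per_season) {
  n <- length(pr$psi); T <- ncol(pr$p); J <- dim(observed)[3]
  z <- matrix(0L, n, T)
  z[, 1] <- stats::rbinom(n, 1, pr$psi)
  for (t in seq_len(T)[-1]) {
    stay <- stats::rbinom(n, 1, 1 - pr$eps[, t - 1])
    col <- stats::rbinom(n, 1, pr$gamma[, t - 1])
    z[, t] <- ifelse(z[, t - 1] == 1L, stay, col)
  }
  y <- array(NA_real_, dim = c(n, T, J))
  for (t in seq_len(T)) {
    for (j in seq_len(J)) {
      obs <- observed[, t, j]
      if (!any(obs)) next
      y[obs, t, j] <- stats::rbinom(sum(obs), 1, pr$p[obs, t] * z[obs, t])
    }
  }
  list(y = y, z = z)
}
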