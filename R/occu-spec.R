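#' Specify a multiseason occupancy model
#'
#' A model is defined by a seasonal-dynamics structure plus covariate lists
#' for initial occupancy (psi1), local extinction (eps), colonisation (gamma)
#' and detection (p). All probabilities are modelled on the logit scale.
#'
#' Dynamics structures:
#' \describe{
#'   \item{`markov_seasonal`}{First-order Markov changes with
#'     season-specific extinction and colonisation (one intercept per
#'     between-season interval); accommodates unequal season spacing.}
#'   \item{`markov_constant`}{Markov changes with constant eps and gamma.}
#'   \item{`equilibrium`}{Stationary occupancy: eps is derived as
#'     `gamma * (1 - psi) / psi`, so occupancy is identical in every season.}
#'   \item{`random_changes`}{Occupancy changes at random: `eps = 1 - gamma`,
#'     so season t+1 occupancy equals gamma regardless of season t.}
#'   \item{`static`}{No changes: `gamma = eps = 0`.}
#' }
#'
#' Covariate lists are character vectors of covariate column names; the
#' special name `"season"` requests season-specific intercepts (allowed in
#' `eps`, `gamma` and `p`). Covariate effects are additive on the logit
#' scale, e.g. `p = c("season", "understorey")`.
#'
#' @param dynamics One of the five structures above.
#' @param psi1,eps,gamma,p Character vectors of covariate names (possibly
#'   empty for intercept-only). `eps`/`gamma` default to season-specific
#'   intercepts under `markov_seasonal` and to constants otherwise; they are
#'   ignored where the structure derives or fixes them.
#' @return An object of class `occu_spec`.
#' @export
occu_spec <- function(dynamics = c("markov_seasonal", "markov_constant",
                                   "equilibrium", "random_changes", "static"),
                      psi1 = character(), eps = NULL, gamma = NULL,
                      p = "season") {
  dynamics <- match.arg(dynamics)
  psi1 <- as.character(psi1 %||% character())
  p <- as.character(p %||% character())
  eps <- switch(dynamics,
    markov_seasonal = unique(c("season", as.character(eps %||% character()))),
    markov_constant = setdiff(as.character(eps %||% character()), "season"),
    character()  # derived or fixed otherwise
  )
  gamma <- switch(dynamics,
    markov_seasonal = unique(c("season", as.character(gamma %||% character()))),
    markov_constant = setdiff(as.character(gamma %||% character()), "season"),
    equilibrium = as.character(gamma %||% character()),
    random_changes = as.character(gamma %||% character()),
    character()
  )
  if ("season" %in% psi1) {
    stop("psi1 refers to the first season only; 'season' is not a valid term",
         call. = FALSE)
  }
  structure(list(dynamics = dynamics, psi1 = psi1, eps = eps, gamma = gamma,
                 p = p),
            class = "occu_spec")
}

#' @export
print.occu_spec <- function(x, ...) {
  cat("<occu_spec> ", spec_label(x), "\n", sep = "")
  invisible(x)
}

#' Model structure label
#'
#' Compact label in the conventional notation, e.g.
#' `"psi1(forest), eps(season+patch_no), gamma(season), p(season+understorey)"`.
#'
#' @param spec An [occu_spec()].
#' @return A character scalar.
#' @export
spec_label <- function(spec) {
  trm <- function(v) if (length(v) == 0) "." else paste(v, collapse = "+")
  switch(spec$dynamics,
    markov_seasonal = ,
    markov_constant = sprintf("psi1(%s), eps(%s), gamma(%s), p(%s)",
                              trm(spec$psi1), trm(spec$eps), trm(spec$gamma),
                              trm(spec$p)),
    equilibrium = sprintf("psi(%s), gamma(%s), {eps=gamma(1-psi)/psi}, p(%s)",
                          trm(spec$psi1), trm(spec$gamma), trm(spec$p)),
    random_changes = sprintf("psi1(%s), gamma(%s), {eps=1-gamma}, p(%s)",
                             trm(spec$psi1), trm(spec$gamma), trm(spec$p)),
    static = sprintf("psi(%s), {gamma=eps=0}, p(%s)", trm(spec$psi1),
                     trm(spec$p))
  )
}

# Free coefficient blocks implied by a spec. Each block is a list with the
# number of intercepts and the covariate names.
spec_blocks <- function(spec, n_seasons) {
  stopifnot(inherits(spec, "occu_spec"), n_seasons >= 2)
  n_int <- function(terms, per_season_count) {
    if ("season" %in% terms) per_season_count else 1L
  }
  covs <- function(terms) setdiff(terms, "season")
  blocks <- list(psi1 = list(n_int = 1L, covs = covs(spec$psi1)))
  if (spec$dynamics %in% c("markov_seasonal", "markov_constant")) {
    blocks$eps <- list(n_int = n_int(spec$eps, n_seasons - 1L),
                       covs = covs(spec$eps))
  }
  if (spec$dynamics %in% c("markov_seasonal", "markov_constant",
                           "equilibrium", "random_changes")) {
    blocks$gamma <- list(n_int = n_int(spec$gamma, n_seasons - 1L),
                         covs = covs(spec$gamma))
  }
  blocks$p <- list(n_int = n_int(spec$p, n_seasons), covs = covs(spec$p))
  blocks
}

block_size <- function(b) as.integer(b$n_int + length(b$covs))

block_names <- function(name, b, n_seasons) {
  ints <- if (b$n_int == 1L) paste0(name, "_(Intercept)") else
    paste0(name, "_(Intercept:", seq_len(b$n_int), ")")
  c(ints, if (length(b$covs)) paste0(name, "_", b$covs))
}

#' Count free parameters of a model
#'
#' Intercept-only psi1 contributes 1 coefficient (+1 per covariate);
#' season-specific eps and gamma contribute one intercept per between-season
#' interval; season-specific p one intercept per season; constrained
#' structures contribute only their free blocks (equilibrium: psi and gamma;
#' random changes: gamma; static: none beyond psi and p).
#'
#' @param spec An [occu_spec()].
#' @param n_seasons Number of seasons (>= 2).
#' @return Integer K, used as the AIC penalty.
#' @export
count_parameters <- function(spec, n_seasons) {
  sum(vapply(spec_blocks(spec, n_seasons), block_size, integer(1)))
}

coef_names <- function(spec, n_seasons) {
  blocks <- spec_blocks(spec, n_seasons)
  unlist(purrr::imap(blocks, function(b, nm) block_names(nm, b, n_seasons)),
         use.names = FALSE)
}

# Precompile the design: per block, the covariate matrix and the positions
# of its intercepts and slopes in the packed parameter vector. Built once
# per fit so likelihood evaluations are pure matrix arithmetic.
build_model_frame <- function(spec, covariates, n_seasons) {
  blocks <- spec_blocks(spec, n_seasons)
  n <- nrow(covariates)
  offs <- 0L
  compiled <- purrr::imap(blocks, function(b, nm) {
    missing <- setdiff(b$covs, names(covariates))
    if (length(missing)) {
      stop("covariate(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    k <- block_size(b)
    out <- list(
      n_int = b$n_int,
      idx_int = offs + seq_len(b$n_int),
      idx_slope = if (length(b$covs)) offs + b$n_int + seq_along(b$covs)
                  else integer(0),
      X = if (length(b$covs)) as.matrix(covariates[b$covs]) else NULL
    )
    offs <<- offs + k
    out
  })
  list(blocks = compiled, dynamics = spec$dynamics, n = n,
       n_seasons = as.integer(n_seasons), K = offs)
}

# Linear predictor for one compiled block as an n x n_cols matrix.
frame_eta <- function(b, params, n, n_cols) {
  eta <- matrix(params[b$idx_int], n, n_cols, byrow = TRUE)
  if (length(b$idx_slope)) {
    eta <- eta + as.vector(b$X %*% params[b$idx_slope])
  }
  eta
}

fast_inv_logit <- function(eta) 1 / (1 + exp(-pmin(pmax(eta, -CLIP), CLIP)))

probs_from_frame <- function(mf, params) {
  if (length(params) != mf$K) {
    stop("parameter vector has length ", length(params), ", expected ", mf$K,
         call. = FALSE)
  }
  n <- mf$n; Tm1 <- mf$n_seasons - 1L
  b <- mf$blocks
  psi <- fast_inv_logit(frame_eta(b$psi1, params, n, 1L))[, 1]
  eps_m <- if (!is.null(b$eps)) fast_inv_logit(frame_eta(b$eps, params, n, Tm1))
  gamma_m <- if (!is.null(b$gamma))
    fast_inv_logit(frame_eta(b$gamma, params, n, Tm1))
  p_m <- fast_inv_logit(frame_eta(b$p, params, n, mf$n_seasons))
  eps_m <- switch(mf$dynamics,
    markov_seasonal = ,
    markov_constant = eps_m,
    equilibrium = {
      e <- gamma_m * (1 - psi) / psi
      ec <- pmin(pmax(e, 1e-12), 1 - 1e-12)
      # flat regions of the clip carry zero derivative wrt gamma and psi
      attr(ec, "interior") <- e > 1e-12 & e < 1 - 1e-12
      ec
    },
    random_changes = 1 - gamma_m,
    static = matrix(0, n, Tm1)
  )
  if (mf$dynamics == "static") gamma_m <- matrix(0, n, Tm1)
  list(psi = psi, eps = eps_m, gamma = gamma_m, p = p_m)
}

# Evaluate linear predictors and return probability components:
# psi (n), eps (n x T-1), gamma (n x T-1), p (n x T).
# Covariates is a data frame with one row per site.
spec_probabilities <- function(spec, params, covariates, n_seasons) {
  probs_from_frame(build_model_frame(spec, covariates, n_seasons), params)
}
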