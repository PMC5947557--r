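#' Forced-response randomised-response design
#'
#' In a forced-response design a randomising device instructs a fraction of
#' respondents to answer "yes" regardless of truth (probability
#' `p_forced_yes`), a fraction to answer "no" (`p_forced_no`), and the rest
#' to answer truthfully. A symmetric design (both forcing probabilities
#' positive) increases instruction compliance because any single answer is
#' uninformative about the respondent.
#'
#' @param p_forced_yes,p_forced_no Forcing probabilities; their sum must be
#'   below 1. Defaults are the symmetric 1/6, 1/6 design (a die assigning
#'   one face to each prescribed answer).
#' @return An object of class `rrt_design`.
#' @export
rrt_design <- function(p_forced_yes = 1/6, p_forced_no = 1/6) {
  stopifnot(p_forced_yes >= 0, p_forced_no >= 0)
  if (p_forced_yes + p_forced_no >= 1) {
    stop("degenerate design: forcing probabilities must sum to < 1",
         call. = FALSE)
  }
  structure(list(p_forced_yes = p_forced_yes, p_forced_no = p_forced_no),
            class = "rrt_design")
}

#' @export
print.rrt_design <- function(x, ...) {
  cat(sprintf("<rrt_design> forced yes %.4f, forced no %.4f, truthful %.4f\n",
              x$p_forced_yes, x$p_forced_no,
              1 - x$p_forced_yes - x$p_forced_no))
  invisible(x)
}

#' Prevalence estimate from forced-response answers
#'
#' The observed yes-probability is `lambda = p_fy + (1 - p_fy - p_fn) * pi`,
#' so the prevalence estimator inverts it:
#' `pi_hat = (lambda_hat - p_fy) / (1 - p_fy - p_fn)`. The raw (possibly
#' out-of-range) estimate is reported alongside a companion clipped to
#' \code{[0, 1]}.
#'
#' @param yes_count Number of "yes" answers.
#' @param n Number of respondents.
#' @param design An [rrt_design()].
#' @return A one-row tibble with `n`, `yes_count`, `lambda_hat`, `estimate`
#'   (unclipped) and `estimate_clipped`.
#' @export
rrt_prevalence <- function(yes_count, n, design = rrt_design()) {
  stopifnot(inherits(design, "rrt_design"), n > 0, yes_count >= 0,
            yes_count <= n)
  lambda <- yes_count / n
  denom <- 1 - design$p_forced_yes - design$p_forced_no
  est <- (lambda - design$p_forced_yes) / denom
  tibble::tibble(n = n, yes_count = yes_count, lambda_hat = lambda,
                 estimate = est,
                 estimate_clipped = pmin(pmax(est, 0), 1))
}

#' Bootstrap confidence interval for the forced-response prevalence
#'
#' Nonparametric respondent-level resampling: each replicate redraws `n`
#' answers with replacement and re-applies the prevalence estimator. The
#' interval is the percentile 2.5/97.5 range and the standard error the
#' bootstrap standard deviation.
#'
#' @param answers Binary vector of recorded answers (1 = "yes").
#' @param design An [rrt_design()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble with `estimate`, `se`, `lower`, `upper`,
#'   `n_boot`.
#' @export
rrt_bootstrap_ci <- function(answers, design = rrt_design(), n_boot = 1000,
                             seed = 1L, conf = 0.95) {
  stopifnot(all(answers %in% c(0, 1)))
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  n <- length(answers)
  if (n < 30) warning("fewer than 30 respondents: the prevalence estimate ",
                      "will be imprecise")
  est <- rrt_prevalence(sum(answers), n, design)$estimate
  denom <- 1 - design$p_forced_yes - design$p_forced_no
  boot <- with_seed(seed, {
    yes <- vapply(seq_len(n_boot), function(b) {
      sum(answers[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    (yes / n - design$p_forced_yes) / denom
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), names = FALSE, type = 7)
  tibble::tibble(estimate = est, se = stats::sd(boot),
                 lower = qs[1], upper = qs[2], n_boot = n_boot)
}

# Forced-response log-likelihood: the yes-probability of respondent i is
# q_i = p_fy + (1 - p_fy - p_fn) * logistic(x_i' beta).
rrt_loglik <- function(beta, X, y, design) {
  pi_i <- inv_logit(as.vector(X %*% beta))
  q <- design$p_forced_yes +
    (1 - design$p_forced_yes - design$p_forced_no) * pi_i
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  sum(y * log(q) + (1 - y) * log1p(-q))
}

#' Logistic regression for forced-response RRT data
#'
#' Maximum-likelihood logistic regression on the latent sensitive trait,
#' incorporating the known forcing probabilities in the likelihood. With a
#' degenerate design (no forcing) it reduces exactly to ordinary logistic
#' regression. Coefficients whose magnitude exceeds `separation_threshold`
#' on the logit scale are flagged as separation symptoms; flagged predictors
#' should normally be refitted out of the model.
#'
#' @param data Data frame containing the answer column and predictors.
#' @param formula Model formula, e.g. `answer ~ age + income`.
#' @param design An [rrt_design()].
#' @param separation_threshold Absolute coefficient above which a term is
#'   flagged (default 10).
#' @return An object of class `rrt_fit` with `coefficients`, `se`, `vcov`,
#'   `loglik`, `converged`, `separation` (character vector of flagged
#'   terms), plus the call ingredients for refitting.
#' @export
rrt_logistic <- function(data, formula, design = rrt_design(),
                         separation_threshold = 10) {
  stopifnot(inherits(design, "rrt_design"))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  stopifnot(all(y %in% c(0, 1)))
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    stop("predictor matrix is rank deficient", call. = FALSE)
  }
  k <- ncol(X)
  denom <- 1 - design$p_forced_yes - design$p_forced_no
  fn <- function(b) -rrt_loglik(b, X, y, design)
  gr <- function(b) {
    pi_i <- inv_logit(as.vector(X %*% b))
    q <- pmin(pmax(design$p_forced_yes + denom * pi_i, 1e-12), 1 - 1e-12)
    w <- (y / q - (1 - y) / (1 - q)) * denom * pi_i * (1 - pi_i)
    -as.vector(crossprod(X, w))
  }
  # start at the inverted pooled prevalence (the likelihood is flat once
  # the latent probability hits the forcing floor, so a far-off start can
  # strand a quasi-Newton line search there)
  pi0 <- min(max((mean(y) - design$p_forced_yes) / denom, 0.02), 0.98)
  start <- rep(0, k)
  if (colnames(X)[1] == "(Intercept)") start[1] <- logit(pi0)
  res <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  H <- num_hessian(fn, res$par)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(vcov), 0))
  nms <- colnames(X)
  coefs <- stats::setNames(res$par, nms)
  sep <- nms[abs(res$par) > separation_threshold]
  if (length(sep)) {
    warning("possible separation: |coefficient| > ", separation_threshold,
            " for ", paste(sep, collapse = ", "),
            "; consider excluding these predictors")
  }
  dimnames(vcov) <- list(nms, nms)
  structure(list(
    coefficients = coefs, se = stats::setNames(se, nms), vcov = vcov,
    loglik = -res$value, converged = res$convergence == 0, separation = sep,
    n = length(y), formula = formula, design = design, data = data
  ), class = "rrt_fit")
}

#' @export
print.rrt_fit <- function(x, ...) {
  cat("<rrt_fit> forced-response logistic regression, n = ", x$n, "\n",
      sep = "")
  cat(sprintf("  logLik = %.3f%s\n", x$loglik,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (length(x$separation)) {
    cat("  separation flagged: ", paste(x$separation, collapse = ", "), "\n",
        sep = "")
  }
  print(tidy.rrt_fit(x), n = Inf)
  invisible(x)
}

#' Tidy RRT regression table with odds ratios
#'
#' @param x An `rrt_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `p.value` (Wald),
#'   `odds_ratio`, `or_lower`, `or_upper` (95%).
#' @export
tidy.rrt_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      term = names(x$coefficients),
      estimate = unname(x$coefficients),
      std.error = unname(x$se),
      p.value = unname(2 * stats::pnorm(-abs(x$coefficients / x$se)))
    ),
    dplyr::select(odds_ratios(x), -"term")
  )
}

#' @export
glance.rrt_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, df = length(x$coefficients),
                 converged = x$converged,
                 n_separation_flags = length(x$separation))
}

#' Likelihood-ratio test between nested RRT regressions
#'
#' `Delta G^2 = 2 (logLik_full - logLik_reduced)`, referred to a chi-square
#' distribution with degrees of freedom equal to the difference in
#' coefficient counts.
#'
#' @param full,reduced `rrt_fit` objects; the reduced model's terms must be
#'   a subset of the full model's.
#' @return A one-row tibble with `delta_g2`, `df`, `p.value`.
#' @export
rrt_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "rrt_fit"), inherits(reduced, "rrt_fit"))
  if (!all(names(reduced$coefficients) %in% names(full$coefficients))) {
    stop("models are not nested: reduced terms ",
         paste(setdiff(names(reduced$coefficients),
                       names(full$coefficients)), collapse = ", "),
         " absent from the full model", call. = FALSE)
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  g2 <- max(2 * (full$loglik - reduced$loglik), 0)
  p <- if (df == 0) 1 else stats::pchisq(g2, df, lower.tail = FALSE)
  tibble::tibble(delta_g2 = g2, df = df, p.value = p)
}

#' Odds ratios with 95% confidence intervals
#'
#' `OR = exp(beta)` with Wald interval `exp(beta +/- 1.96 SE)`.
#'
#' @param fit An `rrt_fit`, or a numeric vector of coefficients (then `se`
#'   must be supplied).
#' @param se Standard errors when `fit` is a plain vector.
#' @return A tibble with `term`, `odds_ratio`, `or_lower`, `or_upper`.
#' @export
odds_ratios <- function(fit, se = NULL) {
  if (inherits(fit, "rrt_fit")) {
    beta <- fit$coefficients; se <- fit$se
  } else {
    beta <- fit
    stopifnot(!is.null(se), length(se) == length(beta))
  }
  tibble::tibble(
    term = names(beta) %||% paste0("beta", seq_along(beta)),
    odds_ratio = exp(unname(beta)),
    or_lower = exp(unname(beta - 1.96 * se)),
    or_upper = exp(unname(beta + 1.96 * se))
  )
}
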