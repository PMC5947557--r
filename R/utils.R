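# Internal numeric helpers shared across modules.

# Linear predictors are clipped to +/- CLIP before the inverse logit so that
# probabilities stay inside (0, 1) in double precision and the likelihood
# never returns NaN for wild optimizer proposals.
CLIP <- 35

clip_eta <- function(eta) pmin(pmax(eta, -CLIP), CLIP)

inv_logit <- function(eta) stats::plogis(clip_eta(eta))

logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))

# Elementwise log(exp(a) + exp(b)) guarded against -Inf in both arguments.
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Central-difference Hessian. numDeriv is not a dependency; for the smooth,
# well-scaled log-likelihoods in this package a fixed-step central scheme at
# h ~ eps^(1/3) is accurate enough for Wald standard errors.
num_hessian <- function(fn, x, h = NULL, ...) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * (.Machine$double.eps)^(1/3)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x, ...)
  for (i in seq_len(k)) {
    ei <- h[i]
    for (j in i:k) {
      ej <- h[j]
      if (i == j) {
        xp <- x; xp[i] <- x[i] + ei
        xm <- x; xm[i] <- x[i] - ei
        H[i, i] <- (fn(xp, ...) - 2 * f0 + fn(xm, ...)) / ei^2
      } else {
        xpp <- x; xpp[i] <- x[i] + ei; xpp[j] <- x[j] + ej
        xpm <- x; xpm[i] <- x[i] + ei; xpm[j] <- x[j] - ej
        xmp <- x; xmp[i] <- x[i] - ei; xmp[j] <- x[j] + ej
        xmm <- x; xmm[i] <- x[i] - ei; xmm[j] <- x[j] - ej
        H[i, j] <- H[j, i] <-
          (fn(xpp, ...) - fn(xpm, ...) - fn(xmp, ...) + fn(xmm, ...)) /
          (4 * ei * ej)
      }
    }
  }
  H
}

# Central-difference gradient of a vector-valued map, used for delta-method
# standard errors of derived quantities.
num_jacobian <- function(fn, x, h = NULL, ...) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * sqrt(.Machine$double.eps)
  f0 <- fn(x, ...)
  J <- matrix(NA_real_, length(f0), k)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    J[, i] <- (fn(xp, ...) - fn(xm, ...)) / (2 * h[i])
  }
  J
}

# Truncated normal draws by inverse-CDF; ranges here are wide relative to the
# sd so the quantile transform is numerically safe.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (mean < lower || mean > upper) {
    stop("truncation range [", lower, ", ", upper, "] does not contain mean ",
         mean, call. = FALSE)
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Seed an expression's RNG use and restore the caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  code
}

# Seeds derived from a root seed stay below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
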