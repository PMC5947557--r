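# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations (enumeration, double loops, grid
# search): slow but transparently correct on tiny problems.

# Likelihood of one site's detection history by explicit enumeration of all
# 2^T latent occupancy sequences.
enumerate_site_likelihood <- function(y, psi, eps, gamma, p) {
  T <- nrow(y)
  total <- 0
  for (bits in 0:(2^T - 1)) {
    z <- as.integer(intToBits(bits))[1:T]
    pr <- if (z[1] == 1) psi else 1 - psi
    if (T > 1) {
      for (t in 2:T) {
        pr <- pr * if (z[t - 1] == 1) {
          if (z[t] == 1) 1 - eps[t - 1] else eps[t - 1]
        } else {
          if (z[t] == 1) gamma[t - 1] else 1 - gamma[t - 1]
        }
      }
    }
    for (t in 1:T) {
      for (j in seq_len(ncol(y))) {
        yy <- y[t, j]
        if (is.na(yy)) next
        pr <- pr * if (z[t] == 1) p[t]^yy * (1 - p[t])^(1 - yy) else
          as.numeric(yy == 0)
      }
    }
    total <- total + pr
  }
  total
}

# Full-data negative log-likelihood by enumeration, for constant-covariate
# seasonal models (psi scalar, eps/gamma length T-1, p length T).
enumerate_nll <- function(y_array, psi, eps, gamma, p) {
  T <- dim(y_array)[2]; J <- dim(y_array)[3]
  -sum(log(vapply(seq_len(dim(y_array)[1]), function(i) {
    enumerate_site_likelihood(matrix(y_array[i, , ], T, J), psi, eps,
                              gamma, p)
  }, numeric(1))))
}

# Random small detection instance with missingness, guaranteeing every site
# keeps at least one observed occasion.
random_instance <- function(n, T, J, miss_frac = 0.15) {
  y <- array(stats::rbinom(n * T * J, 1, stats::runif(1, 0.2, 0.6)),
             dim = c(n, T, J))
  y[sample(length(y), round(miss_frac * length(y)))] <- NA
  for (i in seq_len(n)) {
    if (all(is.na(y[i, , ]))) y[i, 1, 1] <- 0
  }
  detection_array(y)
}

# Single-season occupancy MLE by direct 2-d grid search over (psi, p).
grid_search_single_season <- function(d, nn, grid_n = 400) {
  g <- seq(0.001, 0.999, length.out = grid_n)
  best <- c(NA, NA, Inf)
  for (psi in g) {
    ll <- vapply(g, function(p) {
      site_l <- psi * p^d * (1 - p)^(nn - d) + (1 - psi) * (d == 0)
      -sum(log(site_l))
    }, numeric(1))
    k <- which.min(ll)
    if (ll[k] < best[3]) best <- c(psi, g[k], ll[k])
  }
  list(psi = best[1], p = best[2], nll = best[3])
}

# Moran's I by a literal double loop.
moran_double_loop <- function(x, y, v, band) {
  n <- length(v)
  z <- v - mean(v)
  num <- 0; W <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      dij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (dij > 0 && dij <= band) {
        num <- num + z[i] * z[j]
        W <- W + 1
      }
    }
  }
  (n / W) * num / sum(z^2)
}

# Expected detection-history frequencies for one season by exhausting all
# 2^J histories (no missingness), given per-site psi and p.
exhaustive_expected_counts <- function(psi, p, J) {
  hists <- expand.grid(rep(list(0:1), J))
  E <- apply(hists, 1, function(h) {
    dh <- sum(h)
    sum(psi * p^dh * (1 - p)^(J - dh) + (1 - psi) * (dh == 0))
  })
  names(E) <- apply(hists, 1, paste, collapse = "")
  E
}
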