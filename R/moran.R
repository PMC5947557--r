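#' Moran's I with a fixed distance band
#'
#' Tests per-site values (for detection surveys, typically the proportion of
#' non-missing occasions with a detection in a season) for spatial
#' autocorrelation. Binary weights connect every pair of sites whose
#' planar distance is positive and at most `band`; I is the cross-product
#' statistic
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centred values z
#' and `W = sum_ij w_ij`. Under no autocorrelation `E[I] = -1/(n-1)`.
#' Significance is assessed by a permutation null (value labels shuffled
#' across sites) and, for reference, by the normal approximation under the
#' randomisation assumption.
#'
#' @param points Data frame with columns `x`, `y` (planar coordinates in
#'   metres) and a value column.
#' @param value Name of the value column (default `"value"`).
#' @param band Band distance in metres (default 3000): pairs strictly
#'   farther apart carry zero weight.
#' @param n_perm Number of permutations for the permutation p-value
#'   (default 999).
#' @param seed Integer seed for the permutations.
#' @return A one-row tibble with `I`, `expected`, `sd_norm`, `p_norm`
#'   (two-sided normal approximation), `p_perm` (two-sided permutation),
#'   `n_sites`, `n_links`.
#' @export
moran_test <- function(points, value = "value", band = 3000, n_perm = 999,
                       seed = 1L) {
  stopifnot(is.data.frame(points), all(c("x", "y", value) %in% names(points)))
  v <- points[[value]]
  n <- length(v)
  if (n < 8) warning("fewer than 8 sites: the test has little meaning")
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    stop("values are constant: Moran's I is undefined", call. = FALSE)
  }
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  W <- (D > 0 & D <= band) * 1
  sumW <- sum(W)
  if (sumW == 0) {
    stop("no site pairs within the ", band, " m band", call. = FALSE)
  }
  moran_stat <- function(vals) {
    z <- vals - mean(vals)
    (n / sumW) * drop(t(z) %*% W %*% z) / sum(z^2)
  }
  I_obs <- moran_stat(v)
  expected <- -1 / (n - 1)
  # randomisation-assumption variance (standard closed form)
  z <- v - mean(v)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- (sum(z^4) / n) / (sum(z^2) / n)^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * sumW^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * sumW^2)) /
    ((n - 1) * (n - 2) * (n - 3) * sumW^2) - expected^2
  sd_norm <- sqrt(max(varI, 0))
  p_norm <- 2 * stats::pnorm(-abs((I_obs - expected) / sd_norm))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) moran_stat(sample(v)), numeric(1))
  })
  # two-sided rank-based permutation p with the observed value included
  p_lo <- (sum(perm <= I_obs) + 1) / (n_perm + 1)
  p_hi <- (sum(perm >= I_obs) + 1) / (n_perm + 1)
  p_perm <- min(2 * min(p_lo, p_hi), 1)
  tibble::tibble(I = I_obs, expected = expected, sd_norm = sd_norm,
                 p_norm = p_norm, p_perm = p_perm, n_sites = n,
                 n_links = sumW)
}

#' Per-season site detection summaries for spatial screening
#'
#' Computes, for each site and season, the proportion of non-missing
#' occasions with a detection — the value fed to [moran_test()].
#'
#' @param data A [detection_array()].
#' @param points Data frame with `site_id`, `x`, `y` (one row per site).
#' @return A tibble with `site_id`, `x`, `y`, `season`, `value`; sites with
#'   a season fully missing are dropped for that season.
#' @export
detection_rates <- function(data, points) {
  stopifnot(inherits(data, "detection_array"),
            all(c("site_id", "x", "y") %in% names(points)))
  st <- detection_stats(data)
  purrr::map_dfr(seq_len(st$n_seasons), function(t) {
    keep <- st$nn[, t] > 0
    tibble::tibble(site_id = data$site_ids[keep],
                   season = data$season_labels[t],
                   value = st$d[keep, t] / st$nn[keep, t])
  }) |>
    dplyr::inner_join(dplyr::select(points, "site_id", "x", "y"),
                      by = "site_id") |>
    dplyr::select("site_id", "x", "y", "season", "value")
}
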