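#' Detection/non-detection history container
#'
#' A `detection_array` stores binary detection histories from a repeated
#' camera-trap survey as a 3-d array (site x season x occasion) with `NA`
#' marking missing occasions (camera malfunction or theft, an unsurveyed
#' season, or a season shorter than the maximum occasion count). A site may
#' have a whole season missing — e.g. units that joined the study from the
#' second season onwards — and such seasons contribute nothing to the model
#' likelihood.
#'
#' @param y 3-d numeric array, sites x seasons x occasions, values in
#'   `{0, 1, NA}`.
#' @param site_ids Character vector of site identifiers, one per row of `y`.
#' @param season_labels Ordered character vector of season labels.
#' @param occasions_per_season Integer vector giving the number of occasions
#'   scheduled in each season; occasions beyond this count are structurally
#'   missing.
#' @return An object of class `detection_array`.
#' @export
detection_array <- function(y, site_ids = NULL, season_labels = NULL,
                            occasions_per_season = NULL) {
  stopifnot(is.array(y), length(dim(y)) == 3)
  vals <- y[!is.na(y)]
  if (length(vals) == 0L) stop("all observations are missing", call. = FALSE)
  if (!all(vals %in% c(0, 1))) {
    stop("non-missing detection values must be 0 or 1", call. = FALSE)
  }
  n <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  site_ids <- site_ids %||% sprintf("site_%03d", seq_len(n))
  season_labels <- season_labels %||% sprintf("season_%d", seq_len(T))
  occasions_per_season <- occasions_per_season %||% rep(J, T)
  stopifnot(length(site_ids) == n, length(season_labels) == T,
            length(occasions_per_season) == T,
            all(occasions_per_season <= J))
  all_missing_site <- apply(y, 1, function(m) all(is.na(m)))
  if (any(all_missing_site)) {
    stop("site(s) with no non-missing occasion: ",
         paste(site_ids[all_missing_site], collapse = ", "), call. = FALSE)
  }
  structure(
    list(y = y, site_ids = site_ids, season_labels = season_labels,
         occasions_per_season = as.integer(occasions_per_season)),
    class = "detection_array"
  )
}

#' @export
print.detection_array <- function(x, ...) {
  d <- dim(x$y)
  n_det <- sum(x$y == 1, na.rm = TRUE)
  n_obs <- sum(!is.na(x$y))
  cat("<detection_array> ", d[1], " sites x ", d[2], " seasons x ", d[3],
      " occasions\n", sep = "")
  cat("  ", n_obs, " observed occasions, ", n_det, " detections (naive p = ",
      signif(n_det / n_obs, 3), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.detection_array <- function(x) dim(x$y)

#' Naive per-season occupancy
#'
#' Proportion of sites with at least one detection in each season, among sites
#' with at least one non-missing occasion that season. Uncorrected for
#' imperfect detection.
#'
#' @param x A [detection_array()].
#' @return A tibble with columns `season`, `n_sites`, `naive_occupancy`.
#' @export
naive_occupancy <- function(x) {
  stopifnot(inherits(x, "detection_array"))
  T <- dim(x$y)[2]
  purrr::map_dfr(seq_len(T), function(t) {
    m <- x$y[, t, , drop = FALSE]
    seen <- apply(m, 1, function(v) if (all(is.na(v))) NA else any(v == 1, na.rm = TRUE))
    tibble::tibble(
      season = x$season_labels[t],
      n_sites = sum(!is.na(seen)),
      naive_occupancy = mean(seen, na.rm = TRUE)
    )
  })
}

#' Pool paired camera-trap day records into survey occasions
#'
#' Two cameras monitor each sample unit; their day-level records are pooled
#' and collapsed into blocks of `block_days` consecutive days, each block one
#' independent sampling occasion. An occasion scores 1 if any non-missing day
#' on either camera has a detection, 0 if every non-missing day is 0, and
#' `NA` when all days on both cameras are missing (malfunction/theft).
#'
#' @param cam1,cam2 Numeric vectors of day-level records in `{0, 1, NA}`,
#'   aligned to the same calendar days.
#' @param block_days Days per occasion (default 2, the interval over which
#'   consecutive records are treated as non-independent).
#' @return Numeric vector of occasion values, length `length(cam1) / block_days`.
#' @export
pool_camera_histories <- function(cam1, cam2, block_days = 2L) {
  if (length(cam1) != length(cam2)) {
    stop("camera day ranges are misaligned: ", length(cam1), " vs ",
         length(cam2), " days", call. = FALSE)
  }
  ok <- function(v) all(v %in% c(0, 1) | is.na(v))
  if (!ok(cam1) || !ok(cam2)) {
    stop("day records must be 0, 1 or NA", call. = FALSE)
  }
  n_days <- length(cam1)
  if (n_days %% block_days != 0) {
    stop("number of days (", n_days, ") is not a multiple of block_days (",
         block_days, ")", call. = FALSE)
  }
  blocks <- rep(seq_len(n_days / block_days), each = block_days)
  vapply(split(c(cam1, cam2), c(blocks, blocks)), function(v) {
    if (all(is.na(v))) return(NA_real_)
    as.numeric(any(v == 1, na.rm = TRUE))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Convert a wide detection table to a detection array
#'
#' The wide layout has one row per site: a `site_id` column plus columns named
#' `season<t>_occ<j>` (1-based indices in headers).
#'
#' @param tbl A data frame in wide layout.
#' @param season_labels Optional season labels (defaults to `season_<t>`).
#' @return A [detection_array()].
#' @export
as_detection_array <- function(tbl, season_labels = NULL) {
  stopifnot(is.data.frame(tbl), "site_id" %in% names(tbl))
  occ_cols <- grep("^season[0-9]+_occ[0-9]+$", names(tbl), value = TRUE)
  if (length(occ_cols) == 0L) stop("no season<t>_occ<j> columns found", call. = FALSE)
  idx <- do.call(rbind, regmatches(occ_cols, regexec("^season([0-9]+)_occ([0-9]+)$", occ_cols)))
  t_idx <- as.integer(idx[, 2]); j_idx <- as.integer(idx[, 3])
  T <- max(t_idx); J <- max(j_idx)
  n <- nrow(tbl)
  y <- array(NA_real_, dim = c(n, T, J))
  for (k in seq_along(occ_cols)) {
    v <- tbl[[occ_cols[k]]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      bad <- which(!(v %in% c(0, 1) | is.na(v)))[1]
      stop("non-binary detection value at row ", bad, ", column ",
           occ_cols[k], call. = FALSE)
    }
    y[, t_idx[k], j_idx[k]] <- as.numeric(v)
  }
  occ_per_season <- vapply(seq_len(T), function(t) max(j_idx[t_idx == t]), integer(1))
  detection_array(y, site_ids = as.character(tbl$site_id),
                  season_labels = season_labels,
                  occasions_per_season = occ_per_season)
}

#' Convert a detection array to a wide tibble
#'
#' Inverse of [as_detection_array()]; columns are `site_id` then
#' `season<t>_occ<j>` with 1-based indices.
#'
#' @param x A [detection_array()].
#' @param ... Unused.
#' @return A tibble, one row per site.
#' @export
as_tibble.detection_array <- function(x, ...) {
  d <- dim(x$y)
  out <- tibble::tibble(site_id = x$site_ids)
  for (t in seq_len(d[2])) {
    for (j in seq_len(x$occasions_per_season[t])) {
      out[[sprintf("season%d_occ%d", t, j)]] <- x$y[, t, j]
    }
  }
  out
}

#' Read / write a wide detection CSV
#'
#' Missing cells are encoded as literal `NA`. `read_detection_csv` validates
#' that every cell is 0, 1 or missing and that rows are complete;
#' `write_detection_csv` round-trips exactly.
#'
#' @param path File path.
#' @param season_labels Optional season labels passed to [as_detection_array()].
#' @return `read_detection_csv`: a [detection_array()]. `write_detection_csv`:
#'   `path`, invisibly.
#' @export
read_detection_csv <- function(path, season_labels = NULL) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop("malformed detection table at ", path, ": row ", prob$row[1],
         ", column ", prob$col[1], " (", prob$expected[1], ")", call. = FALSE)
  }
  as_detection_array(tbl, season_labels = season_labels)
}

#' @rdname read_detection_csv
#' @param x A [detection_array()].
#' @export
write_detection_csv <- function(x, path) {
  stopifnot(inherits(x, "detection_array"))
  readr::write_csv(as_tibble.detection_array(x), path, na = "NA")
  invisible(path)
}
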