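#' Aggregate household questionnaire responses to sample-unit covariates
#'
#' One or two households are interviewed per sample unit. Binary event
#' covariates (e.g. whether a predation event was reported) take the value 1
#' if any household in the unit reports the event; quantitative covariates
#' take the household median when responses differ.
#'
#' @param records Data frame with a `site_id` column plus response columns.
#' @param binary_cols Character vector naming columns aggregated by presence
#'   (max); all other numeric columns are aggregated by median.
#' @return A tibble with one row per `site_id`.
#' @export
aggregate_household_responses <- function(records, binary_cols = character()) {
  stopifnot(is.data.frame(records), "site_id" %in% names(records))
  if (nrow(records) == 0L) {
    stop("no questionnaire records to aggregate", call. = FALSE)
  }
  value_cols <- setdiff(names(records), c("site_id", "respondent_id"))
  records |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(value_cols),
      ~ if (dplyr::cur_column() %in% binary_cols) max(.x) else stats::median(.x)
    ), .groups = "drop") |>
    tibble::as_tibble()
}

#' Standardise continuous covariates to z-scores
#'
#' Continuous covariates are centred and scaled to unit sample (n-1) standard
#' deviation before model fitting, except percentage covariates (e.g. forest
#' or shrub cover), which stay on their natural 0-100 scale so that fitted
#' effects read per percentage point.
#'
#' @param tbl Data frame of per-site covariates.
#' @param exclude Character vector of columns to leave untouched (percentage
#'   covariates, identifiers already excluded automatically).
#' @return A tibble with standardised columns; attributes `scaled_center` and
#'   `scaled_scale` record the transformation.
#' @export
standardise_covariates <- function(tbl, exclude = character()) {
  stopifnot(is.data.frame(tbl))
  num_cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  target <- setdiff(num_cols, exclude)
  target <- setdiff(target, c("site_id", "respondent_id"))
  ctr <- numeric(0); scl <- numeric(0)
  out <- tibble::as_tibble(tbl)
  for (cn in target) {
    s <- stats::sd(out[[cn]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardise zero-variance column '", cn, "'", call. = FALSE)
    }
    m <- mean(out[[cn]], na.rm = TRUE)
    out[[cn]] <- (out[[cn]] - m) / s
    ctr[cn] <- m; scl[cn] <- s
  }
  attr(out, "scaled_center") <- ctr
  attr(out, "scaled_scale") <- scl
  out
}

#' Screen covariates for collinearity
#'
#' Computes Pearson and Spearman correlations for every pair of numeric
#' columns and flags a pair when either |r| exceeds `threshold` (default .7).
#' From each flagged pair the covariate ranked higher in `priority` — the one
#' with greater ecological/social meaning — is retained and the other
#' dropped. Ties in priority are broken by column order.
#'
#' @param tbl Data frame of candidate covariates (numeric columns screened).
#' @param threshold Absolute correlation above which a pair is flagged.
#' @param priority Character vector of column names, most meaningful first.
#'   Must cover every column involved in a flagged pair.
#' @return A list with `retained` (character vector), `dropped` (tibble of
#'   dropped columns with the partner and correlations that triggered the
#'   drop), and `correlations` (tibble of all flagged pairs).
#' @export
collinearity_screen <- function(tbl, threshold = 0.7, priority = names(tbl)) {
  stopifnot(is.data.frame(tbl))
  num_cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("site_id", "respondent_id"))
  if (length(num_cols) < 2L) stop("need at least two numeric columns", call. = FALSE)
  prs <- utils::combn(num_cols, 2, simplify = FALSE)
  flagged <- purrr::map_dfr(prs, function(pr) {
    x <- tbl[[pr[1]]]; y <- tbl[[pr[2]]]
    rp <- suppressWarnings(stats::cor(x, y, method = "pearson",
                                      use = "pairwise.complete.obs"))
    rs <- suppressWarnings(stats::cor(x, y, method = "spearman",
                                      use = "pairwise.complete.obs"))
    tibble::tibble(var1 = pr[1], var2 = pr[2], pearson = rp, spearman = rs,
                   flagged = isTRUE(max(abs(c(rp, rs)), na.rm = TRUE) > threshold))
  })
  rank_of <- function(v) {
    r <- match(v, priority)
    if (anyNA(r)) {
      stop("priority list missing column(s) in a flagged pair: ",
           paste(v[is.na(r)], collapse = ", "), call. = FALSE)
    }
    r
  }
  dropped <- tibble::tibble(column = character(), kept_partner = character(),
                            pearson = numeric(), spearman = numeric())
  retained <- num_cols
  flg <- flagged[flagged$flagged, , drop = FALSE]
  for (i in seq_len(nrow(flg))) {
    v1 <- flg$var1[i]; v2 <- flg$var2[i]
    if (!(v1 %in% retained) || !(v2 %in% retained)) next
    r <- rank_of(c(v1, v2))
    loser <- if (r[1] <= r[2]) v2 else v1
    keeper <- setdiff(c(v1, v2), loser)
    retained <- setdiff(retained, loser)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      column = loser, kept_partner = keeper,
      pearson = flg$pearson[i], spearman = flg$spearman[i]
    ))
  }
  list(retained = retained, dropped = dropped, correlations = flagged)
}
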