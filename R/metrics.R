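# The seven per-individual movement covariates and the transformed matrix
# that feeds clustering: number of installations with detections, number of
# detections, mean time between consecutive detections (minutes), and the
# 25/50/75/99% quantiles of great-circle distance (km) between consecutive
# detections. The 99% quantile summarizes long-distance movement without
# collapsing to the single maximum hop.

#' Great-circle (haversine) distance in kilometres
#'
#' Spherical Earth of radius 6371.0 km. Vectorized with recycling.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  .assert_lat_lon(lat1, lon1)
  .assert_lat_lon(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371.0))
}

.covariates_one <- function(n_det, n_inst, gaps_sec, step_km) {
  tibble::tibble(
    n_installations = n_inst,
    n_detections = n_det,
    mean_gap_min = mean(gaps_sec) / 60,
    q25_km = unname(quantile(step_km, 0.25, type = 7)),
    q50_km = unname(quantile(step_km, 0.50, type = 7)),
    q75_km = unname(quantile(step_km, 0.75, type = 7)),
    q99_km = unname(quantile(step_km, 0.99, type = 7))
  )
}

#' Movement covariates for one track
#'
#' Distances are computed between the receiver coordinates of consecutive
#' detections in time order (within-installation receiver-to-receiver hops
#' included, since they are consecutive detections); quantiles use linear
#' interpolation between order statistics at positions `1 + (n-1)p`
#' (R's default type-7 convention). Tracks with fewer than `min_detections`
#' detections are rejected (return `NULL`), never silently dropped by the
#' table-level wrapper.
#'
#' @param track tibble of one individual's detections (columns `tag_id`,
#'   `timestamp`, `receiver_id`, `installation_id`, `latitude`, `longitude`);
#'   re-sorted defensively by (timestamp, receiver_id).
#' @param min_detections minimum detections to accept a track (default 2;
#'   gaps and distances need at least one consecutive pair).
#' @return one-row tibble with `tag_id` and the seven covariates, or `NULL`
#'   if the track is rejected.
#' @export
compute_covariates <- function(track, min_detections = 2L) {
  if (nrow(track) < min_detections || nrow(track) < 2) return(NULL)
  tr <- dplyr::arrange(track, .data$timestamp, .data$receiver_id)
  n <- nrow(tr)
  step_km <- haversine_km(tr$latitude[-n], tr$longitude[-n],
                          tr$latitude[-1], tr$longitude[-1])
  gaps <- diff(as.numeric(tr$timestamp))
  dplyr::bind_cols(
    tibble::tibble(tag_id = tr$tag_id[1]),
    .covariates_one(n, dplyr::n_distinct(tr$installation_id), gaps, step_km)
  )
}

#' Movement covariates for every individual in a detection table
#'
#' @param detections detections tibble (all individuals).
#' @param min_detections minimum detections per individual.
#' @return list with `covariates` (tibble: tag_id + seven covariates, one row
#'   per retained individual, in first-appearance tag order) and `excluded`
#'   (tibble: tag_id, n_detections, reason).
#' @export
covariate_table <- function(detections, min_detections = 2L) {
  min_detections <- max(as.integer(min_detections), 2L)
  if (nrow(detections) == 0) {
    return(list(
      covariates = tibble::tibble(tag_id = character()),
      excluded = tibble::tibble(tag_id = character(), n_detections = integer(),
                                reason = character())
    ))
  }
  d <- dplyr::arrange(detections, .data$tag_id, .data$timestamp, .data$receiver_id)
  d <- d |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::mutate(
      .plat = dplyr::lag(.data$latitude),
      .plon = dplyr::lag(.data$longitude),
      .gap = as.numeric(.data$timestamp) - dplyr::lag(as.numeric(.data$timestamp))
    ) |>
    dplyr::ungroup()
  has_prev <- !is.na(d$.plat)
  d$.step <- NA_real_
  d$.step[has_prev] <- haversine_km(d$.plat[has_prev], d$.plon[has_prev],
                                    d$latitude[has_prev], d$longitude[has_prev])
  cov <- d |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      n_installations = dplyr::n_distinct(.data$installation_id),
      n_detections = dplyr::n(),
      mean_gap_min = mean(.data$.gap, na.rm = TRUE) / 60,
      q25_km = unname(quantile(.data$.step, 0.25, na.rm = TRUE, type = 7)),
      q50_km = unname(quantile(.data$.step, 0.50, na.rm = TRUE, type = 7)),
      q75_km = unname(quantile(.data$.step, 0.75, na.rm = TRUE, type = 7)),
      q99_km = unname(quantile(.data$.step, 0.99, na.rm = TRUE, type = 7)),
      .groups = "drop"
    )
  # preserve first-appearance order of tags
  cov <- cov[match(unique(d$tag_id), cov$tag_id), ]
  keep <- cov$n_detections >= min_detections
  excluded <- tibble::tibble(
    tag_id = cov$tag_id[!keep],
    n_detections = cov$n_detections[!keep],
    reason = sprintf("fewer than %d detections", min_detections)
  )
  list(covariates = cov[keep, ], excluded = excluded)
}

#' Build the transformed covariate matrix for clustering
#'
#' Column-wise transform in fixed order: square root (to reduce skew), then
#' centre, then scale by the sample standard deviation (n - 1 denominator),
#' giving columns with mean 0 and sd 1. The raw matrix is retained alongside.
#'
#' @param covariates tibble from [covariate_table()] (`tag_id` + the seven
#'   covariate columns), or any tibble with those columns.
#' @return object of class `fmc_covariates`: list with `tag_id`, `raw`
#'   (matrix), `transformed` (matrix).
#' @export
build_covariate_matrix <- function(covariates) {
  stopifnot(nrow(covariates) >= 2)
  missing_cols <- setdiff(COVARIATE_NAMES, names(covariates))
  if (length(missing_cols) > 0) {
    abort(sprintf("covariate table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  raw <- as.matrix(covariates[, COVARIATE_NAMES])
  rownames(raw) <- covariates$tag_id
  if (any(raw < 0)) abort("covariates must be non-negative for the square-root transform")
  s <- sqrt(raw)
  sds <- apply(s, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance covariate column(s) after square root: %s (scaling undefined)",
                  paste(COVARIATE_NAMES[sds == 0], collapse = ", ")))
  }
  transformed <- scale(s, center = TRUE, scale = TRUE)
  attr(transformed, "scaled:center") <- NULL
  attr(transformed, "scaled:scale") <- NULL
  structure(list(tag_id = covariates$tag_id, raw = raw,
                 transformed = transformed),
            class = "fmc_covariates")
}
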