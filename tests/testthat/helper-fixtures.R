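# Shared fixtures, all generated in code. Expensive datasets are cached per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

# canonical study-condition dataset (the simulator's defaults)
canonical_dataset <- function() {
  if (is.null(.fixture_cache$canonical)) {
    .fixture_cache$canonical <- generate_dataset(simulation_config())
  }
  .fixture_cache$canonical
}

canonical_covmat <- function() {
  if (is.null(.fixture_cache$canonical_cm)) {
    cv <- covariate_table(canonical_dataset()$detections)
    .fixture_cache$canonical_cm <- build_covariate_matrix(cv$covariates)
  }
  .fixture_cache$canonical_cm
}

# a fast, small-scale analogue of the default configuration
small_config <- function(seed = 7L) {
  simulation_config(
    n_installations = 6L, coast_length_km = 800,
    # five receivers as in the canonical geometry: with fewer, a quarter or
    # more of consecutive detections share a receiver and q25 degenerates to
    # zero variance across all tags
    receivers_per_installation = 5L, receiver_spread_km = 1,
    imos_fraction = 0.34,
    counts = c(RESIDENT = 6L, OCCASIONAL = 8L, IRRUPTOR = 4L, ROAMER = 6L),
    archetypes = default_archetypes(track_days = 90L),
    seed = seed
  )
}

small_dataset <- function(seed = 7L) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dataset(small_config(seed))
  }
  .fixture_cache[[key]]
}

# hand-built detection rows
make_detections <- function(tag, time, receiver, installation, lat, lon, qc = 1L) {
  n <- max(lengths(list(tag, time, receiver, installation, lat, lon)))
  tibble::tibble(
    tag_id = rep_len(tag, n),
    species_label = NA_character_,
    timestamp = as.POSIXct(rep_len(time, n), tz = "UTC"),
    receiver_id = rep_len(receiver, n),
    station_id = NA_character_,
    installation_id = rep_len(installation, n),
    latitude = rep_len(lat, n),
    longitude = rep_len(lon, n),
    qc_flag = rep_len(as.integer(qc), n)
  )
}

# brute-force minimal W over all partitions of points into k non-empty groups
brute_force_w <- function(X, k) {
  n <- nrow(X)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    lab <- as.integer(grids[r, ])
    if (length(unique(lab)) < k) next
    W <- sum(vapply(seq_len(k), function(j) {
      pts <- X[lab == j, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    best <- min(best, W)
  }
  best
}

# a random single-tag track for property tests
random_track <- function(n, seed) {
  set.seed(seed)
  make_detections(
    tag = "T1",
    time = "2020-01-01 00:00:00",
    receiver = sprintf("R%02d", sample.int(8, n, replace = TRUE)),
    installation = sprintf("I%d", sample.int(3, n, replace = TRUE)),
    lat = runif(n, -44, -20),
    lon = runif(n, 140, 154)
  ) |>
    dplyr::mutate(timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                    sort(sample.int(5e6, n)))
}
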