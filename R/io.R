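# Reading and writing detection and installation tables.
#
# External CSV dialects:
#   detections: transmitter_id, detection_datetime (ISO 8601), receiver_name,
#     installation_name, station_name (optional), latitude, longitude,
#     QC_flag, species_common_name (optional)
#   installations: installation_name, installation_type ("IMOS"/"non-IMOS"),
#     receiver_name, latitude, longitude  (one row per receiver)

.DETECTION_MANDATORY <- c(
  "transmitter_id", "detection_datetime", "receiver_name",
  "installation_name", "latitude", "longitude", "QC_flag"
)

#' Read a detection log, applying quality-control filtering
#'
#' Reads a detections CSV, parses timestamps to UTC (second resolution),
#' validates coordinates, and keeps only rows whose QC flag is in `qc_keep`.
#' National-repository detection exports carry per-detection QC flags; flags
#' 1 and 2 are the conventional "pass" values and are kept by default.
#'
#' Rows with unparseable timestamps or out-of-range coordinates are never
#' silently dropped: they are collected in the `rejected` attribute of the
#' returned tibble (with a `reason` column) and a warning reports the count.
#' Rows removed by the QC filter are an ordinary filter, not rejections.
#'
#' @param path path to the detections CSV.
#' @param qc_keep integer QC flag values to retain (default `c(1, 2)`).
#' @return tibble with columns `tag_id`, `species_label`, `timestamp`
#'   (POSIXct, UTC), `receiver_id`, `station_id`, `installation_id`,
#'   `latitude`, `longitude`, `qc_flag`; attribute `rejected` holds the
#'   per-row rejection report.
#' @export
read_detections <- function(path, qc_keep = c(1L, 2L)) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(.DETECTION_MANDATORY, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("detections file is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  empty <- tibble::tibble(
    tag_id = character(), species_label = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    receiver_id = character(), station_id = character(),
    installation_id = character(),
    latitude = double(), longitude = double(), qc_flag = integer()
  )
  if (nrow(raw) == 0) {
    warn(sprintf("'%s' contains a header but no detection rows", path))
    attr(empty, "rejected") <- tibble::tibble(row = integer(), reason = character())
    return(empty)
  }
  ts <- suppressWarnings(readr::parse_datetime(raw$detection_datetime))
  ts <- as.POSIXct(floor(as.numeric(ts)), origin = "1970-01-01", tz = "UTC")
  lat <- suppressWarnings(readr::parse_double(raw$latitude))
  lon <- suppressWarnings(readr::parse_double(raw$longitude))
  qc <- suppressWarnings(as.integer(readr::parse_double(raw$QC_flag)))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180] <- "coordinate out of range or unparseable"
  reason[is.na(ts)] <- "unparseable timestamp"
  rejected <- tibble::tibble(row = which(!is.na(reason)), reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0) {
    warn(sprintf("%d row(s) rejected (see attr(, 'rejected')): %s",
                 nrow(rejected),
                 paste(utils::head(unique(rejected$reason), 3), collapse = "; ")))
  }
  ok <- is.na(reason) & !is.na(qc) & qc %in% as.integer(qc_keep)
  out <- tibble::tibble(
    tag_id = raw$transmitter_id[ok],
    species_label = if ("species_common_name" %in% names(raw)) raw$species_common_name[ok] else NA_character_,
    timestamp = ts[ok],
    receiver_id = raw$receiver_name[ok],
    station_id = if ("station_name" %in% names(raw)) raw$station_name[ok] else NA_character_,
    installation_id = raw$installation_name[ok],
    latitude = lat[ok],
    longitude = lon[ok],
    qc_flag = qc[ok]
  )
  attr(out, "rejected") <- rejected
  out
}

#' Write detections in the exchange CSV schema
#'
#' Serializes a detections tibble to the exact schema [read_detections()]
#' consumes; timestamps are written as ISO 8601 UTC with a `Z` suffix.
#' Output is byte-stable for a fixed input ordering.
#'
#' @param detections tibble as returned by [read_detections()] or
#'   [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- tibble::tibble(
    transmitter_id = detections$tag_id,
    detection_datetime = format(detections$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    receiver_name = detections$receiver_id,
    installation_name = detections$installation_id,
    station_name = if ("station_id" %in% names(detections)) detections$station_id else NA_character_,
    latitude = detections$latitude,
    longitude = detections$longitude,
    QC_flag = detections$qc_flag,
    species_common_name = if ("species_label" %in% names(detections)) detections$species_label else NA_character_
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the installation/receiver table
#'
#' One row per receiver. Installation centroids are the means of member
#' receiver coordinates. Errors if any receiver is listed under more than one
#' installation, or if an installation type is not "IMOS"/"non-IMOS".
#'
#' @param path installations CSV with columns installation_name,
#'   installation_type, receiver_name, latitude, longitude.
#' @return object of class `fmc_array`: list with `installations` (tibble:
#'   installation_id, installation_type, centroid_lat, centroid_lon,
#'   n_receivers) and `receivers` (tibble: receiver_id, installation_id,
#'   latitude, longitude).
#' @export
read_installations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    installation_name = readr::col_character(),
    installation_type = readr::col_character(),
    receiver_name = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double()
  ), progress = FALSE)
  needed <- c("installation_name", "installation_type", "receiver_name", "latitude", "longitude")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("installations file is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  receivers <- tibble::tibble(
    receiver_id = raw$receiver_name,
    installation_id = raw$installation_name,
    latitude = raw$latitude,
    longitude = raw$longitude
  )
  new_array(receivers,
            types = stats::setNames(raw$installation_type, raw$installation_name))
}

# Construct an fmc_array from a receiver table + installation type lookup,
# validating the membership partition.
new_array <- function(receivers, types) {
  dup <- receivers$receiver_id[duplicated(receivers$receiver_id)]
  if (length(dup) > 0) {
    per_inst <- unique(receivers[, c("receiver_id", "installation_id")])
    if (anyDuplicated(per_inst$receiver_id)) {
      abort(sprintf("receiver(s) assigned to more than one installation: %s",
                    paste(unique(dup), collapse = ", ")))
    }
  }
  .assert_lat_lon(receivers$latitude, receivers$longitude, "receiver")
  type_by_inst <- types[!duplicated(names(types))]
  bad_type <- setdiff(unique(type_by_inst), c("IMOS", "non-IMOS"))
  if (length(bad_type) > 0) {
    abort(sprintf("installation_type must be 'IMOS' or 'non-IMOS'; found: %s",
                  paste(bad_type, collapse = ", ")))
  }
  installations <- receivers |>
    dplyr::group_by(.data$installation_id) |>
    dplyr::summarise(centroid_lat = mean(.data$latitude),
                     centroid_lon = mean(.data$longitude),
                     n_receivers = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(installation_type = unname(type_by_inst[.data$installation_id])) |>
    dplyr::select("installation_id", "installation_type",
                  "centroid_lat", "centroid_lon", "n_receivers")
  if (anyNA(installations$installation_type)) {
    abort("every installation must have an installation_type")
  }
  structure(list(installations = installations, receivers = receivers),
            class = "fmc_array")
}

#' Write the installation/receiver table
#'
#' @param array an `fmc_array` (see [read_installations()], [simulate_array()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_installations <- function(array, path) {
  type_lookup <- stats::setNames(array$installations$installation_type,
                                 array$installations$installation_id)
  out <- tibble::tibble(
    installation_name = array$receivers$installation_id,
    installation_type = unname(type_lookup[array$receivers$installation_id]),
    receiver_name = array$receivers$receiver_id,
    latitude = array$receivers$latitude,
    longitude = array$receivers$longitude
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split detections into per-individual, time-ordered tracks
#'
#' Ties in timestamp are broken by receiver id (lexicographic) so that
#' consecutive-detection distance sequences are reproducible.
#'
#' @param detections detections tibble.
#' @return named list of tibbles, one per `tag_id`, each sorted by
#'   (timestamp, receiver_id). The track lengths partition the input:
#'   duplicated rows are kept as distinct detections.
#' @export
build_tracks <- function(detections) {
  if (nrow(detections) == 0) return(stats::setNames(list(), character(0)))
  d <- dplyr::arrange(detections, .data$tag_id, .data$timestamp, .data$receiver_id)
  split(d, factor(d$tag_id, levels = unique(d$tag_id)))
}
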