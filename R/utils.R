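# Internal helpers shared across modules.

# Deterministic counter-based substream seed: one master stream per dataset or
# analysis, split by an integer counter so results do not depend on the order
# in which individuals or stages are processed. Kept below 2^31 - 1.
substream_seed <- function(seed, counter) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(counter) * 30269 + 11213
  as.integer(s %% 2147483647)
}

.assert_lat_lon <- function(lat, lon, what = "coordinate") {
  bad <- !is.finite(lat) | !is.finite(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    abort(sprintf(
      "%d %s(s) out of range or non-finite (latitude must be in [-90, 90], longitude in [-180, 180])",
      sum(bad), what
    ))
  }
  invisible(TRUE)
}

# All permutations of a vector (used for exact bijective cluster matching).
.permutations <- function(v) {
  n <- length(v)
  if (n <= 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Best bijective agreement between two labelings
#'
#' Builds the contingency table between a clustering and a reference labeling
#' and finds the injective cluster-to-reference mapping that maximizes the
#' number of agreeing observations. Used to score archetype recovery on
#' simulated data and to compare Full-array and subset clusterings.
#'
#' @param labels vector of cluster labels.
#' @param reference vector of reference labels, same length.
#' @return list with `accuracy` (matched fraction), `table` (contingency
#'   table), and `mapping` (named character vector cluster -> reference).
#' @export
match_clusters <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  tab <- table(cluster = as.character(labels), reference = as.character(reference))
  r <- nrow(tab); c <- ncol(tab)
  # enumerate injective maps from the smaller side into the larger
  if (max(r, c) > 8) {
    # greedy fallback for large label sets
    t2 <- tab
    map <- character(0)
    while (nrow(t2) > 0 && ncol(t2) > 0) {
      ij <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
      map[rownames(t2)[ij[1]]] <- colnames(t2)[ij[2]]
      t2 <- t2[-ij[1], -ij[2], drop = FALSE]
    }
    matched <- sum(tab[cbind(names(map), unname(map))])
    return(list(accuracy = matched / length(labels), table = tab, mapping = map))
  }
  best <- -1L; best_map <- NULL
  if (r <= c) {
    for (p in .permutations(seq_len(c))) {
      sel <- p[seq_len(r)]
      m <- sum(tab[cbind(seq_len(r), sel)])
      if (m > best) { best <- m; best_map <- setNames(colnames(tab)[sel], rownames(tab)) }
    }
  } else {
    for (p in .permutations(seq_len(r))) {
      sel <- p[seq_len(c)]
      m <- sum(tab[cbind(sel, seq_len(c))])
      if (m > best) { best <- m; best_map <- setNames(colnames(tab), rownames(tab)[sel]) }
    }
  }
  list(accuracy = best / length(labels), table = tab, mapping = best_map)
}
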