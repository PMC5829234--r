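# Relative-movement networks over installations. Edge weight a -> b is the
# number of times individuals moved between installations a and b divided by
# the total number of between-installation movements (pooled over
# individuals by default). Metric conventions, fixed here: density counts
# directed edges over n(n-1); path metrics (diameter, average path length)
# use unweighted directed shortest paths on the largest weakly connected
# component; strength is the sum of in- plus out-weights; eigenvector
# centrality is computed on the symmetrized weighted graph and scaled to a
# maximum of 1; betweenness is directed and unweighted. Together with edge
# count, node count, community count, modularity, reciprocity and
# transitivity this gives 9 network-level and 5 node-level metrics.

.subset_types <- c(full = NA, imos = "IMOS", non_imos = "non-IMOS")

.installation_table <- function(installations) {
  if (inherits(installations, "fmc_array")) installations$installations else installations
}

#' Relative-movement matrix between installations
#'
#' Detections are first restricted to installations of the requested type
#' (so a tag passing through an excluded installation contributes a "skip"
#' transition between the surviving neighbours), then transitions are the
#' consecutive-detection pairs at different installations within each
#' individual. Installations with no retained transitions are dropped.
#'
#' @param detections detections tibble.
#' @param installations an `fmc_array` or its `installations` tibble
#'   (installation_id, installation_type).
#' @param subset `"full"`, `"imos"`, or `"non_imos"`.
#' @param tag_filter optional character vector of tag ids to keep (used for
#'   per-class networks).
#' @param normalization `"pooled"` divides all counts by the grand total of
#'   transitions; `"per_individual"` normalizes each individual's counts to
#'   sum to 1 and averages the resulting matrices over individuals.
#' @return object of class `fmc_rmm`: list with `matrix` (square, named,
#'   zero diagonal, entries summing to 1 when any transition exists),
#'   `counts` (raw transition counts), `n_transitions`, `subset`,
#'   `normalization`. Zero transitions overall give an empty (0 x 0) matrix
#'   with a warning.
#' @export
relative_movement_matrix <- function(detections, installations,
                                     subset = c("full", "imos", "non_imos"),
                                     tag_filter = NULL,
                                     normalization = c("pooled", "per_individual")) {
  subset <- match.arg(subset)
  normalization <- match.arg(normalization)
  inst <- .installation_table(installations)
  d <- detections
  if (!is.null(tag_filter)) d <- d[d$tag_id %in% tag_filter, ]
  if (subset != "full") {
    keep_inst <- inst$installation_id[inst$installation_type == .subset_types[[subset]]]
    d <- d[d$installation_id %in% keep_inst, ]
  } else {
    d <- d[d$installation_id %in% inst$installation_id, ]
  }
  empty <- function() {
    warn(sprintf("no between-installation transitions in the '%s' subset; empty network", subset))
    structure(list(matrix = matrix(numeric(0), 0, 0), counts = matrix(integer(0), 0, 0),
                   n_transitions = 0L, subset = subset, normalization = normalization),
              class = "fmc_rmm")
  }
  if (nrow(d) < 2) return(empty())
  d <- dplyr::arrange(d, .data$tag_id, .data$timestamp, .data$receiver_id)
  same_tag <- d$tag_id[-1] == d$tag_id[-nrow(d)]
  from <- d$installation_id[-nrow(d)][same_tag]
  to <- d$installation_id[-1][same_tag]
  tag <- d$tag_id[-1][same_tag]
  moved <- from != to
  if (!any(moved)) return(empty())
  from <- from[moved]; to <- to[moved]; tag <- tag[moved]
  nodes <- sort(unique(c(from, to)))
  f <- factor(from, nodes); t2 <- factor(to, nodes)
  counts <- unclass(table(f, t2))
  dimnames(counts) <- list(nodes, nodes)
  if (normalization == "pooled") {
    M <- counts / sum(counts)
  } else {
    tags <- unique(tag)
    M <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (tg in tags) {
      sel <- tag == tg
      ct <- unclass(table(factor(from[sel], nodes), factor(to[sel], nodes)))
      M <- M + ct / sum(ct)
    }
    M <- M / length(tags)
  }
  structure(list(matrix = M, counts = counts, n_transitions = length(from),
                 subset = subset, normalization = normalization),
            class = "fmc_rmm")
}

.rmm_matrix <- function(x) if (inherits(x, "fmc_rmm")) x$matrix else as.matrix(x)

.as_graphs <- function(M) {
  g <- igraph::graph_from_adjacency_matrix(M, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  gs <- igraph::graph_from_adjacency_matrix(M + t(M), mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  list(directed = g, symmetric = gs)
}

#' Detect installation communities
#'
#' Modularity-maximizing greedy agglomeration on the symmetrized weighted
#' graph, with nodes put in lexicographic order first so membership does not
#' depend on input order. Isolated installations form singleton communities.
#'
#' @param M an `fmc_rmm` or a square weighted adjacency matrix.
#' @return object of class `fmc_communities`: list with `membership`
#'   (tibble: installation_id, community), `n_communities`, `modularity`,
#'   `edges` (tibble: from, to, weight, within_community).
#' @export
detect_communities <- function(M) {
  A <- .rmm_matrix(M)
  if (nrow(A) == 0) {
    return(structure(list(
      membership = tibble::tibble(installation_id = character(), community = integer()),
      n_communities = 0L, modularity = NA_real_,
      edges = tibble::tibble(from = character(), to = character(),
                             weight = double(), within_community = logical())
    ), class = "fmc_communities"))
  }
  ord <- order(rownames(A))
  A <- A[ord, ord, drop = FALSE]
  gs <- .as_graphs(A)$symmetric
  cl <- igraph::cluster_fast_greedy(gs, weights = if (igraph::ecount(gs) > 0) igraph::E(gs)$weight else NULL)
  memb <- igraph::membership(cl)
  # canonical community ids: order of first appearance over sorted nodes
  ids <- as.integer(factor(memb, levels = unique(memb)))
  membership <- tibble::tibble(installation_id = rownames(A), community = ids)
  lookup <- stats::setNames(ids, rownames(A))
  el <- which(A > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(A)[el[, 1]], to = colnames(A)[el[, 2]],
    weight = A[el],
    within_community = lookup[rownames(A)[el[, 1]]] == lookup[colnames(A)[el[, 2]]]
  )
  structure(list(membership = membership,
                 n_communities = length(unique(ids)),
                 modularity = igraph::modularity(cl),
                 edges = edges),
            class = "fmc_communities")
}

#' Network- and installation-level metrics of a relative-movement network
#'
#' @param M an `fmc_rmm` or a square weighted adjacency matrix.
#' @return object of class `fmc_netsummary`: list with `network` (one-row
#'   tibble: n_nodes, n_edges, density, diameter, avg_path_length,
#'   n_communities, modularity, reciprocity, transitivity) and `nodes`
#'   (tibble per installation: in_degree, out_degree, strength,
#'   eigenvector, betweenness). Path metrics are `NA` for degenerate
#'   (single-node or empty) networks.
#' @export
network_metrics <- function(M) {
  A <- .rmm_matrix(M)
  n <- nrow(A)
  if (n == 0) {
    return(structure(list(
      network = tibble::tibble(n_nodes = 0L, n_edges = 0L, density = NA_real_,
                               diameter = NA_real_, avg_path_length = NA_real_,
                               n_communities = 0L, modularity = NA_real_,
                               reciprocity = NA_real_, transitivity = NA_real_),
      nodes = tibble::tibble(installation_id = character(), in_degree = integer(),
                             out_degree = integer(), strength = double(),
                             eigenvector = double(), betweenness = double())
    ), class = "fmc_netsummary"))
  }
  gg <- .as_graphs(A)
  g <- gg$directed; gs <- gg$symmetric
  m <- igraph::ecount(g)
  density <- if (n > 1) m / (n * (n - 1)) else 0
  if (m > 0) {
    comp <- igraph::components(g, mode = "weak")
    big <- which.max(comp$csize)
    lwc <- igraph::induced_subgraph(g, which(comp$membership == big))
    diam <- igraph::diameter(lwc, directed = TRUE, weights = NA)
    apl <- igraph::mean_distance(lwc, directed = TRUE, weights = NA)
  } else {
    diam <- NA_real_; apl <- NA_real_
  }
  comm <- detect_communities(A)
  recip <- if (m > 0) igraph::reciprocity(g) else NA_real_
  trans <- igraph::transitivity(g, type = "global")
  ec <- if (igraph::ecount(gs) > 0) {
    igraph::eigen_centrality(gs, weights = igraph::E(gs)$weight)$vector
  } else {
    stats::setNames(rep(0, n), rownames(A))
  }
  nodes <- tibble::tibble(
    installation_id = rownames(A),
    in_degree = as.integer(igraph::degree(g, mode = "in")[rownames(A)]),
    out_degree = as.integer(igraph::degree(g, mode = "out")[rownames(A)]),
    strength = as.numeric(igraph::strength(g, mode = "all")[rownames(A)]),
    eigenvector = as.numeric(ec[rownames(A)]),
    betweenness = as.numeric(igraph::betweenness(g, directed = TRUE, weights = NA)[rownames(A)])
  )
  structure(list(
    network = tibble::tibble(
      n_nodes = n, n_edges = as.integer(m), density = density,
      diameter = as.numeric(diam), avg_path_length = apl,
      n_communities = comm$n_communities, modularity = comm$modularity,
      reciprocity = recip, transitivity = trans
    ),
    nodes = nodes
  ), class = "fmc_netsummary")
}

#' Per-class relative-movement networks
#'
#' Builds one Full-subset network per functional movement class from that
#' class's tags only, with metrics and communities. Classes without
#' between-installation movement yield empty-network entries (with the
#' warning from [relative_movement_matrix()]); this is expected for strongly
#' resident classes.
#'
#' @param detections detections tibble.
#' @param installations an `fmc_array` or installations tibble.
#' @param assignment an `fmc_assignment` (tag_id, class_name).
#' @param normalization passed to [relative_movement_matrix()].
#' @return named list (one entry per class) of lists with `rmm`, `summary`,
#'   `communities` (the latter two `NULL` for empty networks).
#' @export
per_fmc_networks <- function(detections, installations, assignment,
                             normalization = "pooled") {
  classes <- unique(assignment$class_name)
  out <- list()
  for (cl in classes) {
    tags <- assignment$tag_id[assignment$class_name == cl]
    rmm <- relative_movement_matrix(detections, installations, subset = "full",
                                    tag_filter = tags,
                                    normalization = normalization)
    out[[cl]] <- if (nrow(rmm$matrix) == 0) {
      list(rmm = rmm, summary = NULL, communities = NULL)
    } else {
      list(rmm = rmm, summary = network_metrics(rmm),
           communities = detect_communities(rmm))
    }
  }
  out
}
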