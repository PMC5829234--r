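# Relative-movement matrices, network metrics, and community detection.

toy_installations <- function(ids = c("A", "B", "C"),
                              types = c("IMOS", "non-IMOS", "non-IMOS")) {
  tibble::tibble(installation_id = ids, installation_type = types,
                 centroid_lat = seq(-30, by = 1, length.out = length(ids)),
                 centroid_lon = 150, n_receivers = 1L)
}

moves <- function(tag, insts, start = "2020-01-01 00:00:00") {
  make_detections(tag, start, receiver = paste0(insts, "_R1"),
                  installation = insts, lat = -30, lon = 150) |>
    dplyr::mutate(timestamp = as.POSIXct(start, tz = "UTC") +
                    3600 * seq_along(insts))
}

test_that("relative movements are counted and normalized as defined", {
  inst <- toy_installations()
  det <- dplyr::bind_rows(moves("t1", c("A", "B", "A")), moves("t2", c("A", "C")))
  rmm <- relative_movement_matrix(det, inst)
  # 3 total transitions: A->B, B->A, A->C
  expect_equal(rmm$n_transitions, 3L)
  expect_equal(rmm$matrix["A", "B"], 1 / 3)
  expect_equal(rmm$matrix["B", "A"], 1 / 3)
  expect_equal(rmm$matrix["A", "C"], 1 / 3)
  expect_equal(sum(rmm$matrix), 1)
  expect_true(all(diag(rmm$matrix) == 0))

  # repeated detections at the same installation are not movements
  det2 <- moves("t1", c("A", "A", "B"))
  rmm2 <- relative_movement_matrix(det2, inst)
  expect_equal(rmm2$matrix["A", "B"], 1)
  expect_equal(rmm2$n_transitions, 1L)

  # all detections at one installation -> empty network with a warning
  expect_warning(rmm3 <- relative_movement_matrix(moves("t1", c("A", "A")), inst),
                 "empty network")
  expect_equal(nrow(rmm3$matrix), 0)

  # per-individual normalization still sums to 1
  rmm4 <- relative_movement_matrix(det, inst, normalization = "per_individual")
  expect_equal(sum(rmm4$matrix), 1)
  # t2's matrix is all-in on A->C (its only transition); mean over 2 tags
  expect_equal(rmm4$matrix["A", "C"], 1 / 2)
  expect_equal(rmm4$matrix["A", "B"], 1 / 4)
})

test_that("subsetting filters detections before transitions are formed", {
  inst <- toy_installations(c("A", "B", "C"), c("IMOS", "non-IMOS", "IMOS"))
  # tag passes A (IMOS) -> B (non-IMOS) -> C (IMOS); IMOS subset sees A -> C
  det <- moves("t1", c("A", "B", "C"))
  full <- relative_movement_matrix(det, inst, subset = "full")
  imos <- relative_movement_matrix(det, inst, subset = "imos")
  expect_equal(full$n_transitions, 2L)
  expect_equal(imos$n_transitions, 1L)
  expect_equal(imos$matrix["A", "C"], 1)
  expect_false("B" %in% rownames(imos$matrix))
  # IMOS and non-IMOS node sets partition the full node set by type
  expect_warning(non <- relative_movement_matrix(det, inst, subset = "non_imos"))
  expect_length(intersect(rownames(imos$matrix), rownames(non$matrix)), 0)
})

test_that("network metrics match hand computations on canonical graphs", {
  # complete directed triangle
  M <- matrix(1 / 6, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(M) <- 0
  s <- network_metrics(M)
  expect_equal(s$network$n_nodes, 3)
  expect_equal(s$network$n_edges, 6L)
  expect_equal(s$network$density, 1)
  expect_equal(s$network$diameter, 1)
  expect_equal(s$network$avg_path_length, 1)
  expect_equal(s$network$reciprocity, 1)

  # directed path A -> B -> C
  P <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  P["A", "B"] <- 0.5; P["B", "C"] <- 0.5
  sp <- network_metrics(P)
  expect_equal(sp$network$density, 2 / 6, tolerance = 1e-12)
  expect_equal(sp$network$diameter, 2)
  # reachable directed pairs: A->B (1), B->C (1), A->C (2)
  expect_equal(sp$network$avg_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(sp$nodes$in_degree, c(0L, 1L, 1L))
  expect_equal(sp$nodes$out_degree, c(1L, 1L, 0L))
  expect_equal(sp$nodes$strength, c(0.5, 1.0, 0.5))

  # symmetric star: centre has strictly maximal eigenvector centrality
  n <- 6
  S <- matrix(0, n, n, dimnames = list(paste0("N", 1:n), paste0("N", 1:n)))
  S["N1", paste0("N", 2:n)] <- 0.1
  S[paste0("N", 2:n), "N1"] <- 0.1
  ss <- network_metrics(S)
  ec <- ss$nodes$eigenvector
  expect_equal(ss$nodes$installation_id[which.max(ec)], "N1")
  expect_equal(max(ec), 1)
  expect_true(all(ec[-which.max(ec)] < 1))
})

test_that("community detection recovers planted structure, order-invariantly", {
  # two disconnected dyads
  M <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  M["a", "b"] <- M["b", "a"] <- 0.25
  M["c", "d"] <- M["d", "c"] <- 0.25
  cm <- detect_communities(M)
  expect_equal(cm$n_communities, 2)
  memb <- stats::setNames(cm$membership$community, cm$membership$installation_id)
  expect_equal(memb[["a"]], memb[["b"]])
  expect_equal(memb[["c"]], memb[["d"]])
  expect_false(memb[["a"]] == memb[["c"]])

  # two dense 5-cliques joined by one weak edge
  ids <- paste0("n", 1:10)
  A <- matrix(0, 10, 10, dimnames = list(ids, ids))
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 0.01
  cl <- detect_communities(A / sum(A))
  memb <- stats::setNames(cl$membership$community, cl$membership$installation_id)
  expect_equal(length(unique(memb[ids[1:5]])), 1)
  expect_equal(length(unique(memb[ids[6:10]])), 1)
  expect_false(memb[["n1"]] == memb[["n10"]])

  # permuting the node order leaves membership unchanged
  perm <- c(7, 3, 10, 1, 5, 2, 8, 6, 4, 9)
  cl2 <- detect_communities(A[perm, perm] / sum(A))
  m2 <- stats::setNames(cl2$membership$community, cl2$membership$installation_id)
  expect_identical(m2[names(memb)], memb)

  # isolated node forms a singleton community
  B <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  B["x", "y"] <- B["y", "x"] <- 0.5
  cb <- detect_communities(B)
  expect_equal(cb$n_communities, 2)
})

test_that("per-class networks partition the full transition counts", {
  ds <- small_dataset()
  cv <- covariate_table(ds$detections)
  cm <- build_covariate_matrix(cv$covariates)
  fit <- kmeans_fit(cm$transformed, 4, seed = 3)
  asn <- name_clusters(fit, cm)
  full <- relative_movement_matrix(ds$detections, ds$array)
  nets <- suppressWarnings(per_fmc_networks(ds$detections, ds$array, asn))

  # union of per-class counts equals the full counts
  agg <- matrix(0, nrow(full$counts), ncol(full$counts),
                dimnames = dimnames(full$counts))
  for (cl in names(nets)) {
    ct <- nets[[cl]]$rmm$counts
    if (length(ct) > 0) agg[rownames(ct), colnames(ct)] <- agg[rownames(ct), colnames(ct)] + ct
  }
  expect_equal(agg, full$counts, ignore_attr = TRUE)

  # every non-empty class matrix is normalized
  for (cl in names(nets)) {
    M <- nets[[cl]]$rmm$matrix
    if (nrow(M) > 0) {
      expect_equal(sum(M), 1, tolerance = 1e-12, info = cl)
      expect_true(all(diag(M) == 0), info = cl)
    }
  }

  # residents move less than roamers
  if (!is.null(nets$Residents$summary) && !is.null(nets$Roamers$summary)) {
    expect_lte(nets$Residents$summary$network$n_edges,
               nets$Roamers$summary$network$n_edges)
  }
})
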