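# k-means, gap-statistic model selection, class naming, sensitivity, PCA.

test_that("k-means attains the exhaustive-enumeration optimum on small instances", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(8), 4, 2)
    for (k in 2:3) {
      fit <- kmeans_fit(X, k, n_init = 30, seed = rep)
      expect_equal(fit$W_k, brute_force_w(X, k), tolerance = 1e-9,
                   info = sprintf("rep %d k %d", rep, k))
    }
  }

  # two well-separated 2-point groups at k = 2 are split cleanly
  X <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  fit <- kmeans_fit(X, 2, n_init = 10, seed = 1)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
  # W = sum of within-pair squared distances to pair means: 2 * (0.5^2 + 0.5^2)
  expect_equal(fit$W_k, 1, tolerance = 1e-12)

  # one point per cluster -> zero dispersion
  expect_equal(kmeans_fit(X, 4, seed = 2)$W_k, 0)

  # determinism
  set.seed(99)
  Y <- matrix(rnorm(60), 20, 3)
  expect_identical(kmeans_fit(Y, 3, seed = 7)$labels, kmeans_fit(Y, 3, seed = 7)$labels)
})

test_that("the Lloyd fallback repairs empty clusters deterministically", {
  X <- rbind(matrix(rnorm(20, 0, .1), 10, 2), matrix(rnorm(20, 10, .1), 10, 2))
  # third center absurdly far away: goes empty on the first assignment
  cen <- rbind(c(0, 0), c(0.05, 0.05), c(100, 100))
  fit <- moveclass:::.lloyd_reseed(X, cen)
  expect_equal(sort(unique(fit$cluster)), 1:3)
  expect_true(all(tabulate(fit$cluster, 3) > 0))
})

test_that("the one-standard-error selection rule applies as stated", {
  expect_equal(select_gap_k(c(1.0, 1.5, 1.55), c(0.1, 0.1, 0.1)), 2L)
  expect_equal(select_gap_k(c(2.0, 1.5), c(0.1, 0.1)), 1L)
  expect_warning(k <- select_gap_k(c(1, 2, 3), c(0.01, 0.01, 0.01)), "k_max")
  expect_equal(k, 3L)
})

test_that("gap statistic recovers planted structure and the null case", {
  set.seed(8)
  X4 <- rbind(matrix(rnorm(160, 0), 80, 2), matrix(rnorm(160, 8), 80, 2),
              cbind(rnorm(80, 0), rnorm(80, 8)), cbind(rnorm(80, 8), rnorm(80, 0)))
  hits <- vapply(1:5, function(s) {
    gap_statistic(X4, k_max = 6, B = 20, n_init = 10, seed = 500 + s)$chosen_k
  }, integer(1))
  expect_gte(sum(hits == 4), 4)

  null_hits <- vapply(1:5, function(s) {
    set.seed(700 + s)
    Xb <- matrix(runif(400), 200, 2)
    suppressWarnings(gap_statistic(Xb, k_max = 5, B = 20, n_init = 10,
                                   seed = 800 + s)$chosen_k)
  }, integer(1))
  expect_gte(sum(null_hits == 1), 4)

  expect_error(gap_statistic(matrix(c(1, NA, 2, 3), 2, 2), k_max = 2),
               "non-finite")
})

test_that("gap curve agrees with the clusGap reference implementation", {
  set.seed(21)
  X <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2), matrix(rnorm(100, 6, 0.5), 50, 2),
             cbind(rnorm(50, 0, 0.5), rnorm(50, 6, 0.5)))
  mine <- gap_statistic(X, k_max = 5, B = 30, n_init = 20, seed = 4)
  set.seed(5)
  ref <- cluster::clusGap(X, FUN = function(x, k) kmeans(x, k, nstart = 20, iter.max = 100),
                          K.max = 5, B = 30, d.power = 2, spaceH0 = "original",
                          verbose = FALSE)
  # same data log-dispersion curve up to clusGap's halved pairwise-sum
  # convention (W_clusGap = W / 2, a constant log(2) offset that cancels in
  # the gap values)
  expect_equal(mine$curve$log_Wk - log(2), unname(ref$Tab[, "logW"]),
               tolerance = 1e-6)
  # same selection under the Tibshirani one-SE rule
  ref_k <- cluster::maxSE(ref$Tab[, "gap"], ref$Tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  expect_equal(mine$chosen_k, ref_k)
  expect_equal(mine$chosen_k, 3L)
})

fake_fit <- function(labels, tags) {
  structure(list(k = length(unique(labels)),
                 labels = stats::setNames(as.integer(labels), tags),
                 centroids = NULL, W_k = NA_real_, n_init = 1L, seed = NULL),
            class = "fmc_kmeans")
}

test_that("class naming follows the covariate heuristic and is relabel-invariant", {
  tags <- sprintf("t%d", 1:8)
  raw <- tibble::tibble(
    tag_id = tags,
    n_installations = c(1, 1, 2, 2, 1, 1, 9, 9),
    n_detections = c(5e4, 5e4, 3e3, 3e3, 3e4, 3e4, 1e3, 1e3),
    mean_gap_min = c(30, 30, 4000, 4000, 40, 40, 500, 500),
    q25_km = rep(0.5, 8), q50_km = rep(1, 8), q75_km = c(rep(2, 6), 5, 5),
    q99_km = c(3, 3, 50, 50, 8, 8, 700, 700)
  )
  fit <- fake_fit(c(1, 1, 2, 2, 3, 3, 4, 4), tags)
  asn <- name_clusters(fit, raw)
  map <- attr(asn, "class_map")
  expect_setequal(unname(map), c("Residents", "Occasionals", "Irruptors", "Roamers"))
  expect_equal(asn$class_name[1], "Residents")     # max detections
  expect_equal(asn$class_name[3], "Occasionals")   # max mean gap
  expect_equal(asn$class_name[5], "Irruptors")     # remainder
  expect_equal(asn$class_name[7], "Roamers")       # max q99

  # permuting cluster indices leaves tag -> name unchanged
  fit2 <- fake_fit(c(4, 4, 3, 3, 2, 2, 1, 1), tags)
  asn2 <- name_clusters(fit2, raw)
  expect_equal(asn2$class_name, asn$class_name)

  # non-four fits get numeric names
  asn3 <- name_clusters(fake_fit(c(1, 1, 2, 2, 3, 3, 3, 3), tags), raw)
  expect_setequal(unique(asn3$class_name), c("class_1", "class_2", "class_3"))

  # an exact tie in a deciding mean demands manual naming
  raw_tied <- raw
  raw_tied$q99_km <- rep(5, 8)
  expect_error(name_clusters(fit, raw_tied), "tie")
})

test_that("naming on simulated data matches the majority truth archetype", {
  ds <- canonical_dataset()
  cm <- canonical_covmat()
  fit <- kmeans_fit(cm$transformed, 4, seed = 17)
  asn <- name_clusters(fit, cm)
  truth <- ds$truth$archetype[match(asn$tag_id, ds$truth$tag_id)]
  # The Irruptor archetype is the smallest and overlaps the site-attached
  # classes (rare excursions barely move its step quantiles), so its named
  # cluster is not required to have an Irruptor majority; the three
  # well-separated classes must match.
  expected <- c(Residents = "RESIDENT", Occasionals = "OCCASIONAL",
                Roamers = "ROAMER")
  for (cl in names(expected)) {
    in_cl <- truth[asn$class_name == cl]
    expect_equal(names(which.max(table(in_cl))), unname(expected[cl]), info = cl)
  }
  expect_setequal(unique(asn$class_name),
                  c("Residents", "Occasionals", "Irruptors", "Roamers"))
})

test_that("sensitivity analysis is deterministic and honours removal sizes", {
  set.seed(13)
  X <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 6), 40, 2))
  full_k <- gap_statistic(X, k_max = 3, B = 12, n_init = 8, seed = 9)$chosen_k
  s1 <- sensitivity_analysis(X, removal_sizes = c(0L, 5L), iterations = 3,
                             k_max = 3, B = 12, n_init = 8, seed = 77)
  # removal of nothing reproduces the full-data selection in every iteration
  expect_true(all(s1$results$chosen_k[s1$results$removal_size == 0] == full_k))
  # same master seed, identical per-iteration lists
  s2 <- sensitivity_analysis(X, removal_sizes = c(0L, 5L), iterations = 3,
                             k_max = 3, B = 12, n_init = 8, seed = 77)
  expect_identical(s1$results, s2$results)
  expect_equal(nrow(s1$summary), 2)
  expect_error(sensitivity_analysis(X, removal_sizes = 80L, iterations = 1,
                                    k_max = 3, B = 12, seed = 1), "smaller")
})

test_that("PCA projection matches a direct SVD and reports variance shares", {
  set.seed(23)
  X <- scale(matrix(rnorm(140), 20, 7))
  p <- pca_project(X)
  sv <- svd(X)
  scores_ref <- sv$u %*% diag(sv$d)
  # compare up to the fixed sign convention via absolute values
  expect_equal(abs(p$scores$PC1), abs(scores_ref[, 1]), tolerance = 1e-8)
  expect_equal(abs(p$scores$PC2), abs(scores_ref[, 2]), tolerance = 1e-8)
  # sign convention: dominant loading of each component is positive
  expect_gt(p$rotation[which.max(abs(p$rotation[, 1])), 1], 0)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  expect_gte(p$percent_variance[1], p$percent_variance[2])

  # variance concentrated in one column -> first dimension explains all of it
  X1 <- cbind(rnorm(10), 0, 0)
  expect_equal(pca_project(X1)$percent_variance[1], 100, tolerance = 1e-9)

  expect_error(pca_project(matrix(0, 3, 7)), "at least as many rows")
})
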