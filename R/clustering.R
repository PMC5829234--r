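# Partitioning individuals into functional movement classes: k-means with
# multiple restarts, gap-statistic model selection, a-posteriori class
# naming, PCA visualization coordinates, and the tag-removal sensitivity
# analysis.

# Lloyd iterations with a deterministic empty-cluster repair: an emptied
# centroid is reseeded at the point currently farthest from its assigned
# centroid (first index on ties). Used as fallback when the C implementation
# reports an empty cluster, and as the reference path in tests.
.lloyd_reseed <- function(X, centers, iter.max = 300L, tol = 1e-8) {
  n <- nrow(X); k <- nrow(centers)
  rsX <- rowSums(X^2)
  for (it in seq_len(iter.max)) {
    repeat {
      d2 <- outer(rsX, rowSums(centers^2), "+") - 2 * X %*% t(centers)
      lab <- max.col(-d2, ties.method = "first")
      sizes <- tabulate(lab, k)
      if (all(sizes > 0)) break
      own <- d2[cbind(seq_len(n), lab)]
      for (j in which(sizes == 0)) {
        far <- which.max(own)
        centers[j, ] <- X[far, ]
        own[far] <- -Inf
      }
    }
    new_centers <- rowsum(X, lab) / tabulate(lab, k)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- outer(rsX, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  lab <- max.col(-d2, ties.method = "first")
  W <- sum(pmax(d2[cbind(seq_len(n), lab)], 0))
  list(cluster = lab, centers = centers, tot.withinss = W)
}

# One Lloyd run from given centers; prefers the C implementation, falling
# back to .lloyd_reseed when an empty cluster arises.
.lloyd_once <- function(X, centers, iter.max = 300L) {
  empty <- FALSE
  fit <- withCallingHandlers(
    stats::kmeans(X, centers = centers, iter.max = iter.max, algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w))) empty <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (empty || any(fit$size == 0)) {
    fit <- .lloyd_reseed(X, centers, iter.max = iter.max)
  }
  fit
}

#' Fit k-means with seeded random restarts
#'
#' Best (lowest total within-cluster sum of squares) of `n_init` restarts,
#' each initialized at `k` distinct data points sampled from the current RNG
#' stream (seeded by `seed` when given). Lloyd iterations run to convergence
#' (max 300). Every returned cluster is non-empty.
#'
#' @param X numeric matrix (rows = individuals, typically the transformed
#'   covariate matrix).
#' @param k number of clusters (1 <= k <= nrow(X)).
#' @param n_init number of random restarts (default 25).
#' @param seed optional integer seed; omit to use the ambient RNG stream.
#' @return object of class `fmc_kmeans`: list with `k`, `labels` (named by
#'   rownames of `X` when present), `centroids`, `W_k`, `n_init`, `seed`.
#' @export
kmeans_fit <- function(X, k, n_init = 25L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 1, k <= n, !anyNA(X))
  if (!is.null(seed)) set.seed(seed)
  if (k == 1) {
    cen <- matrix(colMeans(X), 1, ncol(X))
    W <- sum(sweep(X, 2, cen[1, ])^2)
    labels <- rep(1L, n)
  } else {
    ux <- unique(X)
    if (nrow(ux) < k) abort(sprintf("only %d distinct rows; cannot place %d centers", nrow(ux), k))
    best <- NULL
    for (i in seq_len(n_init)) {
      repeat {
        cen0 <- X[sample.int(n, k), , drop = FALSE]
        if (!anyDuplicated(cen0)) break
      }
      fit <- .lloyd_once(X, cen0)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    cen <- best$centers
    W <- best$tot.withinss
    labels <- as.integer(best$cluster)
  }
  names(labels) <- rownames(X)
  structure(list(k = as.integer(k), labels = labels,
                 centroids = unname(cen), W_k = W,
                 n_init = as.integer(n_init), seed = seed),
            class = "fmc_kmeans")
}

# log W_k for k = 1..k_max on one matrix, sharing the ambient RNG stream.
.log_wk_curve <- function(X, k_max, n_init) {
  vapply(seq_len(k_max), function(k) log(kmeans_fit(X, k, n_init = n_init)$W_k),
         numeric(1))
}

#' Gap-statistic selection rule (one standard error)
#'
#' The smallest `k` with `gap[k] >= gap[k + 1] - se[k + 1]`; if no `k`
#' satisfies the rule, returns `length(gap)` with a warning.
#'
#' @param gap gap values for k = 1..k_max.
#' @param se reference-set standard errors, same length.
#' @return chosen k (integer).
#' @export
select_gap_k <- function(gap, se) {
  stopifnot(length(gap) == length(se), length(gap) >= 1)
  k_max <- length(gap)
  if (k_max == 1) return(1L)
  ok <- which(gap[-k_max] >= gap[-1] - se[-1])
  if (length(ok) == 0) {
    warn(sprintf("gap-statistic rule never fired; falling back to k_max = %d", k_max))
    return(as.integer(k_max))
  }
  as.integer(min(ok))
}

#' Gap statistic for choosing the number of clusters
#'
#' For each k, compares `log(W_k)` on the data with its expectation over `B`
#' reference datasets drawn uniformly over the observed range of each column
#' of `X`. `gap_k = mean_b log(W*_kb) - log(W_k)` and
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`; k is selected by the
#' one-standard-error rule ([select_gap_k()]).
#'
#' @param X numeric matrix with no missing/non-finite values.
#' @param k_max largest k considered (default 10).
#' @param B number of reference datasets (default 50).
#' @param n_init k-means restarts per fit (default 25).
#' @param seed optional integer seed.
#' @return object of class `fmc_gap`: list with `curve` (tibble: k, log_Wk,
#'   gap, s), `chosen_k`, `B`, `k_max`, `n_init`, `seed`.
#' @export
gap_statistic <- function(X, k_max = 10L, B = 50L, n_init = 25L, seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("X contains non-finite values")
  stopifnot(k_max >= 2, B >= 10, nrow(X) > k_max)
  if (!is.null(seed)) set.seed(seed)
  logW <- .log_wk_curve(X, k_max, n_init)
  rng <- apply(X, 2, range)
  n <- nrow(X); p <- ncol(X)
  logWstar <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    Xb <- vapply(seq_len(p), function(j) runif(n, rng[1, j], rng[2, j]),
                 numeric(n))
    logWstar[b, ] <- .log_wk_curve(Xb, k_max, n_init)
  }
  gap <- colMeans(logWstar) - logW
  s <- apply(logWstar, 2, sd) * sqrt(1 + 1 / B)
  chosen <- select_gap_k(gap, s)
  structure(list(
    curve = tibble::tibble(k = seq_len(k_max), log_Wk = logW, gap = gap, s = s),
    chosen_k = chosen, B = as.integer(B), k_max = as.integer(k_max),
    n_init = as.integer(n_init), seed = seed
  ), class = "fmc_gap")
}

.CLASS_NAMES <- c("Residents", "Occasionals", "Irruptors", "Roamers")

#' Name clusters as functional movement classes
#'
#' For a four-cluster fit, applies a deterministic heuristic on cluster means
#' of the RAW covariates, operationalizing the a-posteriori class
#' descriptions: Roamers have the largest mean 99% distance quantile; of the
#' rest, Occasionals the largest mean inter-detection gap; of the remaining
#' two, Residents the larger mean detection count; the last cluster is
#' Irruptors. For any other k, clusters get numeric names
#' (`class_1`, ...). Exact ties in a deciding mean raise an error demanding
#' manual naming.
#'
#' @param fit an `fmc_kmeans`.
#' @param covariates an `fmc_covariates` object or a tibble with `tag_id` and
#'   the raw covariate columns, covering every labelled tag.
#' @return object of class `fmc_assignment`: tibble with `tag_id`, `cluster`,
#'   `class_name`; the cluster -> name map is in `attr(, "class_map")`.
#' @export
name_clusters <- function(fit, covariates) {
  stopifnot(inherits(fit, "fmc_kmeans"))
  if (inherits(covariates, "fmc_covariates")) {
    raw <- tibble::as_tibble(covariates$raw)
    raw$tag_id <- covariates$tag_id
  } else {
    raw <- covariates
  }
  tags <- names(fit$labels)
  if (is.null(tags)) abort("fit labels carry no tag names; fit on a matrix with rownames")
  idx <- match(tags, raw$tag_id)
  if (anyNA(idx)) abort("raw covariates do not cover every labelled tag")
  raw <- raw[idx, ]
  cl <- fit$labels

  if (fit$k == 4) {
    mean_by <- function(v) tapply(raw[[v]], cl, mean)
    pick <- function(means, pool) {
      m <- means[as.character(pool)]
      if (sum(m == max(m)) > 1) {
        abort("exact tie in the class-naming heuristic; name clusters manually")
      }
      pool[which.max(m)]
    }
    pool <- sort(unique(as.integer(cl)))
    roamer <- pick(mean_by("q99_km"), pool); pool <- setdiff(pool, roamer)
    occ <- pick(mean_by("mean_gap_min"), pool); pool <- setdiff(pool, occ)
    res <- pick(mean_by("n_detections"), pool)
    irr <- setdiff(pool, res)
    class_map <- stats::setNames(
      c("Residents", "Occasionals", "Irruptors", "Roamers"),
      c(res, occ, irr, roamer)
    )
  } else {
    cls <- sort(unique(as.integer(cl)))
    class_map <- stats::setNames(paste0("class_", cls), cls)
  }
  out <- tibble::tibble(
    tag_id = tags,
    cluster = as.integer(cl),
    class_name = unname(class_map[as.character(cl)])
  )
  attr(out, "class_map") <- class_map
  class(out) <- c("fmc_assignment", class(out))
  out
}

#' Sensitivity of the selected k to random tag removal
#'
#' For each removal size, repeats `iterations` times: remove a uniformly
#' sampled tag subset (without replacement), re-run the gap statistic, and
#' record the chosen k. Reports per-iteration values and the per-size mean.
#'
#' @param X transformed covariate matrix.
#' @param removal_sizes tag counts to remove (default `c(1, 10, 100)`; 0 is
#'   allowed and removes nothing).
#' @param iterations repetitions per removal size (default 20).
#' @param k_max,B,n_init passed to [gap_statistic()].
#' @param seed master seed; per-iteration seeds derive from it.
#' @return list with `results` (tibble: removal_size, iteration, chosen_k)
#'   and `summary` (tibble: removal_size, mean_k).
#' @export
sensitivity_analysis <- function(X, removal_sizes = c(1L, 10L, 100L),
                                 iterations = 20L, k_max = 10L, B = 50L,
                                 n_init = 25L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(removal_sizes >= n)) {
    abort(sprintf("removal sizes must be smaller than the number of rows (%d)", n))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- list()
  for (s in removal_sizes) {
    for (it in seq_len(iterations)) {
      drop_idx <- if (s > 0) sample.int(n, s) else integer(0)
      sub_seed <- sample.int(2147483646L, 1L)
      g <- suppressWarnings(
        gap_statistic(X[setdiff(seq_len(n), drop_idx), , drop = FALSE],
                      k_max = k_max, B = B, n_init = n_init, seed = sub_seed)
      )
      res[[length(res) + 1L]] <- tibble::tibble(
        removal_size = as.integer(s), iteration = as.integer(it),
        chosen_k = g$chosen_k
      )
    }
  }
  results <- dplyr::bind_rows(res)
  summary <- results |>
    dplyr::group_by(.data$removal_size) |>
    dplyr::summarise(mean_k = mean(.data$chosen_k), .groups = "drop")
  list(results = results, summary = summary)
}

#' Project the covariate matrix on its first two principal components
#'
#' Eigendecomposition of the covariance of `X` (which should already be
#' centred and scaled); per-dimension percent variance is the eigenvalue
#' share of the trace. Sign convention: each component is flipped so that
#' its largest-magnitude loading is positive.
#'
#' @param X transformed covariate matrix (rows >= columns).
#' @return object of class `fmc_pca`: list with `scores` (tibble: tag_id,
#'   PC1, PC2), `percent_variance` (all dimensions), `rotation`.
#' @export
pca_project <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X)) abort("PCA needs at least as many rows as columns")
  p <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  pct <- p$sdev^2 / sum(p$sdev^2) * 100
  rot <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = tibble::tibble(
      tag_id = rownames(X) %||% as.character(seq_len(nrow(X))),
      PC1 = scores[, 1], PC2 = scores[, 2]
    ),
    percent_variance = pct,
    rotation = rot
  ), class = "fmc_pca")
}
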