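# Class characterization: which covariates drive the dissimilarity between
# functional movement classes. Euclidean-distance SIMPER with the standard
# pre-transforms (dispersion weighting, then log(x + 1)). Because Euclidean
# distance itself does not decompose additively over variables, contributions
# are shares of squared distance: for rows i (class A) and j (class B) the
# contribution of covariate v is (x_iv - x_jv)^2, averaged over all cross
# pairs.

#' Dispersion-weight and log-transform a covariate table
#'
#' Each covariate is divided by its average within-class index of dispersion
#' (variance / mean, averaged over classes with equal weight), then
#' `log(x + 1)` is applied. Degenerate indices are guarded: a class with mean
#' 0, a zero within-class variance, or a single-member class contributes
#' index 1 (leaving such a covariate unchanged before the log).
#'
#' @param X non-negative numeric matrix or data frame (rows = individuals,
#'   columns = covariates).
#' @param labels class label per row.
#' @return weighted, log-transformed matrix; the per-covariate divisors are
#'   in `attr(, "dispersion")`.
#' @export
dispersion_weight <- function(X, labels) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  if (any(X < 0)) abort("dispersion weighting requires non-negative values")
  classes <- unique(labels)
  disp <- vapply(seq_len(ncol(X)), function(j) {
    idx <- vapply(classes, function(cl) {
      x <- X[labels == cl, j]
      m <- mean(x)
      v <- if (length(x) > 1) var(x) else NA_real_
      i <- if (is.na(v) || m == 0) 1 else v / m
      if (i == 0) 1 else i
    }, numeric(1))
    mean(idx)
  }, numeric(1))
  names(disp) <- colnames(X)
  out <- log1p(sweep(X, 2, disp, "/"))
  attr(out, "dispersion") <- disp
  out
}

# mean over cross pairs of (x_iv - x_jv)^2, via the moment identity
# E[(a - b)^2] = E[a^2] + E[b^2] - 2 E[a] E[b] for independent draws from
# the two groups (exact for the all-pairs mean).
.pair_contrib <- function(XA, XB) {
  colMeans(XA^2) + colMeans(XB^2) - 2 * colMeans(XA) * colMeans(XB)
}

# mean Euclidean distance over all cross pairs (explicit, no identity exists)
.pair_mean_dist <- function(XA, XB) {
  d2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
  mean(sqrt(pmax(d2, 0)))
}

#' SIMPER with Euclidean distance
#'
#' For every unordered pair of classes, and additionally for each class
#' against all others pooled ("one-vs-rest", matching how single per-class
#' percentages are usually reported), computes each covariate's mean
#' contribution to squared between-group Euclidean distance and its percent
#' of the total (summing to 100 per comparison).
#'
#' @param X numeric matrix (typically the output of [dispersion_weight()]).
#' @param labels class label per row; at least two classes, each non-empty.
#' @return object of class `fmc_simper`: list with `contributions` (tibble:
#'   comparison, covariate, mean_sq_contribution, percent,
#'   cumulative_percent; covariates ordered by decreasing percent within each
#'   comparison) and `comparisons` (tibble: comparison, mean_distance,
#'   total_mean_sq).
#' @export
simper_euclidean <- function(X, labels) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("SIMPER needs at least two classes")
  covs <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- covs

  one <- function(name, A, B) {
    XA <- X[A, , drop = FALSE]; XB <- X[B, , drop = FALSE]
    contrib <- .pair_contrib(XA, XB)
    total <- sum(contrib)
    pct <- if (total > 0) contrib / total * 100 else rep(0, length(contrib))
    ord <- order(pct, decreasing = TRUE)
    list(
      contributions = tibble::tibble(
        comparison = name, covariate = covs[ord],
        mean_sq_contribution = unname(contrib[ord]),
        percent = unname(pct[ord]),
        cumulative_percent = cumsum(unname(pct[ord]))
      ),
      comparisons = tibble::tibble(
        comparison = name,
        mean_distance = .pair_mean_dist(XA, XB),
        total_mean_sq = total
      )
    )
  }
  parts <- list()
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (i < j) {
        nm <- sprintf("%s_vs_%s", classes[i], classes[j])
        parts[[nm]] <- one(nm, labels == classes[i], labels == classes[j])
      }
    }
  }
  for (cl in classes) {
    nm <- sprintf("%s_vs_rest", cl)
    parts[[nm]] <- one(nm, labels == cl, labels != cl)
  }
  structure(list(
    contributions = dplyr::bind_rows(lapply(parts, `[[`, "contributions")),
    comparisons = dplyr::bind_rows(lapply(parts, `[[`, "comparisons"))
  ), class = "fmc_simper")
}
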