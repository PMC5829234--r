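# End-to-end orchestration: covariates -> gap-selected k-means -> class
# naming -> SIMPER -> installation networks -> subset effectiveness
# comparison, with CSV artifacts and a JSON run manifest.

#' Pipeline configuration
#'
#' @param detections path to the detections CSV.
#' @param installations path to the installations CSV.
#' @param out_dir output directory (created if absent).
#' @param min_detections minimum detections per retained individual.
#' @param qc_keep QC flags to keep on ingest.
#' @param k_max,B,n_init gap-statistic / k-means parameters.
#' @param seed master analysis seed (mandatory); stage seeds derive from it.
#' @param removal_sizes,iterations sensitivity-analysis parameters.
#' @param include_sensitivity run the (expensive) tag-removal sensitivity
#'   analysis as part of the full run (default `FALSE`; it is available
#'   directly via [sensitivity_analysis()]).
#' @param normalization relative-movement normalization mode.
#' @return list of class `fmc_config`.
#' @export
pipeline_config <- function(detections, installations, out_dir,
                            min_detections = 2L, qc_keep = c(1L, 2L),
                            k_max = 10L, B = 50L, n_init = 25L, seed = 42L,
                            removal_sizes = c(1L, 10L, 100L), iterations = 20L,
                            include_sensitivity = FALSE,
                            normalization = "pooled") {
  if (is.null(seed)) abort("a seed is mandatory for any run that touches randomness")
  structure(list(
    detections = detections, installations = installations, out_dir = out_dir,
    min_detections = as.integer(min_detections), qc_keep = as.integer(qc_keep),
    k_max = as.integer(k_max), B = as.integer(B), n_init = as.integer(n_init),
    seed = as.integer(seed), removal_sizes = as.integer(removal_sizes),
    iterations = as.integer(iterations),
    include_sensitivity = isTRUE(include_sensitivity),
    normalization = normalization
  ), class = "fmc_config")
}

#' Simulate a dataset and write it to disk
#'
#' Wraps [generate_dataset()] and writes `detections.csv`,
#' `installations.csv`, and the archetype truth table `truth.csv` in the
#' exchange dialects of the I/O module.
#'
#' @param config an `fmc_sim_config`.
#' @param out_dir output directory.
#' @return invisibly, a list with the dataset and the three file paths.
#' @export
run_simulation <- function(config = simulation_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(config)
  paths <- list(
    detections = file.path(out_dir, "detections.csv"),
    installations = file.path(out_dir, "installations.csv"),
    truth = file.path(out_dir, "truth.csv")
  )
  write_detections(ds$detections, paths$detections)
  write_installations(ds$array, paths$installations)
  readr::write_csv(ds$truth, paths$truth, progress = FALSE)
  invisible(list(dataset = ds, paths = paths))
}

.write_netsummary <- function(summary, communities, label) {
  net <- dplyr::bind_cols(tibble::tibble(network = label), summary$network)
  nodes <- dplyr::bind_cols(tibble::tibble(network = label), summary$nodes)
  comm <- dplyr::bind_cols(tibble::tibble(network = label), communities$membership)
  list(network = net, nodes = nodes, communities = comm)
}

#' Run the full movement-class analysis
#'
#' Executes, in order: covariate extraction on the full detection stream;
#' gap-statistic selection of k; k-means at the chosen k plus class naming
#' and PCA coordinates; Euclidean SIMPER on dispersion-weighted,
#' log-transformed raw covariates; Full / IMOS-only / non-IMOS-only
#' relative-movement networks with metrics and communities; and the
#' network-effectiveness comparison: (1) gap statistic on covariates
#' recomputed from each installation subset's detections, (2) forced-k
#' clustering of those subsets at the Full chosen k with a cluster-overlap
#' summary (best-bijective-match accuracy and mean silhouettes), and (3) one
#' network per movement class. Every stage writes CSV artifacts under
#' `config$out_dir` and is recorded in `manifest.json`.
#'
#' @param config an `fmc_config` from [pipeline_config()].
#' @return invisibly, a list with all stage objects and the manifest.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "fmc_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t_start <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s (partial artifacts retained in %s)",
                    name, conditionMessage(e), out))
    })
  }
  seeds <- list(
    gap = substream_seed(config$seed, 101L),
    kmeans = substream_seed(config$seed, 102L),
    gap_imos = substream_seed(config$seed, 103L),
    gap_non_imos = substream_seed(config$seed, 104L),
    forced_imos = substream_seed(config$seed, 105L),
    forced_non_imos = substream_seed(config$seed, 106L),
    sensitivity = substream_seed(config$seed, 107L)
  )

  # 1: covariates -------------------------------------------------------
  detections <- array <- cov <- covmat <- NULL
  stage("covariates", {
    detections <- read_detections(config$detections, qc_keep = config$qc_keep)
    array <- read_installations(config$installations)
    cov <- covariate_table(detections, min_detections = config$min_detections)
    covmat <- build_covariate_matrix(cov$covariates)
    cov_out <- dplyr::bind_cols(
      cov$covariates,
      tibble::as_tibble(covmat$transformed) |>
        stats::setNames(paste0(COVARIATE_NAMES, "_transformed"))
    )
    readr::write_csv(cov_out, file.path(out, "covariates.csv"), progress = FALSE)
    readr::write_csv(cov$excluded, file.path(out, "excluded_tags.csv"), progress = FALSE)
    stages$covariates <- c("covariates.csv", "excluded_tags.csv")
  })

  # 2: gap statistic ----------------------------------------------------
  gap <- NULL
  stage("gap_statistic", {
    gap <- gap_statistic(covmat$transformed, k_max = config$k_max, B = config$B,
                          n_init = config$n_init, seed = seeds$gap)
    readr::write_csv(gap$curve, file.path(out, "gap_curve.csv"), progress = FALSE)
    stages$gap_statistic <- "gap_curve.csv"
  })

  # 3: clustering + naming + PCA ---------------------------------------
  fit <- assignment <- pca <- NULL
  stage("classification", {
    fit <- kmeans_fit(covmat$transformed, k = gap$chosen_k,
                       n_init = config$n_init, seed = seeds$kmeans)
    assignment <- name_clusters(fit, covmat)
    pca <- pca_project(covmat$transformed)
    readr::write_csv(assignment, file.path(out, "assignment.csv"), progress = FALSE)
    pca_out <- dplyr::bind_cols(
      pca$scores,
      tibble::tibble(pc1_pct_variance = pca$percent_variance[1],
                     pc2_pct_variance = pca$percent_variance[2])
    )
    readr::write_csv(pca_out, file.path(out, "pca_coordinates.csv"), progress = FALSE)
    stages$classification <- c("assignment.csv", "pca_coordinates.csv")
  })

  # 4: SIMPER -----------------------------------------------------------
  simper <- NULL
  stage("simper", {
    weighted <- dispersion_weight(covmat$raw, assignment$class_name)
    simper <- simper_euclidean(weighted, assignment$class_name)
    readr::write_csv(simper$contributions, file.path(out, "simper.csv"), progress = FALSE)
    stages$simper <- "simper.csv"
  })

  # 5: networks ---------------------------------------------------------
  networks <- NULL
  stage("networks", {
    networks <- lapply(stats::setNames(nm = c("full", "imos", "non_imos")), function(ss) {
      rmm <- relative_movement_matrix(detections, array, subset = ss,
                                      normalization = config$normalization)
      if (nrow(rmm$matrix) == 0) return(list(rmm = rmm, summary = NULL, communities = NULL))
      list(rmm = rmm, summary = network_metrics(rmm), communities = detect_communities(rmm))
    })
    rows <- purrr::compact(lapply(names(networks), function(nm) {
      if (is.null(networks[[nm]]$summary)) return(NULL)
      .write_netsummary(networks[[nm]]$summary, networks[[nm]]$communities, nm)
    }))
    readr::write_csv(dplyr::bind_rows(lapply(rows, `[[`, "network")),
                     file.path(out, "network_metrics.csv"), progress = FALSE)
    readr::write_csv(dplyr::bind_rows(lapply(rows, `[[`, "nodes")),
                     file.path(out, "node_metrics.csv"), progress = FALSE)
    readr::write_csv(dplyr::bind_rows(lapply(rows, `[[`, "communities")),
                     file.path(out, "communities.csv"), progress = FALSE)
    edges <- dplyr::bind_rows(lapply(names(networks), function(nm) {
      M <- networks[[nm]]$rmm$matrix
      if (nrow(M) == 0) return(NULL)
      el <- which(M > 0, arr.ind = TRUE)
      tibble::tibble(network = nm, from = rownames(M)[el[, 1]],
                     to = colnames(M)[el[, 2]], weight = M[el])
    }))
    readr::write_csv(edges, file.path(out, "edges.csv"), progress = FALSE)
    stages$networks <- c("network_metrics.csv", "node_metrics.csv",
                          "communities.csv", "edges.csv")
  })

  # subset detection streams reused by stages 6 and 7
  subset_data <- function(ss) {
    rmm_type <- c(imos = "IMOS", non_imos = "non-IMOS")[[ss]]
    keep <- array$installations$installation_id[
      array$installations$installation_type == rmm_type]
    d <- detections[detections$installation_id %in% keep, ]
    cv <- covariate_table(d, min_detections = config$min_detections)
    list(detections = d, cov = cv)
  }
  subsets <- lapply(stats::setNames(nm = c("imos", "non_imos")), subset_data)

  # 6: effectiveness, approach 1: subset gap statistics ------------------
  eff_gap <- NULL
  stage("effectiveness_gap", {
    eff_gap <- lapply(stats::setNames(nm = names(subsets)), function(ss) {
      cv <- subsets[[ss]]$cov$covariates
      if (nrow(cv) < config$k_max + 1) {
        warn(sprintf("subset '%s' has too few tags (%d) for the gap statistic", ss, nrow(cv)))
        return(NULL)
      }
      cm <- build_covariate_matrix(cv)
      suppressWarnings(gap_statistic(cm$transformed, k_max = config$k_max,
                                     B = config$B, n_init = config$n_init,
                                     seed = seeds[[paste0("gap_", ss)]]))
    })
    curves <- dplyr::bind_rows(lapply(names(eff_gap), function(ss) {
      if (is.null(eff_gap[[ss]])) return(NULL)
      dplyr::bind_cols(tibble::tibble(subset = ss), eff_gap[[ss]]$curve,
                       tibble::tibble(chosen_k = eff_gap[[ss]]$chosen_k))
    }))
    readr::write_csv(curves, file.path(out, "effectiveness_gap.csv"), progress = FALSE)
    stages$effectiveness_gap <- "effectiveness_gap.csv"
  })

  # 7: effectiveness, approach 2: forced-k subset clustering -------------
  eff_forced <- NULL
  stage("effectiveness_forced_k", {
    sil <- function(labels, X) {
      if (length(unique(labels)) < 2) return(NA_real_)
      mean(cluster::silhouette(as.integer(labels), stats::dist(X))[, "sil_width"])
    }
    full_sil <- sil(fit$labels, covmat$transformed)
    eff_forced <- dplyr::bind_rows(lapply(names(subsets), function(ss) {
      cv <- subsets[[ss]]$cov$covariates
      if (nrow(cv) < gap$chosen_k + 1) {
        return(tibble::tibble(subset = ss, n_tags = nrow(cv), forced_k = gap$chosen_k,
                              best_match_accuracy = NA_real_,
                              mean_silhouette = NA_real_,
                              full_mean_silhouette = full_sil))
      }
      cm <- build_covariate_matrix(cv)
      sub_fit <- kmeans_fit(cm$transformed, k = gap$chosen_k,
                            n_init = config$n_init,
                            seed = seeds[[paste0("forced_", ss)]])
      shared <- intersect(names(sub_fit$labels), names(fit$labels))
      acc <- match_clusters(sub_fit$labels[shared], fit$labels[shared])$accuracy
      tibble::tibble(subset = ss, n_tags = nrow(cv), forced_k = gap$chosen_k,
                     best_match_accuracy = acc,
                     mean_silhouette = sil(sub_fit$labels, cm$transformed),
                     full_mean_silhouette = full_sil)
    }))
    readr::write_csv(eff_forced, file.path(out, "effectiveness_forced_k.csv"), progress = FALSE)
    stages$effectiveness_forced_k <- "effectiveness_forced_k.csv"
  })

  # 8: effectiveness, approach 3: per-class networks ---------------------
  fmc_nets <- NULL
  stage("fmc_networks", {
    fmc_nets <- suppressWarnings(
      per_fmc_networks(detections, array, assignment,
                       normalization = config$normalization)
    )
    rows <- dplyr::bind_rows(lapply(names(fmc_nets), function(cl) {
      s <- fmc_nets[[cl]]$summary
      if (is.null(s)) {
        return(tibble::tibble(class_name = cl, n_nodes = 0L, n_edges = 0L))
      }
      dplyr::bind_cols(tibble::tibble(class_name = cl), s$network)
    }))
    readr::write_csv(rows, file.path(out, "fmc_network_metrics.csv"), progress = FALSE)
    stages$fmc_networks <- "fmc_network_metrics.csv"
  })

  sensitivity <- NULL
  if (config$include_sensitivity) {
    stage("sensitivity", {
      sensitivity <- sensitivity_analysis(
        covmat$transformed, removal_sizes = config$removal_sizes,
        iterations = config$iterations, k_max = config$k_max, B = config$B,
        n_init = config$n_init, seed = seeds$sensitivity)
      readr::write_csv(sensitivity$results, file.path(out, "sensitivity.csv"),
                       progress = FALSE)
      stages$sensitivity <- "sensitivity.csv"
    })
  }

  manifest <- list(
    package = "moveclass",
    version = as.character(utils::packageVersion("moveclass")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    inputs = list(
      detections = unname(tools::md5sum(config$detections)),
      installations = unname(tools::md5sum(config$installations))
    ),
    config = unclass(config),
    seeds = seeds,
    chosen_k = gap$chosen_k,
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    detections = detections, array = array, covariates = cov, covmat = covmat,
    gap = gap, fit = fit, assignment = assignment, pca = pca, simper = simper,
    networks = networks, effectiveness_gap = eff_gap,
    effectiveness_forced_k = eff_forced, fmc_networks = fmc_nets,
    sensitivity = sensitivity, manifest = manifest
  ))
}
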