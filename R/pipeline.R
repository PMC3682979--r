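#' Run the full two-species comparison pipeline on simulated data
#'
#' Generates a two-species data set and carries it through every stage:
#' pre-clustering filters, Z-normalization, fuzzy c-means clustering and
#' hard assignment per species, TF-family enrichment per cluster,
#' cross-species cluster pairing (with pooled pair enrichment and the
#' family-distribution homogeneity test), ortholog cluster concordance and
#' expression correlation with their permutation nulls, and the
#' all-pairs time-point distance (hourglass) analysis.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param c,m,threshold,restarts Clustering parameters (defaults c =
#'   `config$n_clusters`, m = 1.25, membership threshold 0.8, 5 restarts).
#' @param n_sets Random-pair sets for the permutation nulls (default 1000).
#' @param alpha_corr Per-pair correlation significance level (default 0.05).
#' @param alpha_family One-sided family-enrichment level (default 0.0025).
#' @return A list of class `devotf_pipeline` with elements `sim`, `a`, `b`
#'   (per species: `filtered`, `z`, `fit`, `assignment`, `enrichment`),
#'   `pairing`, `pair_enrichment`, `family_homogeneity`, `concordance`,
#'   `concordance_null`, `correlations`, `correlation_null`, `hourglass`
#'   (`distance`, `profile_a`, `profile_b`, `minima_a`, `minima_b`).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1,
                         c = config$n_clusters, m = 1.25, threshold = 0.8,
                         restarts = 5, n_sets = 1000, alpha_corr = 0.05,
                         alpha_family = 0.0025) {
  sim <- simulate_species_pair(config, seed)
  stage <- function(x, cat, fit_seed) {
    filtered <- filter_for_clustering(x$expr, x$presence)
    z <- z_normalize(filtered)
    fit <- fuzzy_cmeans(z, c = c, m = m, seed = fit_seed, restarts = restarts)
    assignment <- assign_members(fit, threshold = threshold)
    list(filtered = filtered, z = z, fit = fit, assignment = assignment,
         enrichment = cluster_family_enrichment(assignment, cat,
                                                alpha = alpha_family))
  }
  a <- stage(sim$a, sim$a$catalog, seed + 1L)
  b <- stage(sim$b, sim$b$catalog, seed + 2L)
  centers <- restrict_to_alignment(a$fit$centers, b$fit$centers, sim$alignment)
  pairing <- pair_clusters(centers$a, centers$b)
  pair_enr <- if (nrow(pairing$pairs) > 0) {
    pair_family_enrichment(pairing, a$assignment, b$assignment,
                           sim$a$catalog, sim$b$catalog, alpha = alpha_family)
  }
  fam_hom <- if (nrow(pairing$pairs) >= 2) {
    family_distribution_test(a$assignment, b$assignment, pairing,
                             sim$a$catalog, sim$b$catalog, seed = seed + 5L)
  }
  conc <- ortholog_cluster_concordance(sim$orthologs, a$assignment,
                                       b$assignment, pairing)
  conc_null <- concordance_null(sim$orthologs, a$assignment, b$assignment,
                                pairing, n_sets = n_sets, seed = seed + 3L)
  zal <- restrict_to_alignment(a$z, b$z, sim$alignment)
  corr <- ortholog_correlations(sim$orthologs, zal$a, zal$b, alpha = alpha_corr)
  corr_null <- correlation_null(sim$orthologs, zal$a, zal$b,
                                alpha = alpha_corr, n_sets = n_sets,
                                seed = seed + 4L)
  D <- stage_distance_matrix(a$filtered, b$filtered, sim$orthologs)
  hour <- list(distance = D,
               profile_a = min_distance_profile(D, "a"),
               profile_b = min_distance_profile(D, "b"))
  hour$minima_a <- local_minima(hour$profile_a)
  hour$minima_b <- local_minima(hour$profile_b)
  structure(list(sim = sim, a = a, b = b, pairing = pairing,
                 pair_enrichment = pair_enr, family_homogeneity = fam_hom,
                 concordance = conc, concordance_null = conc_null,
                 correlations = corr, correlation_null = corr_null,
                 hourglass = hour, seed = seed),
            class = "devotf_pipeline")
}

#' Numeric summary of a pipeline run
#'
#' Collects the pipeline's headline numbers into a plain list suitable for
#' JSON serialisation (and for byte-identical reproducibility checks).
#'
#' @param res A [run_pipeline()] result.
#' @return A named list of scalars and small vectors.
#' @export
pipeline_summary <- function(res) {
  stopifnot(inherits(res, "devotf_pipeline"))
  drop_a <- attr(res$a$filtered, "dropped")
  drop_b <- attr(res$b$filtered, "dropped")
  list(
    seed = res$seed,
    n_genes = res$sim$truth$config$n_genes,
    filtered_never = c(a = length(drop_a$never_expressed),
                       b = length(drop_b$never_expressed)),
    filtered_constant = c(a = length(drop_a$constant),
                          b = length(drop_b$constant)),
    n_assigned = c(a = sum(!is.na(res$a$assignment$cluster)),
                   b = sum(!is.na(res$b$assignment$cluster))),
    n_cluster_pairs = nrow(res$pairing$pairs),
    pair_distances = round(res$pairing$pairs$distance, 6),
    n_enriched_over = c(a = sum(res$a$enrichment$over),
                        b = sum(res$b$enrichment$over)),
    concordance = c(n_concordant = res$concordance$n_concordant,
                    n_eligible = res$concordance$n_eligible),
    concordance_z = round(res$concordance_null$z_score, 4),
    concordance_empirical_p = res$concordance_null$empirical_p,
    correlations = c(n_significant = res$correlations$n_significant,
                     n_tested = res$correlations$n_tested),
    correlation_z = round(res$correlation_null$z_score, 4),
    correlation_empirical_p = res$correlation_null$empirical_p,
    hourglass_argmin = list(time_a = res$hourglass$distance$argmin$time_a,
                            time_b = res$hourglass$distance$argmin$time_b,
                            distance = round(res$hourglass$distance$argmin$distance, 6)),
    interior_minima_a = res$hourglass$minima_a$index[!res$hourglass$minima_a$boundary],
    interior_minima_b = res$hourglass$minima_b$index[!res$hourglass$minima_b$boundary]
  )
}

#' @param res A [run_pipeline()] result.
#' @param path Output JSON path.
#' @rdname pipeline_summary
#' @export
write_pipeline_summary <- function(res, path) {
  jsonlite::write_json(pipeline_summary(res), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.devotf_pipeline <- function(x, ...) {
  s <- pipeline_summary(x)
  cat(sprintf("<devotf_pipeline> seed %d\n", s$seed))
  cat(sprintf("  assigned: A %d, B %d; cluster pairs: %d\n",
              s$n_assigned["a"], s$n_assigned["b"], s$n_cluster_pairs))
  cat(sprintf("  concordant orthologs: %d / %d (Z = %.2f, empirical p = %.4g)\n",
              s$concordance["n_concordant"], s$concordance["n_eligible"],
              s$concordance_z, s$concordance_empirical_p))
  cat(sprintf("  correlated orthologs: %d / %d (Z = %.2f, empirical p = %.4g)\n",
              s$correlations["n_significant"], s$correlations["n_tested"],
              s$correlation_z, s$correlation_empirical_p))
  cat(sprintf("  most similar stages: A %s ~ B %s\n",
              s$hourglass_argmin$time_a, s$hourglass_argmin$time_b))
  invisible(x)
}
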