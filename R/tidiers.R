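#' Tidy a fuzzy clustering into a long membership table
#'
#' @param x A [fuzzy_cmeans()] fit.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `cluster`, `membership`.
#' @export
tidy.fuzzy_clustering <- function(x, ...) {
  as_tibble(x$membership, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "cluster", values_to = "membership")
}

#' @rdname tidy.fuzzy_clustering
#' @return `glance()` returns a one-row tibble with `n`, `c`, `m`,
#'   `iterations`, `objective` (final value) and `seed`.
#' @export
glance.fuzzy_clustering <- function(x, ...) {
  tibble(n = nrow(x$membership), c = x$c, m = x$m,
         iterations = x$iterations,
         objective = x$objective[length(x$objective)], seed = x$seed)
}

#' Tidy a permutation-null result
#'
#' @param x A `perm_null` object (from [concordance_null()] or
#'   [correlation_null()]).
#' @param ... Unused.
#' @return A tibble of the null draws (`set`, `value`).
#' @export
tidy.perm_null <- function(x, ...) {
  tibble(set = seq_along(x$null_values), value = x$null_values)
}

#' @rdname tidy.perm_null
#' @return `glance()` returns a one-row tibble with `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `z_score`, `empirical_p`, `n_sets`, `seed`.
#' @export
glance.perm_null <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         null_mean = mean(x$null_values), null_sd = sd(x$null_values),
         z_score = x$z_score, empirical_p = x$empirical_p,
         n_sets = x$n_sets, seed = x$seed)
}

#' Tidy a cross-species cluster pairing
#'
#' @param x A [pair_clusters()] result.
#' @param ... Unused.
#' @return The pair table (`cluster_a`, `cluster_b`, `distance`).
#' @export
tidy.cluster_pairing <- function(x, ...) x$pairs

#' @rdname tidy.cluster_pairing
#' @export
glance.cluster_pairing <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), n_unpaired_a = length(x$unpaired_a),
         n_unpaired_b = length(x$unpaired_b), n_ties = nrow(x$ties),
         rule = x$rule)
}

#' Tidy a stage-distance matrix into long form
#'
#' @param x A [stage_distance_matrix()] result.
#' @param ... Unused.
#' @return A tibble with columns `time_a`, `time_b`, `distance`.
#' @export
tidy.stage_distance <- function(x, ...) {
  as_tibble(x$matrix, rownames = "time_a") %>%
    tidyr::pivot_longer(-"time_a", names_to = "time_b", values_to = "distance")
}

#' @rdname tidy.stage_distance
#' @export
glance.stage_distance <- function(x, ...) {
  dplyr::bind_cols(x$argmin, tibble(n_orthologs = x$n_orthologs))
}
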