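#' Fuzzy c-means clustering of temporal profiles
#'
#' Soft-clusters Z-normalized expression profiles by the classical fuzzy
#' c-means alternating minimization of
#' \deqn{J = \sum_i \sum_k u_{ik}^m \, d(x_k, v_i)^2}
#' with Euclidean distance `d`, membership update
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centers as the
#' `u^m`-weighted mean of the data. A point coinciding with a center
#' receives membership 1 there and 0 elsewhere. Iteration stops when the
#' largest membership change falls below `tol` or after `max_iter`
#' iterations. Memberships are initialized uniformly at random
#' (row-normalized), and the best of `restarts` seeded restarts by final
#' objective is returned, so results are deterministic given `seed`.
#'
#' @param x Numeric matrix of profiles (genes x time points), or an
#'   [expr_timecourse]; rows are expected to be Z-normalized.
#' @param c Number of clusters (default 7).
#' @param m Fuzzifier exponent, > 1 (default 1.25); `m` close to 1
#'   approaches hard k-means.
#' @param tol Convergence tolerance on the maximum membership change.
#' @param max_iter Maximum iterations per restart.
#' @param seed Integer seed controlling initialization.
#' @param restarts Number of random restarts (default 5).
#' @return An object of class `fuzzy_clustering` with elements `centers`
#'   (c x T), `membership` (n x c), `m`, `objective` (per-iteration trace of
#'   the kept restart), `iterations`, `seed`.
#' @export
fuzzy_cmeans <- function(x, c = 7, m = 1.25, tol = 1e-6, max_iter = 1000,
                         seed = 1, restarts = 5) {
  if (inherits(x, "expr_timecourse")) x <- x$values
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("non-finite values in clustering input")
  if (nrow(x) <= c) abort("need more profiles than clusters")
  if (m <= 1) abort("fuzzifier `m` must be > 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- fcm_once(x, c, m, tol, max_iter)
    if (is.null(best) || fit$objective[length(fit$objective)] <
          best$objective[length(best$objective)]) {
      best <- fit
    }
  }
  structure(list(centers = best$centers, membership = best$membership,
                 m = m, c = c, objective = best$objective,
                 iterations = length(best$objective), seed = seed,
                 data = x),
            class = "fuzzy_clustering")
}

fcm_once <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  expo <- 1 / (m - 1)
  x2 <- rowSums(x^2)
  # k-means++-style seeding: spread the initial centers over the data, so a
  # crisp fuzzifier does not trap all centers near the grand centroid
  idx <- sample.int(n, 1)
  for (j in seq_len(c - 1)) {
    d2min <- do.call(pmin, lapply(idx, function(i)
      x2 + x2[i] - 2 * drop(x %*% x[i, ])))
    d2min[d2min < 0] <- 0
    idx <- c(idx, sample.int(n, 1, prob = d2min + 1e-12))
  }
  centers <- x[idx, , drop = FALSE]
  u <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (!is.null(u)) {
      um <- u^m
      centers <- crossprod(um, x) / colSums(um)
    }
    d2 <- outer(x2, rowSums(centers^2), `+`) - 2 * x %*% t(centers)
    d2[d2 < 0] <- 0
    sing <- d2 < 1e-12
    w <- d2^(-expo)
    u_new <- w / rowSums(w)
    hit <- rowSums(sing) > 0
    if (any(hit)) {
      # a profile coinciding with a center belongs to it outright
      u_new[hit, ] <- sing[hit, , drop = FALSE] / rowSums(sing[hit, , drop = FALSE])
    }
    trace <- c(trace, sum(u_new^m * d2))
    delta <- if (is.null(u)) Inf else max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  dimnames(u) <- list(rownames(x), paste0("C", seq_len(c)))
  dimnames(centers) <- list(paste0("C", seq_len(c)), colnames(x))
  list(centers = centers, membership = u, objective = trace)
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("<fuzzy_clustering> %d profiles, c = %d, m = %.3g, %d iteration(s), J = %.4g\n",
              nrow(x$membership), x$c, x$m, x$iterations,
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Hard cluster assignments from a soft clustering
#'
#' A gene is a member of its argmax-membership cluster when that membership
#' strictly exceeds `threshold`; otherwise it stays unassigned.
#'
#' @param f A [fuzzy_cmeans()] fit.
#' @param threshold Membership cutoff in (1/c, 1] (default 0.8); the
#'   inequality is strict, so a membership of exactly `threshold` leaves the
#'   gene unassigned.
#' @return A tibble of class `cluster_assignment` with columns `gene`,
#'   `cluster` (e.g. "C3"; `NA` when unassigned) and `membership` (the
#'   maximum membership). The threshold is recorded as an attribute.
#' @export
assign_members <- function(f, threshold = 0.8) {
  stopifnot(inherits(f, "fuzzy_clustering"))
  if (threshold <= 1 / f$c || threshold > 1) {
    abort(sprintf("`threshold` must be in (1/c, 1] = (%.3g, 1]", 1 / f$c))
  }
  top <- max.col(f$membership, ties.method = "first")
  mx <- f$membership[cbind(seq_len(nrow(f$membership)), top)]
  out <- tibble(gene = rownames(f$membership),
                cluster = ifelse(mx > threshold, colnames(f$membership)[top], NA_character_),
                membership = mx)
  structure(out, threshold = threshold,
            class = c("cluster_assignment", class(out)))
}

#' TF-family representation tests per cluster
#'
#' For every (cluster, family) combination, tests by a two-one-sided
#' hypergeometric test whether the family is over- or under-represented in
#' the cluster relative to the background of all *assigned* genes: the draw
#' is the cluster (size `n`), the marks are the family's assigned members
#' (`K`) and the universe all assigned genes (`N`).
#'
#' @param a A [cluster_assignment].
#' @param cat A [tf_catalog].
#' @param alpha Significance level applied to each one-sided tail
#'   (default 0.0025, a fixed low level accounting for the multiplicity of
#'   cluster-by-family tests).
#' @param min_family Skip families with fewer assigned members (default 1).
#' @return A tibble with columns `cluster`, `family`, `k`, `n`, `K`, `N`,
#'   `p_over`, `p_under`, `over`, `under`.
#' @export
cluster_family_enrichment <- function(a, cat, alpha = 0.0025, min_family = 1) {
  stopifnot(inherits(a, "cluster_assignment"), inherits(cat, "tf_catalog"))
  assigned <- a[!is.na(a$cluster), ]
  if (nrow(assigned) == 0) abort("no assigned genes")
  N <- nrow(assigned)
  fam_assigned <- cat[cat$gene %in% assigned$gene, ]
  fams <- fam_assigned %>% count(.data$family) %>% filter(n >= min_family)
  clusters <- sort(unique(assigned$cluster))
  grid <- tidyr::expand_grid(cluster = clusters, family = fams$family)
  rows <- purrr::pmap_dfr(grid, function(cluster, family) {
    in_cluster <- assigned$gene[assigned$cluster == cluster]
    fam_genes <- fam_assigned$gene[fam_assigned$family == family]
    tibble(cluster = cluster, family = family,
           k = length(intersect(in_cluster, fam_genes)),
           n = length(in_cluster),
           K = length(unique(fam_genes)))
  })
  p <- hypergeometric_overlap(rows$k, rows$n, rows$K, N)
  rows$N <- N
  rows$p_over <- p$p_over
  rows$p_under <- p$p_under
  rows$over <- rows$p_over < alpha
  rows$under <- rows$p_under < alpha
  rows
}
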