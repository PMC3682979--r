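#' Exact hypergeometric tail probabilities for a set overlap
#'
#' For a drawn set of size `n` from a universe of size `N` containing `K`
#' marked items, and an observed overlap of `k`, returns both one-sided
#' tails of the hypergeometric distribution:
#' `p_over = P(X >= k)` and `p_under = P(X <= k)`. The two tails share the
#' point mass at `k`, so `p_over + p_under >= 1`.
#'
#' @param k Observed overlap count(s).
#' @param n Drawn set size(s).
#' @param K Marked items in the universe.
#' @param N Universe size.
#' @return A tibble with columns `k`, `n`, `K`, `N`, `p_over`, `p_under`
#'   (vectorized over the inputs).
#' @examples
#' hypergeometric_overlap(k = 4, n = 4, K = 5, N = 10) # p_over = 5/210
#' @export
hypergeometric_overlap <- function(k, n, K, N) {
  d <- tibble(k = as.integer(k), n = as.integer(n),
              K = as.integer(K), N = as.integer(N))
  bad <- with(d, k < pmax(0L, n + K - N) | k > pmin(n, K) | n > N | K > N |
                k < 0 | n < 0 | K < 0 | N < 0)
  if (any(bad)) {
    abort(sprintf("infeasible hypergeometric counts (k=%d, n=%d, K=%d, N=%d)",
                  d$k[bad][1], d$n[bad][1], d$K[bad][1], d$N[bad][1]))
  }
  d$p_over <- phyper(d$k - 1L, d$K, d$N - d$K, d$n, lower.tail = FALSE)
  d$p_under <- phyper(d$k, d$K, d$N - d$K, d$n)
  d
}

#' Fraction of a gene set called present at each time point
#'
#' @param p A [presence_table].
#' @param genes Gene ids to profile; genes missing from the presence table
#'   are dropped with a message.
#' @return A tibble with columns `time`, `n_present`, `n_total`, `fraction`.
#' @export
percent_expressed <- function(p, genes) {
  stopifnot(inherits(p, "presence_table"))
  genes <- unique(genes)
  have <- genes %in% rownames(p$matrix)
  if (sum(!have) > 0) {
    inform(sprintf("%d gene(s) have no presence data and were dropped", sum(!have)))
  }
  genes <- genes[have]
  if (length(genes) == 0) abort("no gene in the set has presence data")
  m <- p$matrix[genes, , drop = FALSE]
  tibble(time = colnames(m),
         n_present = unname(colSums(m)),
         n_total = length(genes),
         fraction = unname(colSums(m)) / length(genes))
}

#' TF-family utilization profile
#'
#' For each TF family with at least `min_family` members having presence
#' data, computes the fraction of family members expressed at each time
#' point and its relative representation versus the overall TF fraction:
#' `(family fraction - overall fraction) / overall fraction`. Genes carrying
#' several family labels count once in each of their families.
#'
#' @param p A [presence_table].
#' @param cat A [tf_catalog] for the same species.
#' @param min_family Minimum family size (genes with data) for reporting.
#' @return A tibble of class `utilization_profile` with columns `family`,
#'   `time`, `n_genes`, `fraction`, `overall_fraction`, `relative`.
#' @export
family_representation <- function(p, cat, min_family = 5) {
  stopifnot(inherits(p, "presence_table"), inherits(cat, "tf_catalog"))
  cat_here <- cat[cat$gene %in% rownames(p$matrix), ]
  dropped <- length(setdiff(unique(cat$gene), rownames(p$matrix)))
  if (dropped > 0) {
    inform(sprintf("%d catalog gene(s) lack expression data and were dropped", dropped))
  }
  overall <- percent_expressed(p, unique(cat_here$gene))
  fams <- cat_here %>%
    count(.data$family) %>%
    filter(n >= min_family) %>%
    pull(.data$family)
  if (length(fams) == 0) {
    abort(sprintf("no family has >= %d members with data", min_family))
  }
  per_fam <- purrr::map_dfr(fams, function(f) {
    pe <- percent_expressed(p, cat_here$gene[cat_here$family == f])
    tibble(family = f, time = pe$time, n_genes = pe$n_total, fraction = pe$fraction)
  })
  out <- per_fam %>%
    left_join(overall %>% select("time", overall_fraction = "fraction"), by = "time") %>%
    mutate(relative = ifelse(.data$overall_fraction > 0,
                             (.data$fraction - .data$overall_fraction) / .data$overall_fraction,
                             NA_real_))
  structure(out, species = p$species, overall = overall,
            class = c("utilization_profile", class(out)))
}
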