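new_perm_null <- function(statistic, observed, null_values, n_sets, seed, extra = list()) {
  s <- sd(null_values)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mean(null_values)) / s
  if (is.na(z)) inform("null distribution has zero spread: Z undefined")
  structure(c(list(statistic = statistic, observed = observed,
                   null_values = null_values,
                   z_score = z,
                   empirical_p = (1 + sum(null_values >= observed)) / (n_sets + 1),
                   n_sets = n_sets, seed = seed),
              extra),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %s: observed = %.4g, null mean = %.4g (sd %.4g), Z = %s, empirical p = %.4g (%d sets)\n",
              x$statistic, x$observed, mean(x$null_values), sd(x$null_values),
              ifelse(is.na(x$z_score), "NA", sprintf("%.2f", x$z_score)),
              x$empirical_p, x$n_sets))
  invisible(x)
}

#' Cluster-membership concordance of ortholog pairs
#'
#' An ortholog pair is *eligible* when both genes received a hard cluster
#' assignment; it is *concordant* when its two clusters form a
#' cross-species pair in `pairing` (i.e. the orthologs fall into analogous
#' clusters).
#'
#' @param om An [ortholog_map].
#' @param a_a,a_b [cluster_assignment] for species A and B.
#' @param pairing A [pair_clusters()] result.
#' @return A list with `n_concordant`, `n_eligible` and `pairs`, a tibble of
#'   the eligible pairs with their clusters and a `concordant` flag.
#' @export
ortholog_cluster_concordance <- function(om, a_a, a_b, pairing) {
  stopifnot(inherits(pairing, "cluster_pairing"))
  d <- tibble(gene_a = om$gene_a, gene_b = om$gene_b) %>%
    left_join(a_a %>% select("gene", cl_a = "cluster"), by = c(gene_a = "gene")) %>%
    left_join(a_b %>% select("gene", cl_b = "cluster"), by = c(gene_b = "gene")) %>%
    filter(!is.na(.data$cl_a), !is.na(.data$cl_b))
  key <- paste(pairing$pairs$cluster_a, pairing$pairs$cluster_b, sep = "\r")
  d$concordant <- paste(d$cl_a, d$cl_b, sep = "\r") %in% key
  list(n_concordant = sum(d$concordant), n_eligible = nrow(d), pairs = d)
}

#' Permutation null for ortholog cluster concordance
#'
#' Compares the observed concordant-pair count against `n_sets` sets of
#' random gene pairs: each set draws `n_eligible` pairs by sampling (with
#' replacement, uniformly and independently) an assigned gene from each
#' species, and counts how many land in paired clusters.
#'
#' @inheritParams ortholog_cluster_concordance
#' @param n_sets Number of random-pair sets (default 1000).
#' @param seed Integer seed.
#' @return A `perm_null` object with the observed count, the null vector,
#'   `z_score` and the add-one empirical p-value
#'   `(1 + #\{null >= observed\}) / (n_sets + 1)`.
#' @export
concordance_null <- function(om, a_a, a_b, pairing, n_sets = 1000, seed = 1) {
  obs <- ortholog_cluster_concordance(om, a_a, a_b, pairing)
  if (obs$n_eligible < 1) abort("no eligible ortholog pair (both genes assigned)")
  cl_a <- a_a$cluster[!is.na(a_a$cluster)]
  cl_b <- a_b$cluster[!is.na(a_b$cluster)]
  key <- paste(pairing$pairs$cluster_a, pairing$pairs$cluster_b, sep = "\r")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_values <- vapply(seq_len(n_sets), function(i) {
    ra <- sample(cl_a, obs$n_eligible, replace = TRUE)
    rb <- sample(cl_b, obs$n_eligible, replace = TRUE)
    sum(paste(ra, rb, sep = "\r") %in% key)
  }, 1)
  new_perm_null("ortholog cluster concordance", obs$n_concordant, null_values,
                n_sets, seed,
                extra = list(n_eligible = obs$n_eligible))
}

#' Expression correlation of ortholog pairs over common time points
#'
#' For every ortholog pair with both genes present in the aligned matrices,
#' computes the Pearson correlation across the common time points and a
#' two-sided t-test p-value with `T' - 2` degrees of freedom; pairs with a
#' constant profile in the common window are skipped (correlation
#' undefined).
#'
#' @param om An [ortholog_map].
#' @param za,zb Aligned Z-matrices (genes x common time points), e.g. from
#'   [restrict_to_alignment()] on the Z-normalized time courses.
#' @param alpha Per-pair significance level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"` (rank-transformed
#'   Pearson).
#' @return A list with `n_significant`, `n_tested`, `n_skipped` and `pairs`,
#'   a tibble of per-pair `r`, `p` and `significant`.
#' @export
ortholog_correlations <- function(om, za, zb, alpha = 0.05,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  za <- as.matrix(za); zb <- as.matrix(zb)
  if (ncol(za) != ncol(zb)) abort("aligned matrices must share time points")
  if (ncol(za) < 3) abort("need at least 3 common time points")
  keep <- om$gene_a %in% rownames(za) & om$gene_b %in% rownames(zb)
  if (!any(keep)) abort("no ortholog pair with both genes in the matrices")
  A <- za[om$gene_a[keep], , drop = FALSE]
  B <- zb[om$gene_b[keep], , drop = FALSE]
  if (method == "spearman") {
    A <- t(apply(A, 1, rank)); B <- t(apply(B, 1, rank))
  }
  r <- row_cor(A, B)
  skipped <- is.na(r)
  if (any(skipped)) {
    inform(sprintf("%d pair(s) skipped: constant profile in the common window",
                   sum(skipped)))
  }
  df <- ncol(za) - 2
  p <- 2 * pt(-abs(r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))), df)
  p[abs(r) >= 1 - 1e-12] <- 0  # limit of a perfectly collinear pair
  out <- tibble(gene_a = om$gene_a[keep], gene_b = om$gene_b[keep],
                r = r, p = p, significant = !is.na(p) & p < alpha)
  list(n_significant = sum(out$significant, na.rm = TRUE),
       n_tested = sum(!skipped), n_skipped = sum(skipped),
       pairs = out, alpha = alpha, method = method)
}

row_cor <- function(A, B) {
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  va <- rowSums(A^2); vb <- rowSums(B^2)
  r <- rowSums(A * B) / sqrt(va * vb)
  r[va == 0 | vb == 0] <- NA_real_
  unname(pmin(pmax(r, -1), 1))
}

#' Permutation null for ortholog correlation counts
#'
#' Statistic: the number of gene pairs whose expression correlation over
#' the common time points is significant at `alpha`. Each of the `n_sets`
#' null sets pairs `n_tested` genes drawn uniformly (with replacement) from
#' the rows of `za` with genes drawn from the rows of `zb`, on the same
#' common-time-point grid as the observed statistic.
#'
#' @inheritParams ortholog_correlations
#' @param n_sets Number of random-pair sets (default 1000).
#' @param seed Integer seed.
#' @return A `perm_null` object.
#' @export
correlation_null <- function(om, za, zb, alpha = 0.05, n_sets = 1000, seed = 1,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  obs <- ortholog_correlations(om, za, zb, alpha = alpha, method = method)
  za <- as.matrix(za); zb <- as.matrix(zb)
  df <- ncol(za) - 2
  rcrit <- sqrt(stats::qt(1 - alpha / 2, df)^2 / (stats::qt(1 - alpha / 2, df)^2 + df))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- obs$n_tested
  null_values <- vapply(seq_len(n_sets), function(i) {
    A <- za[sample(nrow(za), n, replace = TRUE), , drop = FALSE]
    B <- zb[sample(nrow(zb), n, replace = TRUE), , drop = FALSE]
    if (method == "spearman") {
      A <- t(apply(A, 1, rank)); B <- t(apply(B, 1, rank))
    }
    r <- row_cor(A, B)
    sum(!is.na(r) & abs(r) > rcrit)
  }, 1)
  new_perm_null("significant ortholog correlations", obs$n_significant,
                null_values, n_sets, seed,
                extra = list(n_tested = obs$n_tested, alpha = alpha))
}
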