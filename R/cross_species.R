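#' Restrict two time courses to their aligned ("common") time points
#'
#' @param xa,xb [expr_timecourse] objects (or plain matrices with time-label
#'   column names) for species A and B.
#' @param al A [time_alignment] whose labels occur in the respective
#'   column names, in increasing column order on both sides.
#' @return A list with matrices `a` and `b`, each with one column per
#'   alignment pair, in alignment order.
#' @export
restrict_to_alignment <- function(xa, xb, al) {
  stopifnot(inherits(al, "time_alignment"))
  ma <- if (inherits(xa, "expr_timecourse")) xa$values else as.matrix(xa)
  mb <- if (inherits(xb, "expr_timecourse")) xb$values else as.matrix(xb)
  ia <- match(al$label_a, colnames(ma))
  ib <- match(al$label_b, colnames(mb))
  if (anyNA(ia)) {
    abort(sprintf("alignment label(s) missing from species A: %s",
                  paste(al$label_a[is.na(ia)], collapse = ", ")))
  }
  if (anyNA(ib)) {
    abort(sprintf("alignment label(s) missing from species B: %s",
                  paste(al$label_b[is.na(ib)], collapse = ", ")))
  }
  if (any(diff(ia) <= 0) || any(diff(ib) <= 0)) {
    abort("alignment is not monotone against the time courses")
  }
  list(a = ma[, ia, drop = FALSE], b = mb[, ib, drop = FALSE])
}

#' Euclidean distances between two sets of cluster centers
#'
#' @param centers_a,centers_b Matrices of cluster centers restricted to the
#'   same aligned time points (rows = clusters, equal column counts).
#' @return A `nrow(centers_a)` x `nrow(centers_b)` distance matrix.
#' @export
cluster_center_distances <- function(centers_a, centers_b) {
  centers_a <- as.matrix(centers_a); centers_b <- as.matrix(centers_b)
  if (ncol(centers_a) != ncol(centers_b)) {
    abort("center matrices must share the aligned time-point columns")
  }
  d2 <- outer(rowSums(centers_a^2), rowSums(centers_b^2), `+`) -
    2 * centers_a %*% t(centers_b)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  dimnames(d) <- list(rownames(centers_a), rownames(centers_b))
  d
}

#' Pair expression clusters across two species
#'
#' Builds 1-to-1 cluster pairs from the Euclidean geometry of the cluster
#' centers at aligned time points. Under the default `"combined"` rule, a
#' pair (i, j) forms only when their distance is strictly smaller than the
#' distance from either member to *any* other cluster of either species;
#' `"cross-only"` relaxes this to mutual row/column minima of the
#' cross-species distance matrix. Exact ties among competing candidates
#' disqualify the clusters involved (logged). An average-linkage tree over
#' the combined 2c centers is attached for display.
#'
#' @param centers_a,centers_b Cluster-center matrices restricted to aligned
#'   time points (use [restrict_to_alignment()] on `fit$centers`).
#' @param rule `"combined"` (default) or `"cross-only"`.
#' @return An object of class `cluster_pairing`: list with `pairs` (tibble
#'   `cluster_a`, `cluster_b`, `distance`), `unpaired_a`, `unpaired_b`,
#'   `ties` (tibble of tied candidates, possibly empty), `tree` (an
#'   [stats::hclust] over the 2c combined centers) and `rule`.
#' @export
pair_clusters <- function(centers_a, centers_b, rule = c("combined", "cross-only")) {
  rule <- match.arg(rule)
  centers_a <- as.matrix(centers_a); centers_b <- as.matrix(centers_b)
  if (is.null(rownames(centers_a))) rownames(centers_a) <- paste0("C", seq_len(nrow(centers_a)))
  if (is.null(rownames(centers_b))) rownames(centers_b) <- paste0("C", seq_len(nrow(centers_b)))
  D <- cluster_center_distances(centers_a, centers_b)
  if (!all(is.finite(D))) abort("non-finite center distances")
  Daa <- cluster_center_distances(centers_a, centers_a)
  Dbb <- cluster_center_distances(centers_b, centers_b)
  na <- nrow(D); nb <- ncol(D)
  pairs <- list(); ties <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- D[i, j]
      # competitors: every other cluster of either species, seen from i or j
      comp <- c(D[i, -j], D[-i, j],
                if (rule == "combined") c(Daa[i, -i], Dbb[j, -j]))
      if (all(d <= comp) && any(comp == d)) {
        # would qualify but for an exact tie: conservatively unpaired
        ties[[length(ties) + 1]] <- tibble(cluster_a = rownames(D)[i],
                                           cluster_b = colnames(D)[j],
                                           distance = d)
        next
      }
      if (all(d < comp)) {
        pairs[[length(pairs) + 1]] <- tibble(cluster_a = rownames(D)[i],
                                             cluster_b = colnames(D)[j],
                                             distance = d)
      }
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(cluster_a = character(), cluster_b = character(), distance = numeric())
  ties <- if (length(ties)) bind_rows(ties) else
    tibble(cluster_a = character(), cluster_b = character(), distance = numeric())
  if (nrow(ties) > 0) {
    warn(sprintf("%d exact distance tie(s): tied clusters left unpaired", nrow(ties)))
  }
  combined <- rbind(centers_a, centers_b)
  rownames(combined) <- c(paste0("A_", rownames(centers_a)),
                          paste0("B_", rownames(centers_b)))
  tree <- hclust(dist(combined), method = "average")
  structure(list(pairs = pairs,
                 unpaired_a = setdiff(rownames(D), pairs$cluster_a),
                 unpaired_b = setdiff(colnames(D), pairs$cluster_b),
                 ties = ties, tree = tree, rule = rule,
                 distances = D),
            class = "cluster_pairing")
}

#' @export
print.cluster_pairing <- function(x, ...) {
  cat(sprintf("<cluster_pairing> %d pair(s) (%s rule); unpaired: %d in A, %d in B\n",
              nrow(x$pairs), x$rule, length(x$unpaired_a), length(x$unpaired_b)))
  if (nrow(x$pairs)) print(as.data.frame(x$pairs), row.names = FALSE)
  invisible(x)
}

#' Compare a TF family's distribution over cluster pairs between species
#'
#' For each family, forms the 2 x (number of cluster pairs) contingency
#' table of that family's assigned members per paired cluster (one row per
#' species) and tests homogeneity with Fisher's exact test — exact
#' enumeration when the table total is at most `exact_limit`, otherwise a
#' Monte-Carlo null with `n_mc` tables drawn under fixed margins.
#'
#' @param a_a,a_b [cluster_assignment] for species A and B.
#' @param pairing A [pair_clusters()] result with at least 2 pairs.
#' @param cat_a,cat_b [tf_catalog] for the two species.
#' @param n_mc Monte-Carlo replicates for large tables (default 2000).
#' @param exact_limit Largest table total handled by exact enumeration
#'   (default 200).
#' @param seed Seed for the Monte-Carlo branch.
#' @return A tibble with columns `family`, `n_a`, `n_b`, `p_value`, `method`.
#' @export
family_distribution_test <- function(a_a, a_b, pairing, cat_a, cat_b,
                                     n_mc = 2000, exact_limit = 200, seed = 1) {
  stopifnot(inherits(pairing, "cluster_pairing"))
  if (nrow(pairing$pairs) < 2) abort("need at least 2 cluster pairs")
  fams <- sort(union(unique(cat_a$family), unique(cat_b$family)))
  asg_a <- a_a[!is.na(a_a$cluster), ]
  asg_b <- a_b[!is.na(a_b$cluster), ]
  out <- purrr::map_dfr(fams, function(f) {
    ga <- cat_a$gene[cat_a$family == f]
    gb <- cat_b$gene[cat_b$family == f]
    ca <- vapply(pairing$pairs$cluster_a, function(cl)
      sum(asg_a$gene[asg_a$cluster == cl] %in% ga), 1L)
    cb <- vapply(pairing$pairs$cluster_b, function(cl)
      sum(asg_b$gene[asg_b$cluster == cl] %in% gb), 1L)
    if (sum(ca) + sum(cb) == 0) {
      return(tibble(family = f, n_a = 0L, n_b = 0L,
                    p_value = NA_real_, method = "skipped: no members"))
    }
    tab <- rbind(A = ca, B = cb)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
      return(tibble(family = f, n_a = sum(ca), n_b = sum(cb),
                    p_value = 1, method = "degenerate table"))
    }
    if (sum(tab) <= exact_limit) {
      p <- fisher.test(tab, workspace = 2e7)$p.value
      method <- "exact"
    } else {
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
      set.seed(seed)
      p <- fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
      method <- sprintf("monte-carlo (B=%d)", n_mc)
    }
    tibble(family = f, n_a = sum(ca), n_b = sum(cb), p_value = p, method = method)
  })
  out
}

#' TF-family representation tests per cluster pair, pooling both species
#'
#' Pools the assigned members of each cluster pair across the two species
#' and tests each family's representation against the pooled assigned
#' background with the two one-sided hypergeometric tails.
#'
#' @inheritParams family_distribution_test
#' @param alpha One-sided significance level (default 0.0025).
#' @return A tibble with columns `pair` ("A-cluster/B-cluster"), `family`,
#'   `k`, `n`, `K`, `N`, `p_over`, `p_under`, `over`, `under`.
#' @export
pair_family_enrichment <- function(pairing, a_a, a_b, cat_a, cat_b, alpha = 0.0025) {
  stopifnot(inherits(pairing, "cluster_pairing"))
  if (nrow(pairing$pairs) == 0) abort("pairing is empty")
  asg_a <- a_a[!is.na(a_a$cluster), ]
  asg_b <- a_b[!is.na(a_b$cluster), ]
  N <- nrow(asg_a) + nrow(asg_b)
  fams <- sort(union(unique(cat_a$family), unique(cat_b$family)))
  fam_members <- function(f) {
    c(sum(asg_a$gene %in% cat_a$gene[cat_a$family == f]),
      sum(asg_b$gene %in% cat_b$gene[cat_b$family == f]))
  }
  rows <- purrr::map_dfr(seq_len(nrow(pairing$pairs)), function(i) {
    cl_a <- pairing$pairs$cluster_a[i]; cl_b <- pairing$pairs$cluster_b[i]
    members_a <- asg_a$gene[asg_a$cluster == cl_a]
    members_b <- asg_b$gene[asg_b$cluster == cl_b]
    n <- length(members_a) + length(members_b)
    purrr::map_dfr(fams, function(f) {
      K <- sum(fam_members(f))
      k <- sum(members_a %in% cat_a$gene[cat_a$family == f]) +
        sum(members_b %in% cat_b$gene[cat_b$family == f])
      tibble(pair = paste0(cl_a, "/", cl_b), family = f, k = k, n = n, K = K)
    })
  })
  rows <- rows[rows$K > 0, ]
  p <- hypergeometric_overlap(rows$k, rows$n, rows$K, N)
  rows$N <- N
  rows$p_over <- p$p_over
  rows$p_under <- p$p_under
  rows$over <- rows$p_over < alpha
  rows$under <- rows$p_under < alpha
  rows
}

#' Export the combined-center linkage tree in Newick format
#'
#' @param pairing A [pair_clusters()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_pairing_tree <- function(pairing, path) {
  stopifnot(inherits(pairing, "cluster_pairing"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(pairing$tree), path)
  invisible(path)
}
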