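test_that("alignment restriction selects and orders the common columns", {
  xa <- small_expr(matrix(1:12, 2, 6), times = as.character(seq(0, 10, 2)))
  xb <- small_expr(matrix(13:24, 2, 6), times = as.character(c(1, 3, 5, 7, 9, 11)))
  al <- time_alignment(tibble::tibble(label_a = c("0", "4", "8"),
                                      label_b = c("1", "5", "9")))
  r <- restrict_to_alignment(xa, xb, al)
  expect_equal(colnames(r$a), c("0", "4", "8"))
  expect_equal(colnames(r$b), c("1", "5", "9"))
  expect_equal(r$a, xa$values[, c("0", "4", "8")])

  # identity alignment leaves the matrices unchanged
  ali <- time_alignment(tibble::tibble(label_a = colnames(xa$values),
                                       label_b = colnames(xb$values)))
  ri <- restrict_to_alignment(xa, xb, ali)
  expect_equal(ri$a, xa$values)
  expect_equal(ri$b, xb$values)

  bad <- time_alignment(tibble::tibble(label_a = c("0", "4"), label_b = c("5", "99")))
  expect_error(restrict_to_alignment(xa, xb, bad), "missing from species B")
})

test_that("center distances are Euclidean", {
  a <- rbind(c(0, 0))
  b <- rbind(c(3, 4))
  expect_equal(unname(cluster_center_distances(a, b)[1, 1]), 5)

  # identical center sets: zero diagonal
  set.seed(9)
  m <- matrix(rnorm(21), 7, 3)
  expect_equal(unname(diag(cluster_center_distances(m, m))), rep(0, 7),
               tolerance = 1e-6)

  # brute force on random 7 x 12 fixtures
  ca <- matrix(rnorm(84), 7, 12); cb <- matrix(rnorm(84), 7, 12)
  D <- cluster_center_distances(ca, cb)
  for (i in 1:7) for (j in 1:7) {
    expect_equal(D[i, j], sqrt(sum((ca[i, ] - cb[j, ])^2)), tolerance = 1e-9)
  }
  expect_error(cluster_center_distances(ca, cb[, 1:5]), "share")
})

test_that("mutual-minimum pairing forms, refuses ties, and is symmetric", {
  set.seed(15)
  base <- matrix(rnorm(7 * 6, sd = 4), 7, 6,
                 dimnames = list(paste0("K", 1:7), NULL))
  pert <- base + matrix(rnorm(42, sd = 0.05), 7, 6)
  pr <- pair_clusters(base, pert)
  expect_equal(nrow(pr$pairs), 7)
  expect_equal(pr$pairs$cluster_a, pr$pairs$cluster_b)
  expect_length(pr$unpaired_a, 0)

  # pairing invariant: each pair beats every alternative from either side
  D <- pr$distances
  for (i in seq_len(nrow(pr$pairs))) {
    ia <- match(pr$pairs$cluster_a[i], rownames(D))
    ib <- match(pr$pairs$cluster_b[i], colnames(D))
    expect_true(all(D[ia, ib] < D[ia, -ib]) && all(D[ia, ib] < D[-ia, ib]))
  }

  # symmetry: swapping species swaps roles but keeps the same pair set
  pr2 <- pair_clusters(pert, base)
  expect_setequal(paste(pr$pairs$cluster_a, pr$pairs$cluster_b),
                  paste(pr2$pairs$cluster_b, pr2$pairs$cluster_a))

  # relabeling equivariance
  perm <- sample(7)
  pr3 <- pair_clusters(base, pert[perm, ])
  expect_setequal(paste(pr3$pairs$cluster_a, pr3$pairs$cluster_b),
                  paste(paste0("K", 1:7), paste0("K", 1:7)))

  # an exact tie disqualifies the clusters involved
  ca <- rbind(x = c(0, 0), y = c(10, 10))
  cb <- rbind(p = c(1, 0), q = c(-1, 0), r = c(10, 11))
  expect_warning(prt <- pair_clusters(ca, cb), "tie")
  expect_false("x" %in% prt$pairs$cluster_a)
  expect_true(any(prt$pairs$cluster_a == "y" & prt$pairs$cluster_b == "r"))
})

test_that("shared-archetype species pairs are recovered by pairing", {
  # sigma = 0: exact recovery with zero distances
  sim0 <- simulate_species_pair(sim_config(n_genes = 300, n_orthologs = 50,
                                           noise_sd = 0), seed = 21)
  ca <- cluster_species(sim0, "a", seed = 22)
  cb <- cluster_species(sim0, "b", seed = 23)
  ctr <- restrict_to_alignment(ca$fit$centers, cb$fit$centers, sim0$alignment)
  pr <- quiet(pair_clusters(ctr$a, ctr$b))
  expect_equal(nrow(pr$pairs), 7)
  expect_lt(max(pr$pairs$distance), 1e-6)
  maj_a <- cluster_archetype_map(sim0, "a", ca$assignment)
  maj_b <- cluster_archetype_map(sim0, "b", cb$assignment)
  expect_equal(unname(maj_a[pr$pairs$cluster_a]), unname(maj_b[pr$pairs$cluster_b]))
})

test_that("family distribution homogeneity test matches enumeration", {
  # construct a pairing over two cluster pairs directly
  ca <- rbind(C1 = c(0, 0), C2 = c(8, 8))
  cb <- rbind(C1 = c(0.5, 0), C2 = c(8, 8.5))
  pr <- pair_clusters(ca, cb)
  expect_equal(nrow(pr$pairs), 2)

  mk <- function(genes, clusters) {
    structure(tibble::tibble(gene = genes, cluster = clusters, membership = 1),
              threshold = 0.8,
              class = c("cluster_assignment", "tbl_df", "tbl", "data.frame"))
  }
  # species A: 8 family members in C1, 2 in C2; species B: 1 and 9
  a_a <- mk(paste0("a", 1:10), rep(c("C1", "C2"), c(8, 2)))
  a_b <- mk(paste0("b", 1:10), rep(c("C1", "C2"), c(1, 9)))
  cat_a <- tf_catalog(data.frame(gene = paste0("a", 1:10), family = "Ets"))
  cat_b <- tf_catalog(data.frame(gene = paste0("b", 1:10), family = "Ets"))
  res <- family_distribution_test(a_a, a_b, pr, cat_a, cat_b)
  row <- res[res$family == "Ets", ]
  expect_equal(row$method, "exact")
  expect_equal(row$p_value, enum_fisher_2x2(rbind(c(8, 2), c(1, 9))),
               tolerance = 1e-9)
  expect_equal(row$p_value, 0.005477, tolerance = 1e-3)

  # identical compositions: p = 1
  res2 <- family_distribution_test(a_a, a_a2 <- mk(paste0("b", 1:10),
                                                   rep(c("C1", "C2"), c(8, 2))),
                                   pr, cat_a, cat_b)
  expect_equal(res2$p_value[res2$family == "Ets"], 1)

  # Monte-Carlo branch agrees with the exact one within 3 MC standard errors
  res_mc <- family_distribution_test(a_a, a_b, pr, cat_a, cat_b,
                                     exact_limit = 5, n_mc = 4000, seed = 2)
  p_mc <- res_mc$p_value[res_mc$family == "Ets"]
  se <- sqrt(row$p_value * (1 - row$p_value) / 4000)
  expect_lt(abs(p_mc - row$p_value), 3 * se + 1e-4)
})

test_that("pooled pair enrichment mirrors the per-cluster test", {
  ca <- rbind(C1 = c(0, 0), C2 = c(8, 8))
  cb <- rbind(C1 = c(0.5, 0), C2 = c(8, 8.5))
  pr <- pair_clusters(ca, cb)
  mk <- function(genes, clusters) {
    structure(tibble::tibble(gene = genes, cluster = clusters, membership = 1),
              threshold = 0.8,
              class = c("cluster_assignment", "tbl_df", "tbl", "data.frame"))
  }
  set.seed(31)
  a_a <- mk(paste0("a", 1:80), rep(c("C1", "C2"), each = 40))
  a_b <- mk(paste0("b", 1:80), rep(c("C1", "C2"), each = 40))
  fam_a <- ifelse(seq_len(80) <= 30, "HLH", "other")   # HLH concentrated in C1
  fam_b <- ifelse(seq_len(80) <= 30, "HLH", "other")
  cat_a <- tf_catalog(data.frame(gene = paste0("a", 1:80), family = fam_a))
  cat_b <- tf_catalog(data.frame(gene = paste0("b", 1:80), family = fam_b))
  e <- pair_family_enrichment(pr, a_a, a_b, cat_a, cat_b)
  row <- e[e$pair == "C1/C1" & e$family == "HLH", ]
  # pooled counts: k = 60 HLH in the pooled pair of 80, K = 60 of N = 160
  expect_equal(row$k, 60); expect_equal(row$n, 80)
  expect_equal(row$K, 60); expect_equal(row$N, 160)
  expect_true(row$over)
  manual <- hypergeometric_overlap(60, 80, 60, 160)
  expect_equal(row$p_over, manual$p_over)
})
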