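test_that("pre-clustering filters drop never-expressed and near-constant genes", {
  vals <- rbind(g1 = c(5.0, 5.3, 5.9, 5.2),   # range 0.9 -> constant
                g2 = c(5.0, 5.5, 6.0, 5.2),   # range exactly 1.0 -> retained
                g3 = c(0.0, 8.0, 0.0, 0.0),   # never present -> dropped first
                g4 = c(3.0, 6.0, 4.0, 5.0))
  pres <- rbind(g1 = c(TRUE, TRUE, TRUE, TRUE),
                g2 = c(TRUE, TRUE, TRUE, TRUE),
                g3 = c(FALSE, FALSE, FALSE, FALSE),
                g4 = c(TRUE, TRUE, TRUE, TRUE))
  colnames(vals) <- colnames(pres) <- as.character(1:4)
  x <- expr_timecourse(vals)
  p <- presence_table(pres)
  out <- quiet(filter_for_clustering(x, p))
  expect_setequal(rownames(out$values), c("g2", "g4"))
  d <- attr(out, "dropped")
  expect_equal(d$never_expressed, "g3")
  expect_equal(d$constant, "g1")

  pres[] <- FALSE
  expect_error(quiet(filter_for_clustering(x, presence_table(pres))),
               "all genes removed")
})

test_that("Z-normalization standardizes rows with the population sd", {
  x <- small_expr(rbind(c(1, 2, 3), c(10, 20, 30)))
  z <- z_normalize(x)
  expect_equal(unname(rowMeans(z$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(z$values^2))), c(1, 1), tolerance = 1e-12)

  # hand case with population sd = 2
  z2 <- z_normalize(small_expr(matrix(c(0, 0, 4, 4), 1, 4)))
  expect_equal(unname(z2$values[1, ]), c(-1, -1, 1, 1))

  # affine invariance
  set.seed(2)
  v <- matrix(rnorm(8), 1, 8)
  za <- z_normalize(small_expr(v))
  zb <- z_normalize(small_expr(3.2 * v + 17))
  expect_equal(za$values, zb$values, tolerance = 1e-12)

  expect_error(z_normalize(small_expr(matrix(5, 2, 3))), "zero-variance")
})

test_that("fuzzy c-means separates well-separated clouds crisply", {
  set.seed(10)
  x <- rbind(matrix(rnorm(50 * 4, mean = 5, sd = 0.1), 50, 4),
             matrix(rnorm(50 * 4, mean = -5, sd = 0.1), 50, 4))
  rownames(x) <- paste0("g", 1:100)
  fit <- fuzzy_cmeans(x, c = 2, m = 1.25, seed = 3)
  mx <- apply(fit$membership, 1, max)
  expect_true(all(mx > 0.99))
  top <- apply(fit$membership, 1, which.max)
  expect_equal(length(unique(top[1:50])), 1)
  expect_equal(length(unique(top[51:100])), 1)
  expect_false(top[1] == top[51])

  # membership rows sum to 1, centers inside the data's bounding box
  expect_equal(unname(rowSums(fit$membership)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(fit$centers >= min(x) & fit$centers <= max(x)))

  # determinism
  fit2 <- fuzzy_cmeans(x, c = 2, m = 1.25, seed = 3)
  expect_identical(fit$membership, fit2$membership)
})

test_that("a profile coinciding with a center gets full membership there", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30 * 3, 4, 0.05), 30, 3),
             matrix(rnorm(30 * 3, -4, 0.05), 30, 3))
  x <- rbind(x, colMeans(x[1:30, ]))  # will be (near) the converged center
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 5)
  # the appended point is orders of magnitude closer to one center
  expect_gt(max(fit$membership[61, ]), 0.999)

  # duplicated points: centers land exactly on the two points and the
  # singularity rule hands out memberships of exactly 0/1
  y <- rbind(matrix(rep(c(2, -1, 3), each = 20), 20, 3),
             matrix(rep(c(-2, 4, 0), each = 20), 20, 3))
  rownames(y) <- paste0("g", 1:40)
  fity <- fuzzy_cmeans(y, c = 2, m = 1.5, seed = 8)
  expect_true(all(apply(fity$membership, 1, max) == 1))
})

test_that("the objective is non-increasing across iterations", {
  for (s in 1:50) {
    set.seed(s)
    x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(paste0("g", 1:60), NULL))
    fit <- fuzzy_cmeans(x, c = 4, m = 1.5, seed = s, restarts = 1, max_iter = 60)
    expect_true(all(diff(fit$objective) <= 1e-8), label = paste("seed", s))
  }
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(20)
  x <- rbind(matrix(rnorm(40 * 6, 3, 0.3), 40, 6),
             matrix(rnorm(40 * 6, -3, 0.3), 40, 6),
             matrix(rnorm(40 * 6, c(3, -3), 0.3), 40, 6))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  fit <- fuzzy_cmeans(x, c = 3, m = 1.5, seed = 6)
  ref <- e1071::cmeans(x, centers = fit$centers, m = 1.5, iter.max = 200)
  # same fixed point: centers match up to tiny drift
  d <- cluster_center_distances(fit$centers, ref$centers)
  expect_lt(max(diag(d)), 1e-3)
  # memberships agree (same center order since we seeded from our centers)
  expect_lt(max(abs(unname(fit$membership) - unname(ref$membership))), 1e-3)
})

test_that("small fuzzifier approaches hard k-means on separated data", {
  set.seed(30)
  x <- rbind(matrix(rnorm(40 * 4, 4, 0.2), 40, 4),
             matrix(rnorm(40 * 4, -4, 0.2), 40, 4))
  rownames(x) <- paste0("g", 1:80)
  fit <- fuzzy_cmeans(x, c = 2, m = 1.01, seed = 7)
  km <- stats::kmeans(x, centers = fit$centers)
  soft <- apply(fit$membership, 1, which.max)
  expect_equal(unname(soft), unname(km$cluster))
  expect_true(all(apply(fit$membership, 1, max) > 1 - 1e-6))
})

test_that("member assignment applies a strict membership threshold", {
  u <- rbind(c(0.8, 0.15, 0.05),
             c(0.95, 0.03, 0.02),
             c(0.5, 0.3, 0.2))
  dimnames(u) <- list(paste0("g", 1:3), paste0("C", 1:3))
  fake <- structure(list(centers = matrix(0, 3, 2), membership = u,
                         m = 1.25, c = 3, objective = 1, iterations = 1,
                         seed = 1, data = NULL),
                    class = "fuzzy_clustering")
  a <- assign_members(fake, threshold = 0.8)
  expect_true(is.na(a$cluster[1]))     # exactly 0.8: unassigned
  expect_equal(a$cluster[2], "C1")
  expect_true(is.na(a$cluster[3]))
  expect_error(assign_members(fake, threshold = 0.2), "threshold")
})

test_that("noiseless simulation is recovered exactly", {
  sim <- simulate_species_pair(sim_config(n_genes = 300, n_orthologs = 60,
                                          noise_sd = 0), seed = 12)
  cs <- cluster_species(sim, "a", seed = 13)
  a <- cs$assignment
  expect_true(all(!is.na(a$cluster)))  # all non-noise genes assigned
  tg <- sim$truth$genes[sim$truth$genes$species == "A", ]
  tr <- tg$archetype[match(a$gene, tg$gene)]
  # assignment = planted partition (up to label permutation)
  expect_equal(length(unique(paste(a$cluster, tr))), 7)
})

test_that("cluster family enrichment flags a planted excess and holds its level", {
  set.seed(40)
  genes <- paste0("g", 1:700)
  fam <- c(rep("HLH", 60), rep("other", 640))
  cat <- tf_catalog(data.frame(gene = genes, family = fam))
  mk_assign <- function(cluster1) {
    cl <- rep(NA_character_, 700)
    cl[cluster1] <- "C1"
    cl[setdiff(seq_len(700), cluster1)] <- sample(paste0("C", 2:7), 600, replace = TRUE)
    structure(tibble::tibble(gene = genes, cluster = cl, membership = 1),
              threshold = 0.8,
              class = c("cluster_assignment", "tbl_df", "tbl", "data.frame"))
  }
  # planted 5x-odds enrichment of the 60-member family in a 100-gene cluster
  w <- ifelse(fam == "HLH", 5, 1)
  planted <- sample(700, 100, prob = w)
  e <- cluster_family_enrichment(mk_assign(planted), cat)
  expect_true(e$over[e$cluster == "C1" & e$family == "HLH"])

  # null level per side across random clusters
  flags <- replicate(400, {
    e0 <- cluster_family_enrichment(mk_assign(sample(700, 100)), cat)
    row <- e0[e0$cluster == "C1" & e0$family == "HLH", ]
    c(row$over, row$under)
  })
  expect_lte(mean(flags[1, ]), 0.0025 + 3 * sqrt(0.0025 / 400))
  expect_lte(mean(flags[2, ]), 0.0025 + 3 * sqrt(0.0025 / 400))

  # family absent from a cluster still yields a valid lower tail
  e2 <- cluster_family_enrichment(mk_assign(which(fam == "other")[1:100]), cat)
  row <- e2[e2$cluster == "C1" & e2$family == "HLH", ]
  expect_equal(row$k, 0)
  expect_lte(row$p_under, 1)
})
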