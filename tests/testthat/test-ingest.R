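test_that("TF assignment files parse with set semantics", {
  path <- withr::local_tempfile(fileext = ".tf.ass")
  writeLines(c("# comment line", "g1\tHomeobox", "g1\tzf-C2H2", "g2\tbZIP"), path)
  cat <- read_tf_assignments(path, species = "xt")
  expect_setequal(cat$family[cat$gene == "g1"], c("Homeobox", "zf-C2H2"))
  expect_equal(cat$family[cat$gene == "g2"], "bZIP")
  expect_identical(attr(cat, "species"), "xt")

  # duplicates collapse: 20 rows with 3 duplicated (gene, family) rows
  set.seed(1)
  rows <- sprintf("g%d\tfam%d", rep(1:10, 2), c(1:10, 11:17, 8:10))
  writeLines(rows, path)
  expect_equal(nrow(read_tf_assignments(path)), 17)

  writeLines(c("# only", "# comments"), path)
  expect_error(read_tf_assignments(path), "no assignments")

  writeLines(c("g1\tHomeobox", "badrow-without-tab"), path)
  expect_error(read_tf_assignments(path), "line 2")
})

test_that("quantile normalization equalizes column distributions", {
  # hand case: rank-wise means
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(quantile_normalize(m), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  # identical columns are a fixed point
  m2 <- matrix(rep(c(5, 1, 3), 3), 3, 3)
  expect_equal(quantile_normalize(m2), m2)

  # postcondition: column-sorted vectors identical across columns
  set.seed(42)
  m3 <- matrix(rnorm(200), 40, 5)
  q <- quantile_normalize(m3)
  ref <- rowMeans(apply(m3, 2, sort))
  expect_lt(max(abs(apply(q, 2, sort) - ref)), 1e-9)

  m3[5, 2] <- NA
  expect_error(quantile_normalize(m3), "missing")
  expect_error(quantile_normalize(matrix(1:4, 4, 1)), ">= 2 columns")
})

test_that("probe collapse averages over probes and replicates", {
  pt <- probe_table(
    matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "T0_r1")),
    c(p1 = "g1", p2 = "g1"))
  expect_equal(unname(collapse_probes(pt)$values["g1", "0"]), 3)

  pt2 <- probe_table(
    matrix(c(5, 7), 1, 2, dimnames = list("p1", c("T0_r1", "T0_r2"))),
    c(p1 = "g1"))
  expect_equal(unname(collapse_probes(pt2)$values["g1", "0"]), 6)

  # 3 probes x 2 replicates vs brute-force mean over the 6 cells
  set.seed(3)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("p", 1:3),
                                 c("T0_r1", "T0_r2", "T6_r1", "T6_r2")))
  pt3 <- probe_table(vals, c(p1 = "g1", p2 = "g1", p3 = "g1"))
  out <- collapse_probes(pt3)
  expect_equal(unname(out$values["g1", "0"]), mean(vals[, 1:2]))
  expect_equal(unname(out$values["g1", "6"]), mean(vals[, 3:4]))

  # row permutation of probes does not change the result
  perm <- vals[c(3, 1, 2), ]
  pt4 <- probe_table(perm, c(p1 = "g1", p2 = "g1", p3 = "g1"))
  expect_equal(collapse_probes(pt4)$values, out$values)

  # unmapped probes are dropped with a message
  pt5 <- probe_table(vals, c(p1 = "g1", p2 = "g1"))
  expect_message(collapse_probes(pt5), "1 probe")

  expect_error(probe_table(matrix(1, 1, 1, dimnames = list("p1", "weird")),
                           c(p1 = "g1")),
               "T<label>_r<k>")
})

test_that("FPKM log transform applies a positive pseudocount", {
  m <- matrix(c(1, 0), 1, 2, dimnames = list("g1", c("0", "2")))
  x <- log_transform_fpkm(m, pseudocount = 0.01)
  expect_equal(unname(x$values[1, ]), c(log2(1.01), log2(0.01)), tolerance = 1e-12)
  expect_equal(attr(x, "pseudocount"), 0.01)
  expect_error(log_transform_fpkm(m, pseudocount = 0), "positive")
  expect_error(log_transform_fpkm(matrix(-1, 1, 1, dimnames = list("g", "0"))),
               "non-negative")
  # monotone
  set.seed(1)
  a <- sort(runif(10, 0, 100))
  y <- log_transform_fpkm(matrix(a, 1, 10, dimnames = list("g", 1:10)))
  expect_true(all(diff(y$values[1, ]) > 0))
})

test_that("flag-based presence requires every probe in every replicate", {
  flags <- matrix(TRUE, 2, 4,
                  dimnames = list(c("p1", "p2"),
                                  c("T0_r1", "T0_r2", "T6_r1", "T6_r2")))
  pt <- probe_table(flags, c(p1 = "g1", p2 = "g1"))
  expect_true(call_presence_flags(pt)$matrix["g1", "0"])

  flags2 <- flags; flags2["p2", "T0_r2"] <- FALSE
  pt2 <- probe_table(flags2, c(p1 = "g1", p2 = "g1"))
  p2 <- call_presence_flags(pt2)
  expect_false(p2$matrix["g1", "0"])
  expect_true(p2$matrix["g1", "6"])

  # gene with no probes: absent with a warning
  expect_warning(p3 <- call_presence_flags(pt, genes = c("g1", "g2")),
                 "no probes")
  expect_false(any(p3$matrix["g2", ]))

  # property: equals brute-force conjunction on random tables
  set.seed(11)
  for (i in 1:100) {
    np <- sample(1:5, 1)
    f <- matrix(runif(np * 4) > 0.3, np, 4,
                dimnames = list(paste0("p", 1:np),
                                c("T0_r1", "T0_r2", "T6_r1", "T6_r2")))
    map <- stats::setNames(sample(c("gA", "gB"), np, replace = TRUE),
                           rownames(f))
    res <- call_presence_flags(probe_table(f, map))
    for (g in unique(map)) {
      probes <- names(map)[map == g]
      expect_identical(unname(res$matrix[g, "0"]), all(f[probes, 1:2]))
      expect_identical(unname(res$matrix[g, "6"]), all(f[probes, 3:4]))
    }
  }
})

test_that("FPKM presence threshold is a strict inequality", {
  m <- matrix(c(1.0, 1.0001, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("0", "2")))
  p <- call_presence_fpkm(m, threshold = 1.0)
  expect_false(p$matrix["g1", "0"])   # exactly at threshold: absent
  expect_true(p$matrix["g2", "0"])
  expect_false(any(p$matrix[, "2"]))  # all-zero column absent
})

test_that("table readers and writers round-trip and validate", {
  dir <- withr::local_tempdir()
  x <- small_expr(matrix(rnorm(12), 3, 4), species = "sp1")
  path <- file.path(dir, "expr.tsv")
  write_expression_table(x, path)
  x2 <- read_expression_table(path, species = "sp1")
  expect_equal(x2$values, x$values)

  om <- ortholog_map(tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2")))
  op <- file.path(dir, "orth.tsv")
  write_ortholog_table(om, op)
  expect_equal(as.data.frame(read_ortholog_table(op)), as.data.frame(om))

  # duplicate pairs deduplicate with a message
  writeLines(c("a1\tb1", "a1\tb1", "a2\tb2"), op)
  expect_message(om2 <- read_ortholog_table(op), "1 duplicate")
  expect_equal(nrow(om2), 2)

  al <- time_alignment(tibble::tibble(label_a = c("0", "2"), label_b = c("2", "6")))
  ap <- file.path(dir, "al.tsv")
  write_alignment(al, ap)
  expect_equal(as.data.frame(read_alignment(ap)), as.data.frame(al))

  writeLines(c("0\t6", "2\t2"), ap)  # non-monotone in B
  expect_error(read_alignment(ap), "monotone")

  writeLines(c("a1\tb1", "only-one-field"), op)
  expect_error(read_ortholog_table(op), "line 2")

  p <- small_presence(matrix(c(1, 0, 1, 1), 2, 2))
  pp <- file.path(dir, "pres.tsv")
  write_presence_table(p, pp)
  expect_equal(read_presence_table(pp)$matrix, p$matrix)
})
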