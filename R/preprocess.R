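#' Between-array quantile normalization
#'
#' Forces every column of a matrix onto the same empirical distribution:
#' after normalization, each column's sorted values equal the across-column
#' mean of sorted values, and ties within a column receive the mean of the
#' reference values spanning their rank range.
#'
#' @param values Numeric matrix (rows = probes/genes, columns = arrays),
#'   at least two columns, no missing values.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) abort("quantile normalization needs >= 2 columns")
  if (anyNA(values)) abort("quantile normalization does not accept missing values")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Summarise probe-level values to one value per gene and time point
#'
#' Per gene and time point, the value is the arithmetic mean over all probes
#' mapped to that gene and all replicates of that time point. Probes with no
#' gene mapping are dropped and counted in a message.
#'
#' @param t A [probe_table] of (already normalized) intensities.
#' @param species Species identifier for the result.
#' @return An [expr_timecourse] with one column per distinct time label, in
#'   order of first appearance.
#' @export
collapse_probes <- function(t, species = "unknown") {
  stopifnot(inherits(t, "probe_table"))
  probes <- rownames(t$values)
  mapped <- probes %in% names(t$probe_to_gene)
  if (sum(!mapped) > 0) {
    inform(sprintf("dropping %d probe(s) with no gene mapping", sum(!mapped)))
  }
  if (!any(mapped)) abort("no probe maps to a gene")
  vals <- t$values[mapped, , drop = FALSE]
  genes <- unname(t$probe_to_gene[probes[mapped]])
  times <- unique(t$sample_info$time)
  gene_ids <- unique(genes)
  out <- matrix(NA_real_, length(gene_ids), length(times),
                dimnames = list(gene_ids, times))
  col_time <- t$sample_info$time[match(colnames(vals), t$sample_info$sample)]
  for (tp in times) {
    sub <- vals[, col_time == tp, drop = FALSE]
    out[, tp] <- as.numeric(tapply(rowMeans(sub) * ncol(sub), genes, sum)[gene_ids]) /
      (ncol(sub) * as.numeric(table(genes)[gene_ids]))
  }
  expr_timecourse(out, species = species)
}

#' Log-transform FPKM values
#'
#' Converts non-negative FPKM values to log2 expression with an additive
#' pseudocount: `log2(fpkm + pseudocount)`. The pseudocount keeps
#' never-expressed genes (FPKM 0) at a finite value far below any
#' expression floor and is recorded on the result.
#'
#' @param fpkm Non-negative numeric matrix (genes x time points).
#' @param pseudocount Positive value added before taking log2 (default 0.01).
#' @param species Species identifier.
#' @return An [expr_timecourse] with attribute `pseudocount`.
#' @export
log_transform_fpkm <- function(fpkm, pseudocount = 0.01, species = "unknown") {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) abort("FPKM values must be non-negative")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number")
  }
  x <- expr_timecourse(log2(fpkm + pseudocount), species = species)
  attr(x, "pseudocount") <- pseudocount
  x
}

#' Call presence from probe-level detection flags
#'
#' A gene is called present at a time point only if every probe of that
#' gene, in every replicate of that time point, carries a TRUE detection
#' flag (e.g. an "is well above background" call). Genes with zero mapped
#' probes are called absent with a warning.
#'
#' @param flags A [probe_table] whose values are logical detection flags.
#' @param genes Optional gene universe; genes without probes are reported
#'   absent. Defaults to the genes covered by the probe map.
#' @param species Species identifier.
#' @return A [presence_table].
#' @export
call_presence_flags <- function(flags, genes = NULL, species = "unknown") {
  stopifnot(inherits(flags, "probe_table"))
  if (!is.logical(flags$values)) abort("flag table must be logical")
  probes <- rownames(flags$values)
  mapped <- probes %in% names(flags$probe_to_gene)
  vals <- flags$values[mapped, , drop = FALSE]
  pg <- unname(flags$probe_to_gene[probes[mapped]])
  if (is.null(genes)) genes <- unique(unname(flags$probe_to_gene))
  times <- unique(flags$sample_info$time)
  col_time <- flags$sample_info$time[match(colnames(vals), flags$sample_info$sample)]
  m <- matrix(FALSE, length(genes), length(times), dimnames = list(genes, times))
  no_probe <- setdiff(genes, pg)
  if (length(no_probe) > 0) {
    warn(sprintf("%d gene(s) have no probes and are called absent", length(no_probe)))
  }
  for (tp in times) {
    sub <- vals[, col_time == tp, drop = FALSE]
    all_true <- tapply(rowSums(!sub) == 0, pg, all)
    hit <- intersect(genes, names(all_true))
    m[hit, tp] <- as.logical(all_true[hit])
  }
  presence_table(m, species = species)
}

#' Call presence from FPKM values
#'
#' A gene is present at a time point when its FPKM is strictly greater than
#' the threshold (default 1): FPKM exactly equal to the threshold is absent.
#'
#' @param fpkm Non-negative numeric matrix (genes x time points).
#' @param threshold Presence threshold on the FPKM scale (default 1).
#' @param species Species identifier.
#' @return A [presence_table].
#' @export
call_presence_fpkm <- function(fpkm, threshold = 1.0, species = "unknown") {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) abort("FPKM values must be non-negative")
  presence_table(fpkm > threshold, species = species)
}

#' Filter a time course for clustering
#'
#' Applies the two pre-clustering filters: genes that are never called
#' present at any time point are removed, then genes whose log2 expression
#' range (max minus min) is strictly less than `min_range` are removed as
#' having near-constant expression. A range of exactly `min_range` is
#' retained.
#'
#' @param x An [expr_timecourse].
#' @param p The companion [presence_table] (same genes and time points).
#' @param min_range Minimum retained log2 range (default 1, i.e. two-fold).
#' @return The filtered [expr_timecourse], with attribute `dropped`, a list
#'   with character vectors `never_expressed` and `constant`.
#' @export
filter_for_clustering <- function(x, p, min_range = 1) {
  stopifnot(inherits(x, "expr_timecourse"), inherits(p, "presence_table"))
  genes <- rownames(x$values)
  if (!setequal(genes, rownames(p$matrix))) {
    abort("expression and presence tables cover different genes")
  }
  pm <- p$matrix[genes, colnames(x$values), drop = FALSE]
  never <- genes[rowSums(pm) == 0]
  keep1 <- setdiff(genes, never)
  rng <- apply(x$values[keep1, , drop = FALSE], 1, function(v) max(v) - min(v))
  constant <- keep1[rng < min_range]
  keep <- setdiff(keep1, constant)
  if (length(keep) == 0) abort("all genes removed by filtering")
  inform(sprintf("filtered %d never-expressed and %d near-constant gene(s); %d retained",
                 length(never), length(constant), length(keep)))
  out <- expr_timecourse(x$values[keep, , drop = FALSE], species = x$species,
                         hours = x$hours)
  attr(out, "dropped") <- list(never_expressed = never, constant = constant)
  out
}

#' Z-normalize expression profiles
#'
#' Standardizes each gene's temporal profile to mean 0 and standard
#' deviation 1 across time points, so clustering responds to the direction
#' of change rather than absolute level. The population standard deviation
#' (denominator T) is used.
#'
#' @param x An [expr_timecourse] (post-filtering: every row must vary).
#' @return An [expr_timecourse] in Z units.
#' @export
z_normalize <- function(x) {
  stopifnot(inherits(x, "expr_timecourse"))
  v <- x$values
  mu <- rowMeans(v)
  sdp <- sqrt(rowMeans((v - mu)^2))
  if (any(sdp == 0)) {
    abort(sprintf("zero-variance profile(s): %s",
                  paste(head(rownames(v)[sdp == 0], 5), collapse = ", ")))
  }
  expr_timecourse((v - mu) / sdp, species = x$species, hours = x$hours)
}
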