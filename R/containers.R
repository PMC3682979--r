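#' TF catalog: gene-to-family assignments
#'
#' A TF catalog maps each transcription factor gene of one species to the
#' set of DNA-binding-domain families it belongs to (Homeobox, zf-C2H2,
#' zf-C4, Ets, bZIP, HLH, or any other label). Genes may carry several
#' family labels; every gene carries at least one.
#'
#' @param assignments A data frame with columns `gene` and `family`
#'   (one row per gene-family assignment; duplicates are collapsed).
#' @param species Species identifier string.
#' @return A tibble of class `tf_catalog` with columns `gene` and `family`
#'   and a `species` attribute.
#' @examples
#' tf_catalog(data.frame(gene = c("g1", "g1", "g2"),
#'                       family = c("Homeobox", "zf-C2H2", "bZIP")), "sp")
#' @export
tf_catalog <- function(assignments, species = "unknown") {
  assignments <- as_tibble(assignments)
  if (!all(c("gene", "family") %in% names(assignments))) {
    abort("`assignments` must have columns `gene` and `family`.")
  }
  out <- distinct(assignments[, c("gene", "family")])
  if (nrow(out) == 0L) abort("no assignments: catalog is empty")
  if (any(out$gene == "") || any(out$family == "")) {
    abort("empty gene or family label in catalog")
  }
  structure(out, species = species,
            class = c("tf_catalog", class(out)))
}

#' Expression time course
#'
#' A genes-by-time-points matrix of log2 expression values for one species,
#' with ordered time-point labels (optionally carrying numeric hours).
#'
#' @param values Numeric matrix, rows = genes (rownames required, unique),
#'   columns = ordered time points (colnames required).
#' @param species Species identifier string.
#' @param hours Optional numeric vector of times in hours, one per column.
#'   If `NULL`, the column labels are parsed as numbers when possible.
#' @return An object of class `expr_timecourse`.
#' @export
expr_timecourse <- function(values, species = "unknown", hours = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("expression matrix needs unique row names (gene ids)")
  }
  if (is.null(colnames(values))) abort("expression matrix needs column names (time labels)")
  if (anyNA(values)) abort("expression matrix contains missing values")
  if (is.null(hours)) {
    hours <- suppressWarnings(as.numeric(colnames(values)))
  }
  if (!anyNA(hours)) {
    if (length(hours) != ncol(values)) abort("`hours` must have one entry per column")
    if (any(diff(hours) <= 0)) abort("time points must be strictly increasing")
  } else {
    hours <- rep(NA_real_, ncol(values))
  }
  structure(list(species = species, values = values, hours = hours),
            class = "expr_timecourse")
}

#' @export
print.expr_timecourse <- function(x, ...) {
  cat(sprintf("<expr_timecourse> %s: %d genes x %d time points [%s ... %s]\n",
              x$species, nrow(x$values), ncol(x$values),
              colnames(x$values)[1], colnames(x$values)[ncol(x$values)]))
  invisible(x)
}

#' @export
dim.expr_timecourse <- function(x) dim(x$values)

#' Presence/absence call table
#'
#' A genes-by-time-points logical matrix marking whether each gene is
#' called expressed ("present") at each time point.
#'
#' @param matrix Logical matrix with gene rownames and time-point colnames.
#' @param species Species identifier string.
#' @return An object of class `presence_table`.
#' @export
presence_table <- function(matrix, species = "unknown") {
  matrix <- as.matrix(matrix)
  if (!is.logical(matrix)) abort("presence matrix must be logical")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    abort("presence matrix needs unique row names (gene ids)")
  }
  if (anyNA(matrix)) abort("presence matrix contains missing values")
  structure(list(species = species, matrix = matrix), class = "presence_table")
}

#' @export
print.presence_table <- function(x, ...) {
  cat(sprintf("<presence_table> %s: %d genes x %d time points (%.1f%% present)\n",
              x$species, nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix)))
  invisible(x)
}

#' Probe-level table
#'
#' Probe-by-sample values (intensities or detection flags) together with the
#' probe-to-gene map and the (time point, replicate) identity of each sample
#' column. Sample columns are labelled `T<label>_r<k>`.
#'
#' @param values Matrix (numeric or logical), rows = probes, columns = samples.
#' @param probe_to_gene Named character vector mapping probe id to gene id;
#'   probes missing from the map are treated as unmapped and dropped (with a
#'   count) by downstream summarisation.
#' @param sample_info Optional data frame with columns `sample`, `time`,
#'   `replicate`. If `NULL` it is parsed from the column names.
#' @return An object of class `probe_table`.
#' @export
probe_table <- function(values, probe_to_gene, sample_info = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) abort("probe matrix needs probe ids as row names")
  if (is.null(sample_info)) {
    sample_info <- parse_sample_labels(colnames(values))
  } else {
    sample_info <- as_tibble(sample_info)
    if (!all(c("sample", "time", "replicate") %in% names(sample_info))) {
      abort("`sample_info` needs columns sample, time, replicate")
    }
  }
  missing_cols <- setdiff(colnames(values), sample_info$sample)
  if (length(missing_cols) > 0) {
    abort(sprintf("sample column(s) without a (time, replicate) mapping: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(names(probe_to_gene))) abort("a probe maps to more than one gene")
  structure(list(values = values, probe_to_gene = probe_to_gene,
                 sample_info = sample_info),
            class = "probe_table")
}

parse_sample_labels <- function(labels) {
  if (is.null(labels)) abort("probe matrix needs sample column names")
  m <- regmatches(labels, regexec("^T(.+)_r([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("sample label(s) not of the form T<label>_r<k>: %s",
                  paste(labels[bad], collapse = ", ")))
  }
  tibble(sample = labels,
         time = vapply(m, `[`, "", 2L),
         replicate = as.integer(vapply(m, `[`, "", 3L)))
}

#' Ortholog pair map
#'
#' Unique one-to-one "seed ortholog" pairs between two species.
#'
#' @param pairs Data frame with columns `gene_a` and `gene_b`; duplicate
#'   pairs are collapsed with a message.
#' @param species_a,species_b Species identifier strings.
#' @return A tibble of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs, species_a = "A", species_b = "B") {
  pairs <- as_tibble(pairs)
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    abort("`pairs` must have columns `gene_a` and `gene_b`.")
  }
  pairs <- pairs[, c("gene_a", "gene_b")]
  if (any(pairs$gene_a == "") || any(pairs$gene_b == "")) abort("empty gene id in ortholog pair")
  n0 <- nrow(pairs)
  pairs <- distinct(pairs)
  if (nrow(pairs) < n0) {
    inform(sprintf("dropped %d duplicate ortholog pair(s)", n0 - nrow(pairs)))
  }
  structure(pairs, species_a = species_a, species_b = species_b,
            class = c("ortholog_map", class(pairs)))
}

#' Cross-species time-point alignment
#'
#' An ordered set of comparable ("common") time points between two species'
#' time courses: a monotone list of (label A, label B) pairs.
#'
#' @param pairs Data frame with columns `label_a` and `label_b` (time-point
#'   labels as they appear in the respective expression tables).
#' @param species_a,species_b Species identifier strings.
#' @return A tibble of class `time_alignment`.
#' @export
time_alignment <- function(pairs, species_a = "A", species_b = "B") {
  pairs <- as_tibble(pairs)
  if (!all(c("label_a", "label_b") %in% names(pairs))) {
    abort("`pairs` must have columns `label_a` and `label_b`.")
  }
  pairs <- pairs[, c("label_a", "label_b")]
  pairs$label_a <- as.character(pairs$label_a)
  pairs$label_b <- as.character(pairs$label_b)
  if (nrow(pairs) < 1) abort("alignment is empty")
  if (anyDuplicated(pairs$label_a) || anyDuplicated(pairs$label_b)) {
    abort("alignment labels must be unique in each species")
  }
  # monotonicity can only be checked here when labels are numeric; label
  # order against an actual time course is re-checked on use
  ha <- suppressWarnings(as.numeric(pairs$label_a))
  hb <- suppressWarnings(as.numeric(pairs$label_b))
  if (!anyNA(ha) && any(diff(ha) <= 0)) abort("alignment not monotone in species A")
  if (!anyNA(hb) && any(diff(hb) <= 0)) abort("alignment not monotone in species B")
  structure(pairs, species_a = species_a, species_b = species_b,
            class = c("time_alignment", class(pairs)))
}
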