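#' Read a DBD-style TF family assignment file
#'
#' Parses the tab-delimited `.tf.ass` dialect: one row per
#' (gene id, domain family) assignment, `#` starting a comment line.
#' Multi-domain genes accumulate all their family labels; duplicate rows
#' collapse under set semantics. Family labels outside the canonical six
#' (Homeobox, zf-C2H2, zf-C4, Ets, bZIP, HLH) are kept verbatim.
#'
#' @param path Path to the assignment file.
#' @param species Species identifier recorded on the catalog.
#' @return A [tf_catalog].
#' @export
read_tf_assignments <- function(path, species = "unknown") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) abort(sprintf("no assignments in '%s'", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[nf != 2L][1]
    abort(sprintf("malformed row at line %d of '%s': expected 2 tab-separated fields",
                  bad, path))
  }
  tf_catalog(tibble(gene = vapply(fields, `[`, "", 1L),
                    family = vapply(fields, `[`, "", 2L)),
             species = species)
}

#' Read / write an expression table
#'
#' TSV dialect: first column `gene_id`, one column per time point, header
#' row carrying the time labels.
#'
#' @param path File path.
#' @param species Species identifier.
#' @return [read_expression_table()] returns an [expr_timecourse].
#' @export
read_expression_table <- function(path, species = "unknown") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") abort(sprintf("'%s': first column must be 'gene_id'", path))
  if (ncol(df) < 2) abort(sprintf("'%s': no time-point columns", path))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort(sprintf("'%s': non-numeric expression values", path))
  rownames(vals) <- df$gene_id
  expr_timecourse(vals, species = species)
}

#' @param x An [expr_timecourse].
#' @rdname read_expression_table
#' @export
write_expression_table <- function(x, path) {
  df <- as.data.frame(x$values)
  df <- cbind(gene_id = rownames(x$values), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read / write an ortholog pair table
#'
#' TSV with two columns `gene_a<TAB>gene_b` (a reduced "seed ortholog"
#' projection of an InParanoid-style table). Duplicate pairs are collapsed
#' with a message.
#'
#' @param path File path.
#' @param species_a,species_b Species identifiers.
#' @return [read_ortholog_table()] returns an [ortholog_map].
#' @export
read_ortholog_table <- function(path, species_a = "A", species_b = "B") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) abort(sprintf("'%s' is empty", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[nf != 2L][1]
    abort(sprintf("malformed row at line %d of '%s': expected 2 tab-separated fields",
                  bad, path))
  }
  ortholog_map(tibble(gene_a = vapply(fields, `[`, "", 1L),
                      gene_b = vapply(fields, `[`, "", 2L)),
               species_a = species_a, species_b = species_b)
}

#' @param om An [ortholog_map].
#' @rdname read_ortholog_table
#' @export
write_ortholog_table <- function(om, path) {
  writeLines(paste(om$gene_a, om$gene_b, sep = "\t"), path)
  invisible(path)
}

#' Read / write a time-point alignment table
#'
#' TSV with two columns `time_label_a<TAB>time_label_b`. Non-monotone
#' alignments (judged on numeric labels) are rejected.
#'
#' @param path File path.
#' @param species_a,species_b Species identifiers.
#' @return [read_alignment()] returns a [time_alignment].
#' @export
read_alignment <- function(path, species_a = "A", species_b = "B") {
  lines <- readLines(path)
  idx <- which(nzchar(trimws(lines)))
  if (length(idx) == 0L) abort(sprintf("'%s' is empty", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[nf != 2L][1]
    abort(sprintf("malformed row at line %d of '%s': expected 2 tab-separated fields",
                  bad, path))
  }
  time_alignment(tibble(label_a = vapply(fields, `[`, "", 1L),
                        label_b = vapply(fields, `[`, "", 2L)),
                 species_a = species_a, species_b = species_b)
}

#' @param al A [time_alignment].
#' @rdname read_alignment
#' @export
write_alignment <- function(al, path) {
  writeLines(paste(al$label_a, al$label_b, sep = "\t"), path)
  invisible(path)
}

#' @rdname read_tf_assignments
#' @param cat A [tf_catalog].
#' @export
write_tf_assignments <- function(cat, path) {
  writeLines(paste(cat$gene, cat$family, sep = "\t"), path)
  invisible(path)
}

#' Read / write a presence table
#'
#' TSV dialect matching the expression table: `gene_id` plus one 0/1 column
#' per time point.
#'
#' @param path File path.
#' @param species Species identifier.
#' @export
read_presence_table <- function(path, species = "unknown") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") abort(sprintf("'%s': first column must be 'gene_id'", path))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!all(vals %in% c(0, 1))) abort(sprintf("'%s': presence values must be 0/1", path))
  m <- vals > 0
  rownames(m) <- df$gene_id
  presence_table(m, species = species)
}

#' @param p A [presence_table].
#' @rdname read_presence_table
#' @export
write_presence_table <- function(p, path) {
  df <- as.data.frame(1L * p$matrix)
  df <- cbind(gene_id = rownames(p$matrix), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}
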