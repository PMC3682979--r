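#' Ontology DAG with gene annotations
#'
#' A directed acyclic graph of ontology terms (edges child -> parent,
#' is_a/part_of collapsed) plus direct gene-to-term annotations.
#'
#' @param edges Data frame with columns `child` and `parent` (term ids), or
#'   `NULL`/zero rows for a flat ontology.
#' @param annotations Data frame with columns `gene` and `term` (direct
#'   annotations).
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(edges, annotations) {
  edges <- if (is.null(edges)) tibble(child = character(), parent = character())
           else as_tibble(edges)[, c("child", "parent")]
  annotations <- as_tibble(annotations)[, c("gene", "term")]
  terms <- sort(unique(c(edges$child, edges$parent, annotations$term)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) abort("ontology graph contains a cycle")
  structure(list(edges = edges, annotations = distinct(annotations),
                 graph = g, terms = terms),
            class = "ontology_dag")
}

#' Read an ontology edge list and annotation table
#'
#' Edge list: TSV `child<TAB>parent`; annotations: TSV `gene<TAB>term`.
#'
#' @param edges_path,annotations_path File paths.
#' @return An [ontology_dag].
#' @export
read_ontology <- function(edges_path, annotations_path) {
  read2 <- function(path, names) {
    lines <- readLines(path)
    idx <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 2L)) {
      abort(sprintf("malformed row at line %d of '%s'", idx[nf != 2L][1], path))
    }
    stats::setNames(tibble(vapply(fields, `[`, "", 1L),
                           vapply(fields, `[`, "", 2L)), names)
  }
  ontology_dag(read2(edges_path, c("child", "parent")),
               read2(annotations_path, c("gene", "term")))
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Each term's gene set becomes its direct annotations plus the direct
#' annotations of all its descendants. Idempotent.
#'
#' @param d An [ontology_dag].
#' @return A named list: term id -> character vector of genes.
#' @export
propagate_annotations <- function(d) {
  stopifnot(inherits(d, "ontology_dag"))
  direct <- split(d$annotations$gene, d$annotations$term)
  out <- lapply(stats::setNames(d$terms, d$terms), function(tm) {
    below <- names(igraph::subcomponent(d$graph, tm, mode = "in"))
    sort(unique(unlist(direct[below], use.names = FALSE)))
  })
  out[vapply(out, is.null, TRUE)] <- list(character(0))
  out
}

#' Classic hypergeometric term enrichment
#'
#' Tests every term (with propagated annotations) for over-representation
#' of a study gene set against a background, via the one-sided
#' hypergeometric tail. Terms with no study gene or with fewer than
#' `min_annotated` annotated background genes are skipped.
#'
#' @param d An [ontology_dag].
#' @param study Character vector of study genes (must be within `background`).
#' @param background Character vector of background genes.
#' @param alpha Significance level (default 0.01).
#' @param min_annotated Minimum annotated background genes per tested term
#'   (default 3).
#' @return A tibble with columns `term`, `k`, `n`, `K`, `N`, `p`,
#'   `significant`, `algorithm`.
#' @export
classic_enrichment <- function(d, study, background, alpha = 0.01, min_annotated = 3) {
  study <- unique(study); background <- unique(background)
  if (length(study) == 0) abort("empty study set")
  if (!all(study %in% background)) abort("study genes must be a subset of the background")
  prop <- propagate_annotations(d)
  enrich_table(prop, study, background, alpha, min_annotated, "classic")
}

enrich_table <- function(prop, study, background, alpha, min_annotated, algorithm) {
  rows <- purrr::map_dfr(names(prop), function(tm) {
    ann_bg <- intersect(prop[[tm]], background)
    k <- length(intersect(ann_bg, study))
    tibble(term = tm, k = k, n = length(study), K = length(ann_bg),
           N = length(background))
  })
  rows <- rows[rows$k >= 1 & rows$K >= min_annotated, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(tibble(term = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), p = numeric(),
                  significant = logical(), algorithm = character()))
  }
  rows$p <- hypergeometric_overlap(rows$k, rows$n, rows$K, rows$N)$p_over
  rows$significant <- rows$p < alpha
  rows$algorithm <- algorithm
  arrange(rows, .data$p)
}

#' Term enrichment with hierarchy decorrelation (elim)
#'
#' Processes terms bottom-up (deepest DAG level first, longest path from a
#' root; ties in term-id order). Whenever a term is significant at `alpha`,
#' its annotated study genes are eliminated from the annotation sets of all
#' its ancestors before those are tested, so enrichment signal concentrated
#' in a specific term does not echo up the hierarchy. Both the classic and
#' the elim p-value are reported for every tested term.
#'
#' @inheritParams classic_enrichment
#' @return A tibble with columns `term`, `level`, `k`, `n`, `K`, `N`,
#'   `p_classic`, `p_elim`, `significant` (elim at `alpha`), `algorithm`.
#' @export
elim_enrichment <- function(d, study, background, alpha = 0.01, min_annotated = 3) {
  study <- unique(study); background <- unique(background)
  if (length(study) == 0) abort("empty study set")
  if (!all(study %in% background)) abort("study genes must be a subset of the background")
  prop <- propagate_annotations(d)
  classic <- enrich_table(prop, study, background, alpha, min_annotated, "classic")
  # depth = longest path from any root (term with no parent)
  topo <- rev(names(igraph::topo_sort(d$graph, mode = "out")))  # parents first
  level <- stats::setNames(rep(0L, length(d$terms)), d$terms)
  for (tm in topo) {
    parents <- names(igraph::neighbors(d$graph, tm, mode = "out"))
    if (length(parents)) level[tm] <- max(level[parents]) + 1L
  }
  ord <- d$terms[order(-level[d$terms], d$terms)]
  eliminated <- stats::setNames(vector("list", length(d$terms)), d$terms)
  N <- length(background); n <- length(study)
  rows <- list()
  for (tm in ord) {
    ann_bg <- setdiff(intersect(prop[[tm]], background), eliminated[[tm]])
    k <- length(intersect(ann_bg, study))
    K <- length(ann_bg)
    if (k < 1 || K < min_annotated) next
    p <- hypergeometric_overlap(k, n, K, N)$p_over
    rows[[tm]] <- tibble(term = tm, level = unname(level[tm]),
                         k = k, n = n, K = K, N = N, p_elim = p)
    if (p < alpha) {
      anc <- setdiff(names(igraph::subcomponent(d$graph, tm, mode = "out")), tm)
      drop_genes <- intersect(ann_bg, study)
      for (a in anc) eliminated[[a]] <- union(eliminated[[a]], drop_genes)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(term = character(), level = integer(), k = integer(),
                  n = integer(), K = integer(), N = integer(),
                  p_classic = numeric(), p_elim = numeric(),
                  significant = logical(), algorithm = character()))
  }
  out <- left_join(out, classic %>% select("term", p_classic = "p"), by = "term")
  out$significant <- out$p_elim < alpha
  out$algorithm <- "elim"
  arrange(select(out, "term", "level", "k", "n", "K", "N",
                 "p_classic", "p_elim", "significant", "algorithm"),
          .data$p_elim)
}
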