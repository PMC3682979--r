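#' Cross-species transcriptome distance for every pair of time points
#'
#' For each time point `s` of species A and `t` of species B, computes the
#' Euclidean distance between the two species' ortholog expression vectors:
#' `D[s, t] = sqrt(sum over ortholog pairs (zA[gene_a, s] - zB[gene_b, t])^2)`,
#' where each gene is Z-normalized over its *own* species' full time course.
#' The full matrix over all time points of both species is returned (not
#' restricted to aligned points); its minimum locates the developmental
#' stages at which the two TF transcriptomes are most similar.
#'
#' @param xa,xb [expr_timecourse] objects (filtered as for clustering).
#'   Values are Z-normalized internally unless `normalize = FALSE`.
#' @param om An [ortholog_map]; only pairs with both genes present in both
#'   time courses are used (at least 2 required).
#' @param normalize Z-normalize rows first (default TRUE).
#' @return An object of class `stage_distance`: list with `matrix`
#'   (|T_A| x |T_B|), `n_orthologs`, `argmin` (tibble with the minimizing
#'   time labels and value), `species_a`, `species_b`.
#' @export
stage_distance_matrix <- function(xa, xb, om, normalize = TRUE) {
  stopifnot(inherits(xa, "expr_timecourse"), inherits(xb, "expr_timecourse"))
  if (normalize) {
    xa <- z_normalize(xa); xb <- z_normalize(xb)
  }
  keep <- om$gene_a %in% rownames(xa$values) & om$gene_b %in% rownames(xb$values)
  if (sum(keep) < 2) abort("fewer than 2 usable ortholog pairs")
  A <- xa$values[om$gene_a[keep], , drop = FALSE]  # pairs x T_A
  B <- xb$values[om$gene_b[keep], , drop = FALSE]  # pairs x T_B
  d2 <- outer(colSums(A^2), colSums(B^2), `+`) - 2 * crossprod(A, B)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  dimnames(D) <- list(colnames(xa$values), colnames(xb$values))
  am <- arrayInd(which.min(D), dim(D))
  structure(list(matrix = D, n_orthologs = sum(keep),
                 argmin = tibble(time_a = rownames(D)[am[1]],
                                 time_b = colnames(D)[am[2]],
                                 index_a = am[1], index_b = am[2],
                                 distance = D[am]),
                 species_a = xa$species, species_b = xb$species),
            class = "stage_distance")
}

#' @export
print.stage_distance <- function(x, ...) {
  cat(sprintf("<stage_distance> %s x %s: %d x %d time points over %d ortholog pairs\n",
              x$species_a, x$species_b, nrow(x$matrix), ncol(x$matrix), x$n_orthologs))
  cat(sprintf("  most similar at %s = %s, %s = %s (distance %.4g)\n",
              x$species_a, x$argmin$time_a, x$species_b, x$argmin$time_b,
              x$argmin$distance))
  invisible(x)
}

#' Minimum-distance profile along one species' time axis
#'
#' For each time point of the chosen species, the minimum transcriptome
#' distance to any time point of the other species — the profile used to
#' read off hourglass-like convergence.
#'
#' @param D A [stage_distance_matrix()] result.
#' @param axis `"a"` (default, rows) or `"b"` (columns).
#' @return A tibble of class `min_distance_profile` with columns `time`,
#'   `min_distance`, `argmin_time` (the closest time point of the other
#'   species) and `index`.
#' @export
min_distance_profile <- function(D, axis = c("a", "b")) {
  stopifnot(inherits(D, "stage_distance"))
  axis <- match.arg(axis)
  M <- if (axis == "a") D$matrix else t(D$matrix)
  j <- apply(M, 1, which.min)
  out <- tibble(time = rownames(M),
                min_distance = M[cbind(seq_len(nrow(M)), j)],
                argmin_time = colnames(M)[j],
                index = seq_len(nrow(M)))
  structure(out, axis = axis,
            species = if (axis == "a") D$species_a else D$species_b,
            class = c("min_distance_profile", class(out)))
}

#' Local minima of a distance profile
#'
#' Finds strict interior local minima (values strictly below both
#' neighbours); boundary minima (an endpoint below its single neighbour)
#' are reported too but flagged as such.
#'
#' @param profile A [min_distance_profile()] result or a numeric vector of
#'   length at least 3.
#' @return A tibble with columns `index`, `value`, `boundary`.
#' @export
local_minima <- function(profile) {
  v <- if (inherits(profile, "min_distance_profile")) profile$min_distance
       else as.numeric(profile)
  n <- length(v)
  if (n < 3) abort("profile must have at least 3 points")
  interior <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n]) + 1L
  bound <- c(if (v[1] < v[2]) 1L, if (v[n] < v[n - 1]) n)
  tibble(index = c(interior, bound),
         value = v[c(interior, bound)],
         boundary = c(rep(FALSE, length(interior)), rep(TRUE, length(bound)))) %>%
    arrange(.data$index)
}
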