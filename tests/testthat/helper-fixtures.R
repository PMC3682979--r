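# shared fixture builders: everything is generated in code at test time

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# cluster assignment taken straight from the generator's planted labels
truth_assignment <- function(sim, species = c("a", "b")) {
  species <- match.arg(species)
  tg <- sim$truth$genes[sim$truth$genes$species == toupper(species), ]
  out <- tibble::tibble(
    gene = tg$gene,
    cluster = ifelse(is.na(tg$archetype), NA_character_,
                     paste0("C", tg$archetype)),
    membership = ifelse(is.na(tg$archetype), 0.5, 1))
  structure(out, threshold = 0.8,
            class = c("cluster_assignment", class(out)))
}

# pairing of the planted archetypes themselves (identity correspondence)
truth_pairing <- function(sim) {
  k <- sim$truth$config$n_clusters
  ca <- sim$archetypes$a
  cb <- sim$archetypes$b
  rownames(ca) <- rownames(cb) <- paste0("C", seq_len(k))
  colnames(ca) <- as.character(sim$truth$config$hours_a)
  colnames(cb) <- as.character(sim$truth$config$hours_b)
  r <- restrict_to_alignment(ca, cb, sim$alignment)
  quiet(pair_clusters(r$a, r$b))
}

# filter + z + cluster + assign one species of a simulation
cluster_species <- function(sim, species = c("a", "b"), seed, ...) {
  species <- match.arg(species)
  x <- sim[[species]]
  filtered <- quiet(filter_for_clustering(x$expr, x$presence))
  fit <- fuzzy_cmeans(z_normalize(filtered),
                      c = sim$truth$config$n_clusters, m = 1.25,
                      seed = seed, ...)
  list(filtered = filtered, fit = fit, assignment = assign_members(fit))
}

# majority planted archetype of each recovered cluster
cluster_archetype_map <- function(sim, species, assignment) {
  tg <- sim$truth$genes[sim$truth$genes$species == toupper(species), ]
  asg <- assignment[!is.na(assignment$cluster), ]
  vapply(split(asg$gene, asg$cluster), function(g) {
    names(which.max(table(tg$archetype[match(g, tg$gene)])))
  }, "")
}

# hypergeometric upper/lower tails by direct summation of choose() terms,
# independent of phyper()
enum_hyper <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  mass <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  list(p_over = sum(mass[support >= k]), p_under = sum(mass[support <= k]))
}

# two-sided Fisher p for a 2x2 table by enumerating all tables with the
# observed margins
enum_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  mass <- choose(c1, support) * choose(N - c1, r1 - support) / choose(N, r1)
  obs <- mass[support == tab[1, 1]]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

small_expr <- function(values, genes = NULL, times = NULL, species = "sp") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(times)) times <- as.character(seq_len(ncol(values)))
  dimnames(values) <- list(genes, times)
  expr_timecourse(values, species = species)
}

small_presence <- function(values, genes = NULL, times = NULL, species = "sp") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(times)) times <- as.character(seq_len(ncol(values)))
  dimnames(values) <- list(genes, times)
  presence_table(values > 0 & values, species = species)
}
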