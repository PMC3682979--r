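#' Simulation configuration for a two-species developmental time course
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults describe the study conditions used throughout the package's
#' validation: 700 TFs per species on 12-point time courses, 7 shared
#' temporal archetypes, log2-scale Gaussian noise of sd 0.3, 10% of genes
#' near-constant and 5% never expressed, 300 ortholog pairs of which half
#' are planted concordant, and a 5-fold family enrichment planted in one
#' archetype.
#'
#' @param n_genes Genes per species.
#' @param n_clusters Number of temporal archetypes (shared across species).
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param frac_never Fraction of genes never expressed (values kept below
#'   the presence floor at every time point).
#' @param frac_constant Fraction of genes with near-constant expression
#'   (flat mean, noise sd `min(noise_sd/3, 0.15)` so the log2 range stays
#'   below the constant-expression filter).
#' @param n_orthologs Number of ortholog pairs (drawn among clustered genes).
#' @param concordance Fraction of ortholog pairs planted to share an
#'   archetype (the rest get independent archetypes).
#' @param hours_a,hours_b Time grids (hours) for the two species; equal
#'   length when `alignment_pairs` is `NULL` (complete alignment).
#' @param alignment_pairs Optional data frame `label_a`/`label_b` of
#'   aligned time labels; defaults to the complete point-by-point alignment.
#' @param family_freqs Named vector of TF-family frequencies (sums to 1).
#' @param second_family_prob Probability a gene carries a second family
#'   label (domain assignments are many-to-many).
#' @param enriched_family,enriched_cluster,enrichment_odds A family whose
#'   sampling odds are multiplied by `enrichment_odds` for genes of
#'   archetype `enriched_cluster` (set odds to 1 for no planted enrichment).
#' @param amplitude_range Range of per-gene archetype amplitudes (log2).
#' @param baseline_mean,baseline_sd Per-gene baseline expression (log2).
#' @param never_level Mean level of never-expressed genes (log2).
#' @param presence_floor Expression floor used to derive presence calls.
#' @param hourglass_windows `NULL`, or a list of `c(lo, hi)` intervals in
#'   normalized aligned time (0 = start, 1 = end) within which the two
#'   species' expression converges; away from the windows every gene
#'   receives independent species-specific divergence noise.
#' @param divergence_sd Sd of the divergence noise (log2) at full ramp,
#'   active only with `hourglass_windows`.
#' @param window_ramp Normalized-time distance over which divergence ramps
#'   from 0 (inside a window) to its full size.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 700,
                       n_clusters = 7,
                       noise_sd = 0.3,
                       frac_never = 0.05,
                       frac_constant = 0.10,
                       n_orthologs = 300,
                       concordance = 0.5,
                       hours_a = seq(0, 22, by = 2),
                       hours_b = c(2, 6, 10, 16, 19, 22, 28.5, 31, 34, 40, 43, 49),
                       alignment_pairs = NULL,
                       family_freqs = c("zf-C2H2" = 0.24, "Homeobox" = 0.20,
                                        "HLH" = 0.08, "bZIP" = 0.07,
                                        "zf-C4" = 0.05, "Ets" = 0.04,
                                        "other" = 0.32),
                       second_family_prob = 0.1,
                       enriched_family = "zf-C2H2",
                       enriched_cluster = 1,
                       enrichment_odds = 5,
                       amplitude_range = c(1.5, 2.5),
                       baseline_mean = 6, baseline_sd = 1,
                       never_level = -2,
                       presence_floor = 1,
                       hourglass_windows = NULL,
                       divergence_sd = 1,
                       window_ramp = 0.15) {
  if (concordance < 0 || concordance > 1) abort("`concordance` must be in [0, 1]")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (frac_never < 0 || frac_constant < 0 || frac_never + frac_constant >= 1) {
    abort("never/constant fractions must be >= 0 and sum to < 1")
  }
  if (any(diff(hours_a) <= 0) || any(diff(hours_b) <= 0)) {
    abort("time grids must be strictly increasing")
  }
  if (is.null(alignment_pairs)) {
    if (length(hours_a) != length(hours_b)) {
      abort("complete alignment requires equally long time grids; pass `alignment_pairs`")
    }
    alignment_pairs <- tibble(label_a = as.character(hours_a),
                              label_b = as.character(hours_b))
  } else {
    alignment_pairs <- as_tibble(alignment_pairs)[, c("label_a", "label_b")]
  }
  if (abs(sum(family_freqs) - 1) > 1e-8) abort("`family_freqs` must sum to 1")
  if (!is.null(hourglass_windows)) {
    ok <- vapply(hourglass_windows, function(w)
      length(w) == 2 && w[1] < w[2] && w[1] >= 0 && w[2] <= 1, TRUE)
    if (!all(ok)) abort("each hourglass window must be c(lo, hi) within [0, 1]")
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic library of smooth temporal shapes on [0, 1]; parameters are
# jittered from the active RNG stream so distinct seeds give distinct curves
archetype_shape_functions <- function(k) {
  jit <- function(x, f = 0.12) x * runif(1, 1 - f, 1 + f)
  base <- list(
    `maternal-decay` = function() {
      tau <- jit(0.18); function(s) exp(-s / tau)
    },
    `activated-sustained` = function() {
      s0 <- jit(0.35); sc <- jit(0.07); function(s) stats::plogis((s - s0) / sc)
    },
    `activated-transient` = function() {
      s0 <- jit(0.5); w <- jit(0.015); function(s) exp(-(s - s0)^2 / (2 * w))
    },
    `late-rise` = function() {
      s0 <- jit(0.78); sc <- jit(0.06); function(s) stats::plogis((s - s0) / sc)
    },
    `maternal-late-decay` = function() {
      s0 <- jit(0.55); sc <- jit(0.09)
      function(s) 1 - stats::plogis((s - s0) / sc)
    },
    `early-transient` = function() {
      s0 <- jit(0.22); w <- jit(0.012); function(s) exp(-(s - s0)^2 / (2 * w))
    },
    `high-low-high` = function() {
      ph <- jit(1, 0.05); function(s) cos(2 * pi * s * ph)
    }
  )
  out <- vector("list", k)
  nm <- character(k)
  for (i in seq_len(k)) {
    if (i <= length(base)) {
      out[[i]] <- base[[i]]()
      nm[i] <- names(base)[i]
    } else {
      # extra shapes: low-frequency random Fourier curves
      f <- sample(1:3, 1); ph <- runif(1, 0, 2 * pi); f2 <- sample(1:3, 1)
      a2 <- runif(1, 0.2, 0.6)
      out[[i]] <- local({
        f <- f; ph <- ph; f2 <- f2; a2 <- a2
        function(s) sin(2 * pi * f * s + ph) + a2 * cos(2 * pi * f2 * s)
      })
      nm[i] <- sprintf("fourier-%d", i)
    }
  }
  names(out) <- make.unique(nm)
  out
}

standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  (m - mu) / sdp
}

#' Temporal archetype curves
#'
#' Generates `k` unit-variance temporal shapes on a `T`-point grid:
#' monotone maternal decays, sigmoidal activation, transient pulses, a late
#' rise and, beyond seven, low-frequency Fourier curves. Each curve has
#' mean 0 and (population) sd 1 across time points, and curves are mutually
#' separated in Euclidean distance by at least `min_separation`.
#'
#' @param k Number of archetypes (>= 2).
#' @param T Number of time points (>= 4 and >= k).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param min_separation Required minimum pairwise Euclidean distance
#'   (default 1).
#' @return A list of class `archetype_set` with `curves` (k x T matrix) and
#'   `labels`.
#' @export
make_archetypes <- function(k, T, seed = 1, min_separation = 1) {
  if (k < 2) abort("`k` must be >= 2")
  if (T < 4) abort("`T` must be >= 4")
  if (k > T) abort("more archetypes than time points: shapes undersampled")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  s <- seq(0, 1, length.out = T)
  for (attempt in 1:25) {
    fns <- archetype_shape_functions(k)
    curves <- standardize_rows(t(vapply(fns, function(f) f(s), numeric(T))))
    if (min(dist(curves)) >= min_separation) {
      colnames(curves) <- as.character(seq_len(T))
      return(structure(list(curves = curves, labels = names(fns)),
                       class = "archetype_set"))
    }
  }
  abort("could not generate sufficiently separated archetypes")
}

window_divergence_weight <- function(s, windows, ramp) {
  if (is.null(windows)) return(rep(0, length(s)))
  per <- vapply(windows, function(w) {
    d <- pmax(0, pmax(w[1] - s, s - w[2]))
    pmin(1, d / ramp)
  }, numeric(length(s)))
  apply(matrix(per, nrow = length(s)), 1, min)
}

#' Simulate a two-species developmental expression data set
#'
#' Generates expression time courses for two species built from shared
#' temporal archetypes, with a species-specific time warp (piecewise linear
#' through the configured alignment pairs), i.i.d. Gaussian noise on the
#' log2 scale, planted never-expressed and near-constant genes, TF-family
#' labels with a planted family-by-archetype enrichment, ortholog pairs
#' with a planted concordance fraction, presence calls derived from an
#' expression floor, and (optionally) hourglass-style convergence windows
#' outside which the two species' profiles diverge.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is deterministic given config + seed.
#' @return A list of class `species_pair_sim` with elements `a` and `b`
#'   (each `expr`, `presence`, `catalog`), `orthologs`, `alignment`,
#'   `archetypes` (per-species curve matrices and labels) and `truth`
#'   (`genes`: per-gene status/archetype tibble; `orthologs`: planted
#'   concordance flags; `enrichment`: the planted family-by-archetype
#'   table; `config`).
#' @export
simulate_species_pair <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  k <- cfg$n_clusters
  fns <- archetype_shape_functions(k)

  # normalized developmental position for each species: warp B's hours onto
  # A's clock through the alignment pairs, then rescale A's clock to [0, 1]
  ha_al <- as.numeric(cfg$alignment_pairs$label_a)
  hb_al <- as.numeric(cfg$alignment_pairs$label_b)
  warp_b_to_a <- function(h) stats::approx(hb_al, ha_al, xout = h, rule = 2)$y
  norm_a <- function(h) (h - min(cfg$hours_a)) / diff(range(cfg$hours_a))
  s_a <- norm_a(cfg$hours_a)
  s_b <- norm_a(warp_b_to_a(cfg$hours_b))

  arch <- lapply(list(a = s_a, b = s_b), function(s) {
    m <- standardize_rows(t(vapply(fns, function(f) f(s), numeric(length(s)))))
    rownames(m) <- names(fns)
    m
  })

  n <- cfg$n_genes
  n_never <- round(cfg$frac_never * n)
  n_const <- round(cfg$frac_constant * n)
  n_clustered <- n - n_never - n_const

  sim_species <- function(prefix, s_grid, arch_m, hours, archetype_override = NULL) {
    genes <- sprintf("%s%04d", prefix, seq_len(n))
    status <- c(rep("clustered", n_clustered), rep("constant", n_const),
                rep("never", n_never))
    archetype <- ifelse(status == "clustered",
                        sample.int(k, n, replace = TRUE), NA_integer_)
    if (!is.null(archetype_override)) {
      archetype[seq_along(archetype_override)] <-
        ifelse(is.na(archetype_override),
               archetype[seq_along(archetype_override)], archetype_override)
    }
    T <- length(s_grid)
    w <- window_divergence_weight(s_grid, cfg$hourglass_windows, cfg$window_ramp)
    vals <- matrix(0, n, T, dimnames = list(genes, as.character(hours)))
    amp <- runif(n, cfg$amplitude_range[1], cfg$amplitude_range[2])
    base <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    sd_const <- min(cfg$noise_sd / 3, 0.15)
    # species-specific divergence: independent noise whose sd ramps from 0
    # inside a convergence window to `divergence_sd` away from it
    div_noise <- function() {
      if (is.null(cfg$hourglass_windows)) 0 else
        w * rnorm(T, 0, cfg$divergence_sd)
    }
    for (i in seq_len(n)) {
      vals[i, ] <- switch(status[i],
        clustered = base[i] + amp[i] * arch_m[archetype[i], ] + div_noise() +
          rnorm(T, 0, cfg$noise_sd),
        constant = base[i] + rnorm(T, 0, sd_const),
        never = cfg$never_level + rnorm(T, 0, cfg$noise_sd))
    }
    list(genes = genes, status = status, archetype = archetype, values = vals)
  }

  # ortholog structure: pair clustered genes; the first round(concordance *
  # n_orthologs) pairs share A's archetype, the rest keep B's own draw
  if (cfg$n_orthologs > n_clustered) abort("more ortholog pairs than clustered genes")
  sp_a <- sim_species("A", s_a, arch$a, cfg$hours_a)
  idx_orth <- sample(which(sp_a$status == "clustered"), cfg$n_orthologs)
  n_conc <- round(cfg$concordance * cfg$n_orthologs)
  override <- rep(NA_integer_, n)
  if (n_conc > 0) {
    override[idx_orth[seq_len(n_conc)]] <- sp_a$archetype[idx_orth[seq_len(n_conc)]]
  }
  sp_b <- sim_species("B", s_b, arch$b, cfg$hours_b, archetype_override = override)

  assign_families <- function(sp) {
    fam_names <- names(cfg$family_freqs)
    pick <- function(arch_id) {
      wts <- cfg$family_freqs
      if (!is.na(arch_id) && arch_id == cfg$enriched_cluster) {
        wts[cfg$enriched_family] <- wts[cfg$enriched_family] * cfg$enrichment_odds
      }
      sample(fam_names, 1, prob = wts)
    }
    first <- vapply(sp$archetype, pick, "")
    extra <- runif(n) < cfg$second_family_prob
    second <- ifelse(extra, vapply(seq_len(n), function(i) {
      others <- setdiff(fam_names, first[i])
      sample(others, 1, prob = cfg$family_freqs[others])
    }, ""), NA_character_)
    rows <- tibble(gene = c(sp$genes, sp$genes[extra]),
                   family = c(first, second[extra]))
    rows[order(rows$gene, rows$family), ]
  }
  fam_a <- assign_families(sp_a)
  fam_b <- assign_families(sp_b)

  mk_outputs <- function(sp, fam, species) {
    list(expr = expr_timecourse(sp$values, species = species),
         presence = presence_table(sp$values > cfg$presence_floor, species = species),
         catalog = tf_catalog(fam, species = species))
  }
  alignment <- time_alignment(cfg$alignment_pairs, species_a = "A", species_b = "B")
  orth <- ortholog_map(tibble(gene_a = sp_a$genes[idx_orth],
                              gene_b = sp_b$genes[idx_orth]),
                       species_a = "A", species_b = "B")
  truth_genes <- bind_rows(
    tibble(species = "A", gene = sp_a$genes, status = sp_a$status,
           archetype = sp_a$archetype),
    tibble(species = "B", gene = sp_b$genes, status = sp_b$status,
           archetype = sp_b$archetype))
  truth_orth <- tibble(gene_a = sp_a$genes[idx_orth],
                       gene_b = sp_b$genes[idx_orth],
                       concordant = seq_len(cfg$n_orthologs) <= n_conc)
  structure(list(
    a = mk_outputs(sp_a, fam_a, "A"),
    b = mk_outputs(sp_b, fam_b, "B"),
    orthologs = orth,
    alignment = alignment,
    archetypes = list(a = arch$a, b = arch$b, labels = names(fns)),
    truth = list(genes = truth_genes, orthologs = truth_orth,
                 enrichment = tibble(family = cfg$enriched_family,
                                     archetype = cfg$enriched_cluster,
                                     odds = cfg$enrichment_odds),
                 seed = seed, config = cfg)),
    class = "species_pair_sim")
}

#' @export
print.species_pair_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("<species_pair_sim> %d genes/species, %d archetypes, ",
                     "noise sd %.2g, %d ortholog pairs (%.0f%% concordant)\n"),
              cfg$n_genes, cfg$n_clusters, cfg$noise_sd, cfg$n_orthologs,
              100 * cfg$concordance))
  invisible(x)
}

#' Write a simulated data set in the pipeline's file formats
#'
#' Emits the full file set consumed by the readers: expression and presence
#' tables, TF family assignment files, the ortholog table, the alignment
#' table and `truth.json`.
#'
#' @param sim A [simulate_species_pair()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "species_pair_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$a$expr, file.path(dir, "expr_a.tsv"))
  write_expression_table(sim$b$expr, file.path(dir, "expr_b.tsv"))
  write_presence_table(sim$a$presence, file.path(dir, "presence_a.tsv"))
  write_presence_table(sim$b$presence, file.path(dir, "presence_b.tsv"))
  write_tf_assignments(sim$a$catalog, file.path(dir, "a.tf.ass"))
  write_tf_assignments(sim$b$catalog, file.path(dir, "b.tf.ass"))
  write_ortholog_table(sim$orthologs, file.path(dir, "orthologs.tsv"))
  write_alignment(sim$alignment, file.path(dir, "alignment.tsv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")
  invisible(dir)
}
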