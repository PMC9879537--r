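#' Configuration for the paired-species expression simulator
#'
#' The simulator emulates two bulk transcriptome atlases of species with
#' unmatched sample sets. Expression programs ("archetypes") are smooth
#' positive intensity curves over an abstract organ axis; each species
#' renders the axis into its own sample labels (different numbers of
#' labels stand in for unmatched morphologies), each label in independent
#' biological replicates. A conserved ortholog pair draws both genes'
#' intensities from the same archetype; a diverged pair from independent
#' archetypes. Read counts are negative-binomial around the intensities.
#'
#' @param n_genes_a,n_genes_b Genes per species.
#' @param n_sample_labels_a,n_sample_labels_b Sample labels (organs/
#'   stages) per species.
#' @param replicates_per_label Biological replicates per label.
#' @param conservation_rate Fraction of orthologous pairs sharing an
#'   archetype.
#' @param coexpressed_background_rate Chance that two random non-ortholog
#'   genes share an archetype; derived as `1 / n_archetypes` unless given,
#'   in which case it overrides the archetype count with its reciprocal.
#' @param n_archetypes Number of latent expression programs; the default
#'   30 corresponds to roughly one dominant program per major organ in an
#'   atlas of a few dozen sample labels.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size Expected total counts per sample.
#' @param ortho_fraction Fraction of each species' genes placed in
#'   orthogroups (the rest are unrelated background genes).
#' @param orthogroup_shape_mix Named probabilities over orthogroup shapes
#'   `"1x1"`, `"1x2"`, `"1x3"`, `"2x2"`.
#' @param seed Integer seed; simulations are fully reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes_a = 2000, n_genes_b = 2000,
                              n_sample_labels_a = 40,
                              n_sample_labels_b = 30,
                              replicates_per_label = 2,
                              conservation_rate = 0.8,
                              coexpressed_background_rate = NULL,
                              n_archetypes = 30,
                              dispersion = 0.1,
                              library_size = 2e5,
                              ortho_fraction = 0.7,
                              orthogroup_shape_mix = c("1x1" = 0.7,
                                                       "1x2" = 0.15,
                                                       "1x3" = 0.1,
                                                       "2x2" = 0.05),
                              seed = 1) {
  if (!is.null(coexpressed_background_rate)) {
    n_archetypes <- max(2L, round(1 / coexpressed_background_rate))
  } else {
    coexpressed_background_rate <- 1 / n_archetypes
  }
  cfg <- list(n_genes_a = n_genes_a, n_genes_b = n_genes_b,
              n_sample_labels_a = n_sample_labels_a,
              n_sample_labels_b = n_sample_labels_b,
              replicates_per_label = replicates_per_label,
              conservation_rate = conservation_rate,
              coexpressed_background_rate = coexpressed_background_rate,
              n_archetypes = as.integer(n_archetypes),
              dispersion = dispersion, library_size = library_size,
              ortho_fraction = ortho_fraction,
              orthogroup_shape_mix = orthogroup_shape_mix, seed = seed)
  rates <- c(cfg$conservation_rate, cfg$coexpressed_background_rate,
             cfg$ortho_fraction)
  if (any(rates < 0 | rates > 1)) abort_config("rates must lie in [0, 1]")
  if (cfg$dispersion <= 0) abort_config("dispersion must be positive")
  counts <- c(cfg$n_genes_a, cfg$n_genes_b, cfg$n_sample_labels_a,
              cfg$n_sample_labels_b, cfg$replicates_per_label,
              cfg$n_archetypes)
  if (any(counts < 1)) abort_config("counts must be positive integers")
  if (abs(sum(cfg$orthogroup_shape_mix) - 1) > 1e-8 ||
      any(cfg$orthogroup_shape_mix < 0)) {
    abort_config("orthogroup_shape_mix must be a probability vector")
  }
  structure(cfg, class = "simulation_config")
}

# smooth positive archetype curves: mixtures of Gaussian bumps over the
# organ axis, each normalized to mean intensity 1 on [0, 1]
draw_archetypes <- function(n) {
  lapply(seq_len(n), function(k) {
    n_bumps <- sample(2:3, 1)
    par <- list(h = stats::runif(n_bumps, 0.5, 3),
                c = stats::runif(n_bumps, 0, 1),
                w = stats::runif(n_bumps, 0.05, 0.2))
    grid <- seq(0, 1, length.out = 201)
    par$norm <- mean(eval_archetype(par, grid, norm = 1))
    par
  })
}

eval_archetype <- function(par, t, norm = par$norm) {
  v <- rep(0.02, length(t))
  for (j in seq_along(par$h)) {
    v <- v + par$h[j] * exp(-(t - par$c[j])^2 / (2 * par$w[j]^2))
  }
  v / norm
}

label_positions <- function(n) (seq_len(n) - 0.5) / n

# render gene intensity profiles into a replicate-level NB count matrix
render_counts <- function(archetype_id, amplitude, archetypes, positions,
                          labels, replicates, library_size, dispersion,
                          prefix) {
  arch_at_pos <- vapply(archetypes, eval_archetype, numeric(length(positions)),
                        t = positions)           # positions x archetypes
  intensity <- t(arch_at_pos[, archetype_id, drop = FALSE]) * amplitude
  scale <- library_size / mean(colSums(intensity))
  n_col <- length(labels) * replicates
  sf <- stats::rlnorm(n_col, 0, 0.15)
  mu <- intensity[, rep(seq_along(labels), each = replicates), drop = FALSE]
  mu <- sweep(mu, 2, sf * scale, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
    nrow = nrow(mu))
  dimnames(counts) <- list(
    names(amplitude),
    paste0(rep(labels, each = replicates), ".", seq_len(replicates)))
  list(counts = counts, mu = mu)
}

parse_shape <- function(shape) {
  as.integer(strsplit(shape, "x")[[1]])
}

#' Simulate a pair of species with planted orthology structure
#'
#' See [simulation_config()] for the generative model. Orthogroups are
#' drawn from the configured shape mix until the orthologous share of each
#' species' gene budget is used; remaining genes are unrelated background.
#' Within a group, species-A members carry the family archetype and each
#' species-B member retains it with probability `conservation_rate`
#' (otherwise it expresses an independent archetype - a diverged
#' ortholog).
#'
#' @param config A [simulation_config()].
#' @return A `simulated_comparison`: list with `map_a`, `map_b`
#'   ([expression_map()]s), `orthopairs` (positive [pair_set()] of the
#'   1x1 groups), `orthogroups` (tibble), `truth` (tibble of every
#'   orthogroup pair with label `conserved`/`diverged`), `gene_meta`
#'   (per-gene archetype/amplitude assignments) and `config`. Expected
#'   count means are kept in `attr(, "mu")`.
#' @export
simulate_species_pair <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    archetypes <- draw_archetypes(config$n_archetypes)
    genes_a <- sprintf("A_g%04d", seq_len(config$n_genes_a))
    genes_b <- sprintf("B_g%04d", seq_len(config$n_genes_b))

    budget_a <- floor(config$ortho_fraction * config$n_genes_a)
    budget_b <- floor(config$ortho_fraction * config$n_genes_b)
    shapes <- names(config$orthogroup_shape_mix)
    used_a <- 0L; used_b <- 0L; g <- 0L
    groups <- list()
    repeat {
      shape <- sample(shapes, 1, prob = config$orthogroup_shape_mix)
      dim <- parse_shape(shape)
      if (used_a + dim[1] > budget_a || used_b + dim[2] > budget_b) break
      g <- g + 1L
      groups[[g]] <- list(
        group_id = sprintf("OG%04d", g),
        genes_a = genes_a[used_a + seq_len(dim[1])],
        genes_b = genes_b[used_b + seq_len(dim[2])])
      used_a <- used_a + dim[1]; used_b <- used_b + dim[2]
    }
    orthogroups <- tibble::tibble(
      group_id = vapply(groups, `[[`, character(1), "group_id"),
      genes_a = lapply(groups, `[[`, "genes_a"),
      genes_b = lapply(groups, `[[`, "genes_b"))
    orthogroups <- finalize_groups(orthogroups)

    # archetype / amplitude assignment
    arch_a <- integer(config$n_genes_a); arch_b <- integer(config$n_genes_b)
    amp_a <- numeric(config$n_genes_a); amp_b <- numeric(config$n_genes_b)
    names(arch_a) <- genes_a; names(arch_b) <- genes_b
    names(amp_a) <- genes_a; names(amp_b) <- genes_b
    new_amp <- function(n = 1) stats::rlnorm(n, log(100), 1.5)
    jitter_amp <- function(a) a * stats::rlnorm(length(a), 0, 0.25)
    conserved_b <- logical(config$n_genes_b)
    for (grp in groups) {
      fam_arch <- sample.int(config$n_archetypes, 1)
      fam_amp <- new_amp()
      arch_a[grp$genes_a] <- fam_arch
      amp_a[grp$genes_a] <- jitter_amp(rep(fam_amp, length(grp$genes_a)))
      for (gb in grp$genes_b) {
        if (stats::runif(1) < config$conservation_rate) {
          conserved_b[match(gb, genes_b)] <- TRUE
          arch_b[gb] <- fam_arch
          amp_b[gb] <- jitter_amp(fam_amp)
        } else {
          # diverged ortholog: independent expression program, but the
          # overall expression level stays loosely tied to the family
          # (dosage is conserved more strongly than spatial pattern)
          other <- setdiff(seq_len(config$n_archetypes), fam_arch)
          arch_b[gb] <- if (length(other)) sample(other, 1) else fam_arch
          amp_b[gb] <- fam_amp * stats::rlnorm(1, 0, 0.5)
        }
      }
    }
    bg_a <- arch_a == 0L; bg_b <- arch_b == 0L
    arch_a[bg_a] <- sample.int(config$n_archetypes, sum(bg_a), replace = TRUE)
    amp_a[bg_a] <- new_amp(sum(bg_a))
    arch_b[bg_b] <- sample.int(config$n_archetypes, sum(bg_b), replace = TRUE)
    amp_b[bg_b] <- new_amp(sum(bg_b))

    labels_a <- sprintf("sA%02d", seq_len(config$n_sample_labels_a))
    labels_b <- sprintf("sB%02d", seq_len(config$n_sample_labels_b))
    pos_a <- label_positions(config$n_sample_labels_a)
    pos_b <- label_positions(config$n_sample_labels_b)
    ra <- render_counts(arch_a, amp_a, archetypes, pos_a, labels_a,
                        config$replicates_per_label, config$library_size,
                        config$dispersion, "A")
    rb <- render_counts(arch_b, amp_b, archetypes, pos_b, labels_b,
                        config$replicates_per_label, config$library_size,
                        config$dispersion, "B")
    map_a <- expression_map(ra$counts, "speciesA")
    map_b <- expression_map(rb$counts, "speciesB")

    truth <- orthogroup_pairs(orthogroups)
    truth <- dplyr::mutate(
      tibble::as_tibble(truth),
      label = ifelse(arch_a[.data$gene_a] == arch_b[.data$gene_b],
                     "conserved", "diverged"))

    gene_meta <- dplyr::bind_rows(
      tibble::tibble(gene = genes_a, species = "A", archetype = unname(arch_a),
                     amplitude = unname(amp_a)),
      tibble::tibble(gene = genes_b, species = "B", archetype = unname(arch_b),
                     amplitude = unname(amp_b)))

    sim <- list(map_a = map_a, map_b = map_b,
                orthopairs = orthopairs_from_groups(orthogroups),
                orthogroups = orthogroups, truth = truth,
                gene_meta = gene_meta,
                axis = list(labels_a = labels_a, pos_a = pos_a,
                            labels_b = labels_b, pos_b = pos_b),
                config = config)
    attr(sim, "mu") <- list(a = ra$mu, b = rb$mu)
    class(sim) <- "simulated_comparison"
    sim
  })
}

#' Simulate a self-comparison design
#'
#' One gene set with fixed per-gene archetypes and amplitudes is rendered
#' into two independently noised expression datasets over different
#' sample-label sets, mimicking the upper-bound test of comparing a
#' species' genes against themselves across two independent atlases.
#' Positive pairs are each gene paired with itself across datasets.
#'
#' @param config A [simulation_config()]; `n_genes_a` genes are used for
#'   both datasets, with `n_sample_labels_a` / `n_sample_labels_b` labels.
#' @return A `simulated_comparison` whose orthogroups are the 1x1
#'   identical-gene groups and whose truth labels are all `conserved`.
#' @export
simulate_self_comparison <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    archetypes <- draw_archetypes(config$n_archetypes)
    n <- config$n_genes_a
    genes <- sprintf("g%04d", seq_len(n))
    arch <- sample.int(config$n_archetypes, n, replace = TRUE)
    amp <- stats::rlnorm(n, log(100), 1.5)
    names(arch) <- genes; names(amp) <- genes

    labels_a <- sprintf("sA%02d", seq_len(config$n_sample_labels_a))
    labels_b <- sprintf("sB%02d", seq_len(config$n_sample_labels_b))
    pos_a <- label_positions(config$n_sample_labels_a)
    pos_b <- label_positions(config$n_sample_labels_b)
    ra <- render_counts(arch, amp, archetypes, pos_a, labels_a,
                        config$replicates_per_label, config$library_size,
                        config$dispersion, "A")
    rb <- render_counts(arch, amp, archetypes, pos_b, labels_b,
                        config$replicates_per_label, config$library_size,
                        config$dispersion, "B")

    orthogroups <- tibble::tibble(
      group_id = sprintf("SG%04d", seq_len(n)),
      genes_a = as.list(genes), genes_b = as.list(genes))
    orthogroups <- finalize_groups(orthogroups)
    truth <- dplyr::mutate(
      tibble::as_tibble(orthogroup_pairs(orthogroups)), label = "conserved")

    sim <- list(map_a = expression_map(ra$counts, "datasetA"),
                map_b = expression_map(rb$counts, "datasetB"),
                orthopairs = pair_set(genes, genes, label = "positive"),
                orthogroups = orthogroups, truth = truth,
                gene_meta = tibble::tibble(gene = genes, species = "both",
                                           archetype = unname(arch),
                                           amplitude = unname(amp)),
                axis = list(labels_a = labels_a, pos_a = pos_a,
                            labels_b = labels_b, pos_b = pos_b),
                config = config)
    attr(sim, "mu") <- list(a = ra$mu, b = rb$mu)
    class(sim) <- "simulated_comparison"
    sim
  })
}

#' @export
print.simulated_comparison <- function(x, ...) {
  cat("<simulated_comparison>", nrow(x$map_a$counts), "+",
      nrow(x$map_b$counts), "genes;", nrow(x$orthogroups), "orthogroups;",
      nrow(x$orthopairs), "orthopairs\n")
  invisible(x)
}

#' Sample matching implied by the simulator's organ axis
#'
#' Bins the latent organ axis and matches the two species' sample labels
#' bin by bin: a bin holding exactly one label per species becomes a
#' direct match, larger bins become group matches. Bins lacking one side
#' are merged rightwards so every label is used exactly once.
#'
#' @param sim A `simulated_comparison`.
#' @param n_bins Number of axis bins (default 10).
#' @return A [sample_matching()].
#' @export
synthetic_sample_matching <- function(sim, n_bins = 10) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin_a <- cut(sim$axis$pos_a, breaks, include.lowest = TRUE, labels = FALSE)
  bin_b <- cut(sim$axis$pos_b, breaks, include.lowest = TRUE, labels = FALSE)
  type <- character(); a_l <- list(); b_l <- list()
  acc_a <- character(); acc_b <- character()
  for (bin in seq_len(n_bins)) {
    acc_a <- c(acc_a, sim$axis$labels_a[bin_a == bin])
    acc_b <- c(acc_b, sim$axis$labels_b[bin_b == bin])
    if (length(acc_a) && length(acc_b)) {
      type <- c(type, if (length(acc_a) == 1 && length(acc_b) == 1)
        "direct" else "group")
      a_l <- c(a_l, list(acc_a)); b_l <- c(b_l, list(acc_b))
      acc_a <- character(); acc_b <- character()
    }
  }
  if (length(acc_a) || length(acc_b)) {  # trailing one-sided bins
    a_l[[length(a_l)]] <- c(a_l[[length(a_l)]], acc_a)
    b_l[[length(b_l)]] <- c(b_l[[length(b_l)]], acc_b)
    type[length(type)] <-
      if (length(a_l[[length(a_l)]]) == 1 &&
          length(b_l[[length(b_l)]]) == 1) "direct" else "group"
  }
  sample_matching(type, a_l, b_l)
}

#' Write a simulated comparison to a directory of TSV files
#'
#' Emits exactly the formats the readers consume: `map_a.tsv`,
#' `map_b.tsv` ([read_expression_map()]), `orthopairs.tsv`
#' ([read_orthopairs()]), `orthogroups.tsv` ([read_orthogroups()], wide
#' dialect with columns `speciesA`/`speciesB`) and `truth.tsv`.
#'
#' @param sim A `simulated_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_comparison <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_map(sim$map_a, file.path(dir, "map_a.tsv"))
  write_expression_map(sim$map_b, file.path(dir, "map_b.tsv"))
  write_orthopairs(sim$orthopairs, file.path(dir, "orthopairs.tsv"))
  write_orthogroups(sim$orthogroups, file.path(dir, "orthogroups.tsv"),
                    species_a = "speciesA", species_b = "speciesB")
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
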