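#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' emulate the study regime the pipeline is designed for: 13 species in
#' four orders on [default_species_tree()], bias states switching
#' male<->female along branches under a symmetric two-state Markov chain,
#' lognormal FPKM with a four-fold expression effect, and patchy family
#' occupancy.
#'
#' @param species_tree `phylo` species tree; branch lengths in expected
#'   substitutions/site.
#' @param n_families Number of gene families to simulate.
#' @param bias_rate_mu Per-unit-branch-length switch rate of the
#'   symmetric two-state bias chain.
#' @param root_state_probs Probabilities of (male, female) at the root;
#'   must sum to 1.
#' @param fpkm_log2_baseline Mean log2 FPKM of the unbiased sex.
#' @param fpkm_log2_sd Lognormal noise sd (log2 scale), applied
#'   independently to each sex.
#' @param bias_effect_fold Expression ratio biased sex / other sex (> 1).
#' @param presence_prob Per-species probability that a family has a member.
#' @param extra_copy_prob Probability a present species carries 2 copies.
#' @param seq_length Alignment length in sites for Jukes-Cantor alignments.
#' @param acceleration_factor Multiplier on the focal species' terminal
#'   branch for alignment simulation (>= 1).
#' @param focal_species Species whose terminal branch is accelerated
#'   (NULL for none).
#' @param n_alignment_families Number of families for which
#'   [write_dataset()] emits alignments.
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       n_families = 500L,
                       bias_rate_mu = 0.5,
                       root_state_probs = c(male = 0.5, female = 0.5),
                       fpkm_log2_baseline = log2(10),
                       fpkm_log2_sd = 0.8,
                       bias_effect_fold = 4,
                       presence_prob = 0.7,
                       extra_copy_prob = 0.05,
                       seq_length = 1000L,
                       acceleration_factor = 1,
                       focal_species = "Tcas",
                       n_alignment_families = 5L,
                       seed = 1L) {
  stopifnot(n_families >= 1, bias_rate_mu >= 0,
            all(root_state_probs >= 0),
            abs(sum(root_state_probs) - 1) < 1e-12,
            fpkm_log2_sd >= 0, bias_effect_fold > 1,
            presence_prob > 0, presence_prob <= 1,
            extra_copy_prob >= 0, extra_copy_prob <= 1,
            seq_length >= 1, acceleration_factor >= 1)
  structure(list(species_tree = species_tree, n_families = as.integer(n_families),
                 bias_rate_mu = bias_rate_mu,
                 root_state_probs = root_state_probs,
                 fpkm_log2_baseline = fpkm_log2_baseline,
                 fpkm_log2_sd = fpkm_log2_sd,
                 bias_effect_fold = bias_effect_fold,
                 presence_prob = presence_prob,
                 extra_copy_prob = extra_copy_prob,
                 seq_length = as.integer(seq_length),
                 acceleration_factor = acceleration_factor,
                 focal_species = focal_species,
                 n_alignment_families = as.integer(n_alignment_families),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Flip probability of the symmetric two-state chain over a branch of
# length t at rate mu.
flip_probability <- function(mu, t) (1 - exp(-2 * mu * t)) / 2

#' Simulate binary bias states on a tree
#'
#' Evolves a male/female state from the root to the tips under the
#' symmetric two-state Markov chain: over a branch of length `t` the state
#' flips with probability `(1 - exp(-2*mu*t))/2`. Consumes the current R
#' RNG stream (one uniform for the root, then one per edge in cladewise
#' order).
#'
#' @param tree `phylo` tree with branch lengths.
#' @param mu Non-negative switch rate.
#' @param root_probs Probabilities of (male, female) at the root.
#' @return List with `tip_states` (named character vector over tips) and
#'   `n_transitions` (number of edges whose endpoints differ).
#' @export
simulate_bias_states <- function(tree, mu, root_probs = c(0.5, 0.5)) {
  if (mu < 0) stop_fmt("bias switch rate mu must be non-negative")
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  states <- character(ntip + tree$Nnode)
  root <- ntip + 1L
  states[[root]] <- if (stats::runif(1) < root_probs[[1L]]) "male" else "female"
  p_flip <- flip_probability(mu, tree$edge.length)
  u <- stats::runif(nrow(tree$edge))
  flips <- u < p_flip
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    states[[child]] <- if (flips[[e]]) {
      if (states[[parent]] == "male") "female" else "male"
    } else states[[parent]]
  }
  list(tip_states = stats::setNames(states[seq_len(ntip)], tree$tip.label),
       n_transitions = sum(flips))
}

#' Emit sexed FPKM records for planted bias states
#'
#' Each sex's FPKM is an independent lognormal draw around
#' `fpkm_log2_baseline`, with the biased sex's log2 mean shifted up by
#' `log2(bias_effect_fold)`. With zero noise a male-biased gene at the
#' defaults yields exactly (baseline*fold, baseline). Draw order: all male
#' deviates, then all female deviates.
#'
#' @param states Character vector of planted directions ("male"/"female"),
#'   one per gene.
#' @param config A [sim_config()].
#' @param gene_ids,species_ids Parallel identifier vectors.
#' @param tissue Tissue label for the emitted records.
#' @return Expression data.frame (gene_id, species_id, tissue, m_fpkm,
#'   f_fpkm).
#' @export
emit_expression <- function(states, config, gene_ids, species_ids,
                            tissue = "whole body") {
  n <- length(states)
  stopifnot(length(gene_ids) == n, length(species_ids) == n)
  lf <- log2(config$bias_effect_fold)
  m_mu <- config$fpkm_log2_baseline + ifelse(states == "male", lf, 0)
  f_mu <- config$fpkm_log2_baseline + ifelse(states == "female", lf, 0)
  m <- 2^(m_mu + stats::rnorm(n, 0, config$fpkm_log2_sd))
  f <- 2^(f_mu + stats::rnorm(n, 0, config$fpkm_log2_sd))
  data.frame(gene_id = gene_ids, species_id = species_ids, tissue = tissue,
             m_fpkm = m, f_fpkm = f, stringsAsFactors = FALSE)
}

#' Simulate family membership (occupancy and copy number)
#'
#' Presence of each species in each family is Bernoulli(`presence_prob`);
#' present species carry one gene, or two with probability
#' `extra_copy_prob`. Families landing on zero present species are
#' redrawn. Gene ids are `g<og>_<species>_<copy>`.
#'
#' @param config A [sim_config()].
#' @return List of orthogroups (same structure as [read_orthogroups()]).
#' @export
simulate_membership <- function(config) {
  species <- config$species_tree$tip.label
  lapply(seq_len(config$n_families), function(i) {
    og_id <- sprintf("OG%04d", i)
    repeat {
      present <- stats::runif(length(species)) < config$presence_prob
      if (any(present)) break
    }
    membership <- list()
    for (s in species[present]) {
      n_copies <- 1L + (stats::runif(1) < config$extra_copy_prob)
      membership[[s]] <- sprintf("g%s_%s_%d", sub("^OG", "", og_id), s,
                                 seq_len(n_copies))
    }
    list(og_id = og_id, membership = membership)
  })
}

#' Simulate a Jukes-Cantor alignment on a tree
#'
#' Sites evolve independently under the Jukes-Cantor model from a uniform
#' root; the focal species' terminal branch, if named, is multiplied by
#' `acceleration_factor` first.
#'
#' @param tree `phylo` tree, branch lengths in expected substitutions/site.
#' @param seq_length Number of sites (>= 1).
#' @param acceleration_factor Multiplier (>= 1) applied to the focal
#'   terminal branch.
#' @param focal_species Tip label to accelerate, or NULL.
#' @return Named character vector of equal-length ACGT strings, one per
#'   tip.
#' @export
simulate_alignment <- function(tree, seq_length, acceleration_factor = 1,
                               focal_species = NULL) {
  if (seq_length < 1L) stop_fmt("alignment length must be positive")
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  if (!is.null(focal_species) && acceleration_factor != 1) {
    tip_idx <- match(focal_species, tree$tip.label)
    if (is.na(tip_idx)) stop_fmt("focal species %s not in tree", focal_species)
    e <- which(tree$edge[, 2L] == tip_idx)
    tree$edge.length[e] <- tree$edge.length[e] * acceleration_factor
  }
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- seqs[[tree$edge[e, 1L]]]
    t <- tree$edge.length[[e]]
    p_change <- 0.75 * (1 - exp(-4 * t / 3))
    child <- parent
    hit <- which(stats::runif(seq_length) < p_change)
    if (length(hit)) {
      # jump uniformly to one of the three other nucleotides
      child[hit] <- ((parent[hit] - 1L +
                        sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
    }
    seqs[[tree$edge[e, 2L]]] <- child
  }
  nuc <- c("A", "C", "G", "T")
  out <- vapply(seqs[seq_len(ntip)],
                function(s) paste(nuc[s], collapse = ""), character(1))
  stats::setNames(out, tree$tip.label)
}

#' Simulate a complete labeled dataset in memory
#'
#' Single RNG stream seeded from `config$seed`; draw order: membership,
#' then per family (in og order) bias states then expression deviates.
#'
#' @param config A [sim_config()].
#' @return List: `orthogroups`, `expression`, `species_meta`, `tree`,
#'   `truth` (data.frame og_id, species_id, planted_state, n_transitions,
#'   accelerated), `gene_truth` (gene_id, true_direction).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  orthogroups <- simulate_membership(config)
  meta <- default_species_meta()
  meta <- meta[meta$species_id %in% config$species_tree$tip.label, ,
               drop = FALSE]
  if (nrow(meta) < length(config$species_tree$tip.label)) {
    extra <- setdiff(config$species_tree$tip.label, meta$species_id)
    meta <- rbind(meta, data.frame(species_id = extra, order_name = "Unknown",
                                   sex_system = "unknown",
                                   display_name = extra,
                                   stringsAsFactors = FALSE))
  }
  truth_rows <- vector("list", length(orthogroups))
  expr_rows <- vector("list", length(orthogroups))
  gene_truth <- vector("list", length(orthogroups))
  accel <- if (!is.null(config$focal_species) &&
               config$acceleration_factor > 1) config$focal_species else character(0)
  for (i in seq_along(orthogroups)) {
    og <- orthogroups[[i]]
    sim <- simulate_bias_states(config$species_tree, config$bias_rate_mu,
                                config$root_state_probs)
    sp <- names(og$membership)
    genes <- unlist(og$membership, use.names = FALSE)
    gene_sp <- rep(sp, lengths(og$membership))
    gene_states <- sim$tip_states[gene_sp]
    expr_rows[[i]] <- emit_expression(gene_states, config, genes, gene_sp)
    truth_rows[[i]] <- data.frame(
      og_id = og$og_id, species_id = sp,
      planted_state = unname(sim$tip_states[sp]),
      n_transitions = sim$n_transitions,
      accelerated = sp %in% accel, stringsAsFactors = FALSE)
    gene_truth[[i]] <- data.frame(gene_id = genes,
                                  true_direction = unname(gene_states),
                                  stringsAsFactors = FALSE)
  }
  list(orthogroups = orthogroups,
       expression = do.call(rbind, expr_rows),
       species_meta = meta,
       tree = config$species_tree,
       truth = do.call(rbind, truth_rows),
       gene_truth = do.call(rbind, gene_truth))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `orthogroups.tsv`, `expression.tsv`, `species_meta.tsv`,
#' `species_tree.nwk`, `truth.tsv` and (for the first
#' `n_alignment_families` families) plain-text FASTA alignments under
#' `alignments/`. Byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The `simulate_dataset()` result, invisibly.
#' @export
write_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_fmt("cannot create output directory %s", dir)
  data <- simulate_dataset(config)
  write_orthogroups(data$orthogroups, file.path(dir, "orthogroups.tsv"),
                    species = config$species_tree$tip.label)
  write_expression(data$expression, file.path(dir, "expression.tsv"))
  write_species_meta(data$species_meta, file.path(dir, "species_meta.tsv"))
  write_newick(data$tree, file.path(dir, "species_tree.nwk"))
  write_tsv_stable(data$truth, file.path(dir, "truth.tsv"))
  n_aln <- min(config$n_alignment_families, length(data$orthogroups))
  if (n_aln > 0L) {
    adir <- file.path(dir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (i in seq_len(n_aln)) {
      og <- data$orthogroups[[i]]
      aln <- simulate_alignment(config$species_tree, config$seq_length,
                                config$acceleration_factor,
                                config$focal_species)
      aln <- aln[names(aln) %in% names(og$membership)]
      writeLines(as.vector(rbind(paste0(">", names(aln)), unname(aln))),
                 file.path(adir, paste0(og$og_id, ".fasta")))
    }
  }
  invisible(data)
}
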