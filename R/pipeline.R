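#' Pipeline configuration
#'
#' @param orthogroups,expression,species_meta Paths to the three input
#'   tables (or in-memory objects of the matching types).
#' @param chromosome_map Optional path / data.frame for the
#'   gene-to-chromosome map.
#' @param species_tree Optional path / `phylo` species tree.
#' @param gene_trees Optional named list of `phylo` gene trees or a
#'   directory of `.nwk` files (file name stem = family id); leaves must
#'   be relabelable to species ids via the orthogroup membership.
#' @param call_params A [call_params()] object.
#' @param consensus_rule `"majority"` or `"unanimity"`.
#' @param min_orders,min_species_per_order,min_total_species Single-copy
#'   presence criteria, see [single_copy_families()].
#' @param attribution Turnover attribution mode, `"strict"` or
#'   `"lenient"`.
#' @param ratio_threshold,z_threshold,flag_rule Acceleration-screen
#'   settings, see [terminal_branch_screen()].
#' @param out_dir Output directory for report files (NULL = no files).
#' @param seed Seed recorded in the manifest and used by any simulation
#'   step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(orthogroups, expression, species_meta,
                            chromosome_map = NULL, species_tree = NULL,
                            gene_trees = NULL,
                            call_params = sbgturnover::call_params(),
                            consensus_rule = "majority",
                            min_orders = NULL, min_species_per_order = 1L,
                            min_total_species = NULL,
                            attribution = "strict",
                            ratio_threshold = 3, z_threshold = 2,
                            flag_rule = "and",
                            out_dir = NULL, seed = 1L) {
  structure(list(orthogroups = orthogroups, expression = expression,
                 species_meta = species_meta,
                 chromosome_map = chromosome_map,
                 species_tree = species_tree, gene_trees = gene_trees,
                 call_params = call_params, consensus_rule = consensus_rule,
                 min_orders = min_orders,
                 min_species_per_order = min_species_per_order,
                 min_total_species = min_total_species,
                 attribution = attribution,
                 ratio_threshold = ratio_threshold,
                 z_threshold = z_threshold, flag_rule = flag_rule,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `call_params` key may hold a map with `min_fpkm_floor`,
#' `fold_threshold`, `pseudocount`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cp <- do.call(call_params, y$call_params %||% list())
  y$call_params <- NULL
  do.call(pipeline_config, c(y, list(call_params = cp)))
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Cross-validate pipeline inputs
#'
#' Checks that every species referenced by the orthogroups has metadata
#' (violation = error), and reports orthogroup genes with no expression
#' row (warning; such genes simply remain uncalled).
#'
#' @param orthogroups,expression,species_meta In-memory inputs.
#' @return List with `errors` and `warnings`, each a character vector.
#' @export
validate_dataset <- function(orthogroups, expression, species_meta) {
  errors <- character(0)
  warnings <- character(0)
  og_species <- unique(unlist(lapply(orthogroups,
                                     function(o) names(o$membership))))
  missing_sp <- setdiff(og_species, species_meta$species_id)
  if (length(missing_sp))
    errors <- c(errors, sprintf("species %s in orthogroups has no metadata",
                                missing_sp))
  og_genes <- unlist(lapply(orthogroups, function(o)
    unlist(o$membership, use.names = FALSE)))
  uncalled <- setdiff(og_genes, expression$gene_id)
  if (length(uncalled))
    warnings <- c(warnings,
                  sprintf("gene %s has no expression row", uncalled))
  dup_expr_sp <- expression$species_id[!expression$species_id %in%
                                         species_meta$species_id]
  if (length(dup_expr_sp))
    errors <- c(errors, sprintf("species %s in expression has no metadata",
                                unique(dup_expr_sp)))
  list(errors = errors, warnings = warnings)
}

#' Run the full turnover analysis
#'
#' Executes, in order: input validation, orthogroup summary, per-gene bias
#' calling, order-level consensus, single-copy selection, family
#' classification with label counts, turnover tables and shares for both
#' contexts, the chromosome cross-tabulation (when a map is given) and the
#' tree reports (gene-tree/species-tree congruence and terminal-branch
#' acceleration, when trees are given). Reports are returned as a bundle
#' and, when `out_dir` is set, written as TSV/JSON files together with a
#' run manifest (seed, settings, artifact row counts, warnings).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  orthogroups <- resolve_input(config$orthogroups, read_orthogroups)
  expression <- resolve_input(config$expression, read_expression)
  species_meta <- resolve_input(config$species_meta, read_species_meta)
  chromosome_map <- if (!is.null(config$chromosome_map))
    resolve_input(config$chromosome_map, read_chromosome_map)
  species_tree <- if (!is.null(config$species_tree))
    resolve_input(config$species_tree, function(p) read_newick(path = p))

  val <- validate_dataset(orthogroups, expression, species_meta)
  if (length(val$errors))
    stop_fmt("input validation failed: %s", val$errors[[1L]])

  summary <- summarize_orthogroups(orthogroups, species_meta)
  calls <- call_bias_table(expression, config$call_params)
  consensus <- build_consensus_table(orthogroups, calls, species_meta,
                                     config$consensus_rule)
  min_orders <- config$min_orders %||%
    length(unique(species_meta$order_name))
  sc <- single_copy_families(orthogroups, species_meta,
                             min_orders = min_orders,
                             min_species_per_order = config$min_species_per_order,
                             min_total_species = config$min_total_species)
  cls <- classify_families(consensus[consensus$og_id %in% sc, , drop = FALSE],
                           calls, orthogroups, species_meta)
  label_levels <- c("consistent_male", "consistent_female",
                    "non_consistent_male", "non_consistent_female",
                    "mixed", "unclassified")
  label_counts <- vapply(label_levels, function(l) sum(cls$label == l),
                         integer(1))
  turnover <- lapply(c("female_biased", "male_biased"), function(ctx) {
    count_turnovers(cls, ctx, config$attribution, species_meta)
  })
  names(turnover) <- c("female_biased", "male_biased")
  shares <- lapply(names(turnover), function(ctx) {
    other <- turnover[[setdiff(names(turnover), ctx)]]$total
    if (turnover[[ctx]]$total > 0L)
      turnover_shares(turnover[[ctx]],
                      other_total = if (other > 0L) other else NULL)
    else NULL
  })
  names(shares) <- names(turnover)

  crosstab <- if (!is.null(chromosome_map))
    chromosome_bias_crosstab(calls, chromosome_map, species_meta)

  trees_report <- NULL
  if (!is.null(config$gene_trees) && !is.null(species_tree))
    trees_report <- gene_tree_reports(config$gene_trees, orthogroups,
                                      species_tree, config)

  report <- structure(list(
    summary = summary, calls = calls, consensus = consensus,
    single_copy = sc, classifications = cls, label_counts = label_counts,
    turnover = turnover, shares = shares, crosstab = crosstab,
    trees = trees_report, warnings = val$warnings, config = config),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report_bundle(report, config$out_dir)
  report
}

# Relabel a single-copy gene tree's leaves to species ids using the
# family's membership; returns NULL (with a reason) when the gene->species
# map is not a bijection onto the tree's leaves.
relabel_gene_tree <- function(tree, og) {
  gene2sp <- stats::setNames(rep(names(og$membership),
                                 lengths(og$membership)),
                             unlist(og$membership, use.names = FALSE))
  sp <- gene2sp[tree$tip.label]
  if (anyNA(sp) || anyDuplicated(sp)) return(NULL)
  tree$tip.label <- unname(sp)
  tree
}

gene_tree_reports <- function(gene_trees, orthogroups, species_tree, config) {
  if (is.character(gene_trees) && length(gene_trees) == 1L) {
    files <- list.files(gene_trees, pattern = "\\.nwk$", full.names = TRUE)
    trees <- lapply(files, function(f) read_newick(path = f))
    names(trees) <- sub("\\.nwk$", "", basename(files))
    gene_trees <- trees
  }
  og_index <- stats::setNames(seq_along(orthogroups),
                              vapply(orthogroups, `[[`, character(1), "og_id"))
  congruence <- list(); acceleration <- list(); skipped <- character(0)
  for (id in sort(names(gene_trees))) {
    tr <- gene_trees[[id]]
    og <- orthogroups[[og_index[[id]]]]
    rel <- if (!is.null(og)) relabel_gene_tree(tr, og) else tr
    if (is.null(rel)) {
      skipped <- c(skipped, sprintf("%s: leaves not 1:1 with species", id))
      next
    }
    pruned <- ape::keep.tip(species_tree,
                            intersect(species_tree$tip.label, rel$tip.label))
    congruence[[id]] <- rf_distance(rel, pruned)
    if (length(rel$tip.label) >= 4L && any(rel$edge.length > 0))
      acceleration[[id]] <- terminal_branch_screen(
        rel, config$ratio_threshold, config$z_threshold, config$flag_rule)
  }
  list(congruence = congruence, acceleration = acceleration,
       skipped = skipped)
}

turnover_df <- function(tab, shares) {
  data.frame(species_id = names(tab$counts),
             count = unname(tab$counts),
             share_pct = if (is.null(shares)) NA_real_
                         else unname(shares$shares),
             stringsAsFactors = FALSE)
}

write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  write_tsv_stable(report$calls, file.path(dir, "bias_calls.tsv"))
  write_tsv_stable(report$consensus, file.path(dir, "consensus.tsv"))
  write_tsv_stable(report$classifications,
                   file.path(dir, "classifications.tsv"))
  for (ctx in names(report$turnover))
    write_tsv_stable(turnover_df(report$turnover[[ctx]],
                                 report$shares[[ctx]]),
                     file.path(dir, sprintf("turnover_%s.tsv", ctx)))
  if (!is.null(report$crosstab))
    write_tsv_stable(report$crosstab, file.path(dir, "chromosome_crosstab.tsv"))
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$trees)) {
    cong <- lapply(report$trees$congruence, function(r)
      list(rf = r$rf, max_rf = r$max_rf, normalized_rf = r$normalized_rf,
           discordant_splits = r$discordant_splits))
    jsonlite::write_json(cong, file.path(dir, "congruence.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (id in names(report$trees$acceleration))
      write_tsv_stable(report$trees$acceleration[[id]],
                       file.path(dir, sprintf("acceleration_%s.tsv", id)))
  }
  manifest <- list(
    seed = cfg$seed,
    consensus_rule = cfg$consensus_rule,
    attribution = cfg$attribution,
    call_params = unclass(cfg$call_params)[c("min_fpkm_floor",
                                             "fold_threshold", "pseudocount")],
    label_counts = as.list(report$label_counts),
    row_counts = list(calls = nrow(report$calls),
                      consensus = nrow(report$consensus),
                      classifications = nrow(report$classifications),
                      single_copy = length(report$single_copy)),
    warnings = report$warnings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
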