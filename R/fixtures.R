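#' Turnover benchmark fixture (44 reversal families)
#'
#' Builds the canonical female-bias turnover configuration: 44 single-copy
#' families, each represented by one species per insect order, female-
#' biased everywhere except one male-biased species. The deviating species
#' are distributed 18/7/7/5/3/3/1 over the beetle, the silkworm, three
#' anopheline mosquitoes, a drosophilid and the aphid — the published
#' per-species reversal distribution. FPKM pairs are 40 vs 10, so every
#' intended call is unambiguous at default parameters.
#'
#' @return List: `orthogroups`, `expression`, `species_meta`,
#'   `expected_counts` (named integer vector of reversals per deviating
#'   species).
#' @export
turnover_fixture <- function() {
  meta <- default_species_meta()
  deviators <- c(Tcas = 18L, Bmor = 7L, Agam = 7L, Dpse = 5L,
                 Aalb = 3L, Apis = 3L, Aste = 1L)
  # default representative per order; the deviator replaces (or is) the
  # representative of its own order
  order_rep <- c(Hemiptera = "Apis", Coleoptera = "Tcas",
                 Lepidoptera = "Bmor", Diptera = "Dmel")
  fam_dev <- rep(names(deviators), deviators)
  ogs <- vector("list", length(fam_dev))
  expr <- vector("list", length(fam_dev))
  for (i in seq_along(fam_dev)) {
    dev <- fam_dev[[i]]
    dev_order <- meta$order_name[match(dev, meta$species_id)]
    reps <- order_rep
    reps[[dev_order]] <- dev
    og_id <- sprintf("TF%03d", i)
    genes <- stats::setNames(sprintf("g%s_%s", sub("^TF", "", og_id), reps),
                             reps)
    ogs[[i]] <- list(og_id = og_id,
                     membership = lapply(as.list(genes), identity))
    male <- reps == dev
    expr[[i]] <- data.frame(
      gene_id = unname(genes), species_id = unname(reps),
      tissue = "whole body",
      m_fpkm = ifelse(male, 40, 10), f_fpkm = ifelse(male, 10, 40),
      stringsAsFactors = FALSE)
  }
  list(orthogroups = ogs, expression = do.call(rbind, expr),
       species_meta = meta, expected_counts = deviators)
}

#' Consistency-arithmetic fixture (181-family portfolio)
#'
#' A portfolio of 181 single-copy families spanning every classification
#' label: 12 consistently male-biased, 0 consistently female-biased, 27
#' non-consistently male-biased, 44 non-consistently female-biased
#' (deviators per [turnover_fixture()]'s distribution), 49 mixed (2-2
#' order splits) and 49 unclassified (one order unbiased). Each family is
#' represented by one species per order; FPKM pairs 40/10 (or 10/10 for
#' unbiased).
#'
#' @return List: `orthogroups`, `expression`, `species_meta`,
#'   `expected_labels` (named integer vector).
#' @export
consistency_fixture <- function() {
  meta <- default_species_meta()
  order_rep <- c(Hemiptera = "Apis", Coleoptera = "Tcas",
                 Lepidoptera = "Bmor", Diptera = "Dmel")
  ncm_dev_orders <- rep(names(order_rep), length.out = 27L)
  ncf <- turnover_fixture()
  ogs <- list(); expr <- list(); k <- 0L
  add_family <- function(per_species_dir) {
    k <<- k + 1L
    og_id <- sprintf("CF%03d", k)
    reps <- names(per_species_dir)
    genes <- sprintf("c%03d_%s", k, reps)
    ogs[[length(ogs) + 1L]] <<- list(
      og_id = og_id,
      membership = stats::setNames(as.list(genes), reps))
    m <- ifelse(per_species_dir == "male", 40,
                ifelse(per_species_dir == "female", 10, 10))
    f <- ifelse(per_species_dir == "female", 40,
                ifelse(per_species_dir == "male", 10, 10))
    expr[[length(expr) + 1L]] <<- data.frame(
      gene_id = genes, species_id = reps, tissue = "whole body",
      m_fpkm = m, f_fpkm = f, stringsAsFactors = FALSE)
  }
  for (i in 1:12)
    add_family(stats::setNames(rep("male", 4), order_rep))
  for (o in ncm_dev_orders) {
    dirs <- stats::setNames(rep("male", 4), order_rep)
    dirs[[order_rep[[o]]]] <- "female"
    add_family(dirs)
  }
  for (i in 1:49) {
    dirs <- stats::setNames(c("male", "male", "female", "female"), order_rep)
    add_family(dirs)
  }
  for (i in 1:49) {
    dirs <- stats::setNames(rep("female", 4), order_rep)
    dirs[[order_rep[[1L + (i %% 4L)]]]] <- "unbiased"
    add_family(dirs)
  }
  # fold in the 44 non-consistent female families, renamed to keep ids unique
  ogs <- c(ogs, ncf$orthogroups)
  expr <- c(expr, list(ncf$expression))
  list(orthogroups = ogs, expression = do.call(rbind, expr),
       species_meta = meta,
       expected_labels = c(consistent_male = 12L, consistent_female = 0L,
                           non_consistent_male = 27L,
                           non_consistent_female = 44L,
                           mixed = 49L, unclassified = 49L))
}

#' Worked-example expression fixtures
#'
#' Paths to the small tab-separated fixtures shipped with the package:
#' the two reversal orthogroups' published FPKM tables
#' (`og0001228_expression.tsv`, `og0003141_expression.tsv`), the matching
#' chromosome-class map (`og0001228_chromosomes.tsv`) and the 13-species
#' metadata (`species_meta.tsv`).
#'
#' @param file File name under the package's `extdata`.
#' @return Absolute path.
#' @export
sbg_example <- function(file) {
  p <- system.file("extdata", file, package = "sbgturnover")
  if (!nzchar(p)) stop_fmt("no packaged example file '%s'", file)
  p
}
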