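#' Summarize an orthogroup table
#'
#' Headline occupancy counts: total families, species-specific families
#' (all genes from exactly one species, any copy number) with their gene
#' count, families shared by every species in the metadata, and families
#' qualifying as conserved single-copy under the default criteria of
#' [single_copy_families()].
#'
#' @param orthogroups List of orthogroups.
#' @param species_meta Species metadata.
#' @return List with `n_orthogroups`, `n_species_specific`,
#'   `n_genes_in_species_specific`, `n_shared_by_all`,
#'   `n_single_copy_qualifying`.
#' @export
summarize_orthogroups <- function(orthogroups, species_meta) {
  n_sp <- vapply(orthogroups, function(o) length(o$membership), integer(1))
  sp_specific <- n_sp == 1L
  all_sp <- vapply(orthogroups, function(o)
    all(species_meta$species_id %in% names(o$membership)), logical(1))
  genes_in_specific <- sum(vapply(orthogroups[sp_specific], function(o)
    length(unlist(o$membership)), integer(1)))
  list(
    n_orthogroups = length(orthogroups),
    n_species_specific = sum(sp_specific),
    n_genes_in_species_specific = genes_in_specific,
    n_shared_by_all = sum(all_sp),
    n_single_copy_qualifying =
      length(single_copy_families(orthogroups, species_meta))
  )
}

#' Select conserved single-copy families
#'
#' A family qualifies when every present species carries exactly one gene
#' and the family's taxonomic coverage meets the presence criterion:
#' either at least `min_species_per_order` species in each of at least
#' `min_orders` orders (the default, matching a "conserved across all four
#' orders" requirement), or — when `min_total_species` is given — at least
#' that many species regardless of order (the criterion used for
#' tree-building family sets).
#'
#' @param orthogroups List of orthogroups.
#' @param species_meta Species metadata.
#' @param min_orders Minimum number of orders represented.
#' @param min_species_per_order Minimum species per counted order.
#' @param min_total_species If non-NULL, replaces the order criterion with
#'   a plain species count.
#' @return Character vector of qualifying og_ids, in input order.
#' @export
single_copy_families <- function(orthogroups, species_meta,
                                 min_orders = length(unique(species_meta$order_name)),
                                 min_species_per_order = 1L,
                                 min_total_species = NULL) {
  if (is.null(min_total_species) &&
      min_orders > length(unique(species_meta$order_name)))
    stop_fmt("min_orders exceeds the number of orders in the metadata")
  keep <- vapply(orthogroups, function(og) {
    copies <- lengths(og$membership)
    if (any(copies != 1L)) return(FALSE)
    sp <- names(og$membership)
    if (!is.null(min_total_species)) return(length(sp) >= min_total_species)
    ord <- species_meta$order_name[match(sp, species_meta$species_id)]
    sum(table(ord) >= min_species_per_order) >= min_orders
  }, logical(1))
  vapply(orthogroups[keep], `[[`, character(1), "og_id")
}

#' Classify one family from its order consensus pattern
#'
#' The taxonomy over the configured orders: all orders male-biased ->
#' `consistent_male`; all female -> `consistent_female`; exactly three
#' male and one female -> `non_consistent_male` (the female order
#' deviates); exactly three female and one male -> `non_consistent_female`;
#' any order `unbiased` or `no_data` -> `unclassified`; anything else
#' (e.g. a 2-2 split) -> `mixed`.
#'
#' @param directions Named character vector, one consensus direction per
#'   order.
#' @return List with `label` and `deviating_order` (NA unless
#'   non-consistent).
#' @export
classify_family <- function(directions) {
  n <- length(directions)
  n_m <- sum(directions == "male")
  n_f <- sum(directions == "female")
  if (n_m + n_f < n)
    return(list(label = "unclassified", deviating_order = NA_character_))
  if (n_m == n)
    return(list(label = "consistent_male", deviating_order = NA_character_))
  if (n_f == n)
    return(list(label = "consistent_female", deviating_order = NA_character_))
  if (n_m == n - 1L && n_f == 1L)
    return(list(label = "non_consistent_male",
                deviating_order = names(directions)[directions == "female"]))
  if (n_f == n - 1L && n_m == 1L)
    return(list(label = "non_consistent_female",
                deviating_order = names(directions)[directions == "male"]))
  list(label = "mixed", deviating_order = NA_character_)
}

#' Classify every family in a consensus table
#'
#' Applies [classify_family()] per orthogroup and, for non-consistent
#' families, identifies the deviating species: the species of the
#' deviating order whose own call matches that order's (deviating)
#' direction.
#'
#' @param consensus Long consensus table from [build_consensus_table()].
#' @param calls Per-gene call table (for deviating-species lookup).
#' @param orthogroups List of orthogroups.
#' @param species_meta Species metadata.
#' @return Data.frame: `og_id`, `label`, `deviating_order`,
#'   `deviating_species` (comma-joined, "" if none), `n_deviating`.
#' @export
classify_families <- function(consensus, calls, orthogroups, species_meta) {
  empty <- data.frame(og_id = character(0), label = character(0),
                      deviating_order = character(0),
                      deviating_species = character(0),
                      n_deviating = integer(0), stringsAsFactors = FALSE)
  if (nrow(consensus) == 0L) return(empty)
  og_index <- stats::setNames(seq_along(orthogroups),
                              vapply(orthogroups, `[[`, character(1), "og_id"))
  rows <- lapply(split(consensus, consensus$og_id), function(cc) {
    dirs <- stats::setNames(cc$direction, cc$order)
    cls <- classify_family(dirs)
    dev_sp <- character(0)
    if (!is.na(cls$deviating_order)) {
      og <- orthogroups[[og_index[[cc$og_id[[1L]]]]]]
      spdir <- species_directions(unlist(og$membership, use.names = FALSE),
                                  calls)
      sp_order <- species_meta$order_name[match(spdir$species_id,
                                                species_meta$species_id)]
      dev_dir <- dirs[[cls$deviating_order]]
      dev_sp <- sort(spdir$species_id[sp_order == cls$deviating_order &
                                        spdir$direction == dev_dir])
    }
    data.frame(og_id = cc$og_id[[1L]], label = cls$label,
               deviating_order = cls$deviating_order %||% NA_character_,
               deviating_species = paste(dev_sp, collapse = ","),
               n_deviating = length(dev_sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$og_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count expression-bias turnovers per species
#'
#' For the `female_biased` context, a turnover is a family female-biased
#' in three orders and male-biased in one (`non_consistent_female`); the
#' reversal is attributed to the deviating species. Under `strict`
#' attribution only families with exactly one deviating species count
#' (each contributing 1 to that species; the rest are listed in
#' `excluded`); under `lenient` every deviating species of every such
#' family gets 1.
#'
#' @param classifications Data.frame from [classify_families()].
#' @param context `"female_biased"` (reversals of female bias, i.e. the
#'   deviating species is male-biased) or `"male_biased"`.
#' @param attribution `"strict"` (default) or `"lenient"`.
#' @param species_meta Species metadata (gives the full species universe;
#'   species with zero turnovers are reported as 0).
#' @return List of class `turnover_table`: `context`, `counts` (named
#'   integer vector over all species), `total`, `excluded` (og_ids not
#'   strictly attributable), `attribution`.
#' @export
count_turnovers <- function(classifications,
                            context = c("female_biased", "male_biased"),
                            attribution = c("strict", "lenient"),
                            species_meta) {
  context <- match.arg(context)
  attribution <- match.arg(attribution)
  label <- switch(context,
                  female_biased = "non_consistent_female",
                  male_biased = "non_consistent_male")
  fam <- classifications[classifications$label == label, , drop = FALSE]
  counts <- stats::setNames(integer(length(species_meta$species_id)),
                            species_meta$species_id)
  excluded <- character(0)
  for (i in seq_len(nrow(fam))) {
    sp <- strsplit(fam$deviating_species[[i]], ",", fixed = TRUE)[[1L]]
    sp <- sp[nzchar(sp)]
    if (attribution == "strict") {
      if (length(sp) == 1L) counts[[sp]] <- counts[[sp]] + 1L
      else excluded <- c(excluded, fam$og_id[[i]])
    } else {
      for (s in sp) counts[[s]] <- counts[[s]] + 1L
    }
  }
  structure(list(context = context, counts = counts,
                 total = sum(counts), excluded = excluded,
                 attribution = attribution),
            class = "turnover_table")
}

#' Per-species turnover shares and class excess
#'
#' Shares are `100 * count / total`, rounded half away from zero to one
#' decimal. When `other_total` (the size of the opposite non-consistent
#' class) is supplied, the excess statistic
#' `100 * (total - other_total) / other_total`, rounded to the nearest
#' integer, is included.
#'
#' @param table A `turnover_table` from [count_turnovers()].
#' @param other_total Optional count of the opposite class.
#' @return List with `shares` (named numeric, percent) and `excess_pct`
#'   (integer or NA).
#' @export
turnover_shares <- function(table, other_total = NULL) {
  if (table$total <= 0L) stop_fmt("turnover total is zero; no shares defined")
  shares <- round_half_away(100 * table$counts / table$total, 1L)
  excess <- NA_integer_
  if (!is.null(other_total)) {
    if (other_total <= 0L) stop_fmt("other class total is zero")
    excess <- as.integer(round_half_away(
      100 * (table$total - other_total) / other_total))
  }
  list(shares = shares, excess_pct = excess)
}

#' Cross-tabulate bias direction by chromosome class
#'
#' Counts genes by (direction, chromosome class), stratified by the
#' species' sex-determination system. Genes missing from the map fall in
#' class `unknown`. Counts only; no test is performed.
#'
#' @param calls Per-gene call table.
#' @param chromosome_map Data.frame `gene_id`, `chromosome_class`; may be
#'   empty.
#' @param species_meta Species metadata (supplies `sex_system`).
#' @return Data.frame `sex_system`, `direction`, `chromosome_class`, `n`,
#'   sorted, zero cells omitted.
#' @export
chromosome_bias_crosstab <- function(calls, chromosome_map, species_meta) {
  sys <- species_meta$sex_system[match(calls$species_id,
                                       species_meta$species_id)]
  if (anyNA(sys))
    stop_fmt("species %s not in metadata",
             calls$species_id[is.na(sys)][[1L]])
  cls <- chromosome_map$chromosome_class[match(calls$gene_id,
                                               chromosome_map$gene_id)]
  cls[is.na(cls)] <- "unknown"
  tab <- as.data.frame(table(sex_system = sys, direction = calls$direction,
                             chromosome_class = cls),
                       stringsAsFactors = FALSE)
  names(tab)[[4L]] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  tab <- tab[order(tab$sex_system, tab$direction, tab$chromosome_class), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}
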