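#' Bias-calling parameters
#'
#' @param min_fpkm_floor Minimum of `max(m_fpkm, f_fpkm)` for a gene to be
#'   callable; below it the call is `unbiased` with `passed_floor = FALSE`.
#' @param fold_threshold Minimum pseudocounted ratio for a directional
#'   call. The default 1 makes the call sign-based (any excess in one sex),
#'   which is the least restrictive rule consistent with published
#'   FPKM pairs as close as 104.6 vs 123.0 still being called biased.
#' @param pseudocount Added to both FPKM values before forming the ratio,
#'   stabilizing it at zero expression.
#' @param tissue_priority When a gene has rows from several tissues, the
#'   first matching tissue in this list is used; unlisted tissues rank
#'   after listed ones, alphabetically.
#' @return A list of class `call_params`.
#' @export
call_params <- function(min_fpkm_floor = 1.0, fold_threshold = 1.0,
                        pseudocount = 0.01,
                        tissue_priority = c("whole body", "gonad",
                                            "carcass", "head")) {
  stopifnot(min_fpkm_floor >= 0, fold_threshold >= 1, pseudocount > 0)
  structure(list(min_fpkm_floor = min_fpkm_floor,
                 fold_threshold = fold_threshold,
                 pseudocount = pseudocount,
                 tissue_priority = tissue_priority),
            class = "call_params")
}

#' Call sex bias from a male/female FPKM pair
#'
#' A gene is male-biased when the pseudocounted male/female ratio reaches
#' `fold_threshold` and male expression strictly exceeds female (and
#' symmetrically for female bias); genes whose larger FPKM falls below
#' `min_fpkm_floor` are unbiased with `passed_floor = FALSE`. Vectorized
#' over pairs.
#'
#' @param m_fpkm,f_fpkm Non-negative FPKM values (male / female samples).
#' @param params A [call_params()] object.
#' @return Data.frame with columns `direction` (male/female/unbiased),
#'   `fold_change` (pseudocounted max/min ratio, always >= 1) and
#'   `passed_floor`.
#' @export
call_bias <- function(m_fpkm, f_fpkm, params = call_params()) {
  if (any(m_fpkm < 0) || any(f_fpkm < 0))
    stop_fmt("FPKM values must be non-negative")
  if (length(m_fpkm) != length(f_fpkm))
    stop_fmt("m_fpkm and f_fpkm lengths differ")
  eps <- params$pseudocount
  hi <- pmax(m_fpkm, f_fpkm)
  lo <- pmin(m_fpkm, f_fpkm)
  fold <- (hi + eps) / (lo + eps)
  passed <- hi >= params$min_fpkm_floor
  dir <- rep("unbiased", length(m_fpkm))
  m_wins <- passed & m_fpkm > f_fpkm &
    (m_fpkm + eps) / (f_fpkm + eps) >= params$fold_threshold
  f_wins <- passed & f_fpkm > m_fpkm &
    (f_fpkm + eps) / (m_fpkm + eps) >= params$fold_threshold
  dir[m_wins] <- "male"
  dir[f_wins] <- "female"
  data.frame(direction = dir, fold_change = fold, passed_floor = passed,
             stringsAsFactors = FALSE)
}

# Rank tissues by the configured priority; unlisted tissues follow,
# alphabetically.
tissue_rank <- function(tissue, priority) {
  r <- match(tissue, priority)
  extra <- sort(unique(tissue[is.na(r)]))
  r[is.na(r)] <- length(priority) + match(tissue[is.na(r)], extra)
  r
}

#' Call bias for a whole expression table
#'
#' Selects one row per gene by tissue priority, then applies [call_bias()].
#'
#' @param expression Data.frame from [read_expression()].
#' @param params A [call_params()] object.
#' @return Data.frame with columns `gene_id`, `species_id`, `tissue`,
#'   `direction`, `fold_change`, `passed_floor`, one row per gene, in
#'   gene-id order.
#' @export
call_bias_table <- function(expression, params = call_params()) {
  ord <- order(expression$gene_id,
               tissue_rank(expression$tissue, params$tissue_priority))
  expr <- expression[ord, , drop = FALSE]
  expr <- expr[!duplicated(expr$gene_id), , drop = FALSE]
  calls <- call_bias(expr$m_fpkm, expr$f_fpkm, params)
  out <- cbind(expr[c("gene_id", "species_id", "tissue")], calls)
  rownames(out) <- NULL
  out
}

# Tally a set of directional calls into a single direction.
# majority: strict plurality among male/female (unbiased never wins; a
# male-female tie is unbiased). unanimity: every calling entry must share
# one direction. No calls at all -> no_data.
tally_direction <- function(directions, rule) {
  n_m <- sum(directions == "male")
  n_f <- sum(directions == "female")
  n_u <- sum(directions == "unbiased")
  dir <- if (length(directions) == 0L) {
    "no_data"
  } else if (rule == "majority") {
    if (n_m > n_f) "male" else if (n_f > n_m) "female" else "unbiased"
  } else if (rule == "unanimity") {
    if (n_m == length(directions)) "male"
    else if (n_f == length(directions)) "female"
    else "unbiased"
  } else stop_fmt("unknown consensus rule: %s", rule)
  list(direction = dir, n_male = n_m, n_female = n_f, n_unbiased = n_u)
}

#' Order-level consensus direction for one family
#'
#' Aggregates the per-species calls of one insect order into a single
#' direction. Under `majority`, the strict plurality of male vs female
#' calls wins (unbiased calls are counted but never win; ties are
#' unbiased); under `unanimity`, every calling species must agree.
#'
#' @param calls Data.frame with columns `species_id` and `direction`,
#'   restricted to species of `order_name`.
#' @param order_name The insect order being aggregated.
#' @param species_meta Species metadata; used to verify the restriction.
#' @param rule `"majority"` or `"unanimity"`.
#' @return List with `direction` (male/female/unbiased/no_data) and
#'   supporting counts `n_male`, `n_female`, `n_unbiased`.
#' @export
order_consensus <- function(calls, order_name, species_meta,
                            rule = c("majority", "unanimity")) {
  rule <- match.arg(rule)
  orders <- species_meta$order_name[match(calls$species_id,
                                          species_meta$species_id)]
  if (anyNA(orders))
    stop_fmt("species %s not in metadata",
             calls$species_id[is.na(orders)][[1L]])
  if (any(orders != order_name))
    stop_fmt("species %s belongs to %s, not %s",
             calls$species_id[orders != order_name][[1L]],
             orders[orders != order_name][[1L]], order_name)
  tally_direction(calls$direction, rule)
}

# Per-species direction within a family: families may carry several genes
# for one species; the species-level direction is the majority tally of
# its genes' calls (tie -> unbiased). Single-copy families reduce to the
# single gene's call.
species_directions <- function(gene_ids, calls) {
  idx <- match(gene_ids, calls$gene_id)
  have <- !is.na(idx)
  sub <- calls[idx[have], c("species_id", "direction")]
  if (nrow(sub) == 0L)
    return(data.frame(species_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  dirs <- vapply(split(sub$direction, sub$species_id),
                 function(d) tally_direction(d, "majority")$direction,
                 character(1))
  data.frame(species_id = names(dirs), direction = unname(dirs),
             stringsAsFactors = FALSE)
}

#' Build the family-by-order consensus table
#'
#' For every orthogroup and every insect order in the metadata, computes
#' the order-level consensus direction from the per-gene bias calls.
#' Genes without a call contribute nothing (their absence is reported by
#' [validate_dataset()]); species carrying several genes are first reduced
#' to a per-species majority direction. The result is deterministic and
#' independent of input row order.
#'
#' @param orthogroups List of orthogroups.
#' @param calls Per-gene call table from [call_bias_table()].
#' @param species_meta Species metadata.
#' @param rule Consensus rule, `"majority"` (default) or `"unanimity"`.
#' @return Long data.frame: `og_id`, `order`, `direction`, `n_male`,
#'   `n_female`, `n_unbiased` (counts of calling species), ordered by
#'   og_id then order name.
#' @export
build_consensus_table <- function(orthogroups, calls, species_meta,
                                  rule = c("majority", "unanimity")) {
  rule <- match.arg(rule)
  orders <- sort(unique(species_meta$order_name))
  rows <- lapply(orthogroups, function(og) {
    sp <- names(og$membership)
    bad <- setdiff(sp, species_meta$species_id)
    if (length(bad))
      stop_fmt("gene %s in %s: species %s absent from metadata",
               og$membership[[bad[[1L]]]][[1L]], og$og_id, bad[[1L]])
    spdir <- species_directions(unlist(og$membership, use.names = FALSE),
                                calls)
    sp_order <- species_meta$order_name[match(spdir$species_id,
                                              species_meta$species_id)]
    per_order <- lapply(orders, function(o) {
      tally_direction(spdir$direction[sp_order == o], rule)
    })
    data.frame(og_id = og$og_id, order = orders,
               direction = vapply(per_order, `[[`, character(1), "direction"),
               n_male = vapply(per_order, `[[`, integer(1), "n_male"),
               n_female = vapply(per_order, `[[`, integer(1), "n_female"),
               n_unbiased = vapply(per_order, `[[`, integer(1), "n_unbiased"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$og_id, out$order), , drop = FALSE]
  rownames(out) <- NULL
  out
}
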