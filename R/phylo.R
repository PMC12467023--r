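#' Jukes-Cantor distance matrix from an alignment
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` with `p` the pairwise mismatch
#' fraction. Mismatch fractions at or beyond the model's saturation point
#' (p >= 0.75) either raise an error or are capped, per `on_saturation`.
#'
#' @param alignment Named character vector of equal-length ungapped ACGT
#'   strings (>= 2 taxa).
#' @param on_saturation `"error"` (default) or `"cap"`.
#' @param cap Distance assigned to saturated pairs when capping.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
jc_distance_matrix <- function(alignment, on_saturation = c("error", "cap"),
                               cap = 5) {
  on_saturation <- match.arg(on_saturation)
  n <- length(alignment)
  if (n < 2L) stop_fmt("need at least 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop_fmt("sequences have unequal lengths (%s)",
             paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(mat[i, ] != mat[j, ])
      if (p >= 0.75) {
        if (on_saturation == "error")
          stop_fmt("saturated pair %s/%s (p = %.3f >= 0.75)",
                   names(alignment)[[i]], names(alignment)[[j]], p)
        d[i, j] <- d[j, i] <- cap
      } else {
        d[i, j] <- d[j, i] <- jc_distance(p)
      }
    }
  }
  d
}

#' Jukes-Cantor distance from a mismatch fraction
#' @param p Mismatch fraction in [0, 0.75).
#' @return Expected substitutions per site.
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75)) stop_fmt("p must lie in [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (via [ape::nj()]), made deterministic by
#' pre-sorting taxa lexicographically, with negative estimated branch
#' lengths clamped to zero and the deficit transferred to the sibling
#' branch so path lengths through the join are preserved.
#'
#' @param d Symmetric matrix with zero diagonal and labeled rows, n >= 3.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop_fmt("neighbor joining needs at least 3 taxa")
  if (any(is.na(d)) || any(!is.finite(d)))
    stop_fmt("distance matrix contains NA or non-finite entries")
  if (any(d < 0)) stop_fmt("distance matrix contains negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop_fmt("distance matrix is not symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

# Set each negative branch to zero, adding its (negative) value to a
# sibling branch at the same node; repeats until stable or the residual
# cannot be moved (then truncates at zero).
clamp_negative_branches <- function(tree) {
  for (pass in 1:5) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      if (tree$edge.length[[e]] >= 0) next
      parent <- tree$edge[e, 1L]
      sib <- setdiff(which(tree$edge[, 1L] == parent), e)
      deficit <- tree$edge.length[[e]]
      tree$edge.length[[e]] <- 0
      if (length(sib)) {
        s <- sib[[1L]]
        tree$edge.length[[s]] <- tree$edge.length[[s]] + deficit
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Nontrivial bipartitions of an unrooted tree, canonicalized: each split
# is represented by the side NOT containing the alphabetically first
# leaf, as a sorted comma-joined string.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[[1L]]
  ntip <- length(tree$tip.label)
  internal_children <- tree$edge[tree$edge[, 2L] > ntip, 2L]
  splits <- character(0)
  for (node in internal_children) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (anchor %in% clade) setdiff(tree$tip.label, clade) else clade
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      splits <- c(splits, paste(sort(side), collapse = ","))
  }
  unique(splits)
}

#' Robinson-Foulds congruence between two trees
#'
#' RF distance = size of the symmetric difference of the two trees'
#' nontrivial leaf bipartition sets (unrooted). Splits present in exactly
#' one tree are listed explicitly.
#'
#' @param tree_a,tree_b `phylo` trees over the same leaf set.
#' @return List of class `congruence_report`: `rf`, `max_rf`
#'   (`2*(n-3)`), `normalized_rf`, `discordant_splits` (each a sorted
#'   character vector of leaf labels).
#' @export
rf_distance <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label)
  lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) {
    diff <- union(setdiff(la, lb), setdiff(lb, la))
    stop_fmt("leaf sets differ: %s", paste(diff, collapse = ", "))
  }
  sa <- tree_bipartitions(tree_a)
  sb <- tree_bipartitions(tree_b)
  disc <- sort(union(setdiff(sa, sb), setdiff(sb, sa)))
  n <- length(la)
  max_rf <- 2L * (n - 3L)
  rf <- length(disc)
  structure(list(rf = rf, max_rf = max_rf,
                 normalized_rf = if (max_rf > 0L) rf / max_rf else 0,
                 discordant_splits = lapply(disc, function(s)
                   strsplit(s, ",", fixed = TRUE)[[1L]])),
            class = "congruence_report")
}

#' Screen a tree for accelerated terminal branches
#'
#' For each leaf, computes its terminal branch length, the ratio of that
#' length to the median of the other leaves' terminal lengths, and a
#' robust z-score on the log scale
#' (`(log(len) - median(log others)) / (1.4826 * MAD(log others))`).
#' A leaf is flagged when the ratio and/or z thresholds are exceeded,
#' per `rule`; when the MAD is zero the z criterion is undefined and the
#' ratio criterion decides alone.
#'
#' @param tree `phylo` tree with >= 4 leaves and positive median terminal
#'   length.
#' @param ratio_threshold Flag threshold on the ratio-to-median (default 3).
#' @param z_threshold Flag threshold on the robust z (default 2).
#' @param rule `"and"` (default) or `"or"` combination of the two criteria.
#' @return Data.frame of class `acceleration_report` (leaf,
#'   terminal_length, ratio, robust_z, flagged), sorted by ratio
#'   descending.
#' @export
terminal_branch_screen <- function(tree, ratio_threshold = 3,
                                   z_threshold = 2,
                                   rule = c("and", "or")) {
  rule <- match.arg(rule)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop_fmt("screen needs at least 4 leaves")
  term <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2L])]
  names(term) <- tree$tip.label
  if (all(term == 0)) stop_fmt("all terminal branch lengths are zero")
  stats_rows <- lapply(seq_len(ntip), function(i) {
    others <- term[-i]
    med <- stats::median(others)
    if (med <= 0) stop_fmt("median of other terminal lengths is not positive")
    ratio <- term[[i]] / med
    logo <- log(others[others > 0])
    z <- NA_real_
    if (length(logo) >= 2L) {
      m <- stats::mad(logo)  # 1.4826 * median absolute deviation
      if (m > 0 && term[[i]] > 0)
        z <- (log(term[[i]]) - stats::median(logo)) / m
    }
    ratio_hit <- ratio >= ratio_threshold
    z_hit <- !is.na(z) && z >= z_threshold
    flagged <- if (is.na(z)) ratio_hit
               else if (rule == "and") ratio_hit && z_hit
               else ratio_hit || z_hit
    data.frame(leaf = names(term)[[i]], terminal_length = term[[i]],
               ratio = ratio, robust_z = z, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_rows)
  out <- out[order(-out$ratio, out$leaf), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("acceleration_report", "data.frame")
  out
}
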