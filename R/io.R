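#' Read an orthogroup membership table
#'
#' Parses the OrthoFinder `Orthogroups.tsv` dialect: a tab-separated table
#' whose first column is the orthogroup id and whose remaining columns are
#' species, each cell holding a comma-separated list of gene ids (empty
#' cell = species absent from the family).
#'
#' @param path Path to a tab-separated orthogroups file with a header line.
#' @return A list of orthogroups, each a list with elements `og_id`
#'   (character scalar) and `membership` (named list mapping species_id to
#'   a character vector of gene ids; absent species are not present in the
#'   map). Order matches the file.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop_fmt("orthogroups file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop_fmt("orthogroups file is empty: %s", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop_fmt("orthogroups header needs an id column plus species columns")
  species <- header[-1L]
  ncol <- length(header)
  ogs <- vector("list", length(lines) - 1L)
  seen_og <- character(0)
  seen_genes <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(ogs)) {
    # preserve trailing empty cells
    cells <- strsplit(paste0(lines[[i + 1L]], "\t\x01"), "\t", fixed = TRUE)[[1L]]
    cells <- cells[-length(cells)]
    if (length(cells) != ncol)
      stop_fmt("ragged orthogroup row at line %d: %d cells, expected %d",
               i + 1L, length(cells), ncol)
    og_id <- cells[[1L]]
    if (og_id %in% seen_og) stop_fmt("duplicate orthogroup id: %s", og_id)
    seen_og <- c(seen_og, og_id)
    membership <- list()
    for (s in seq_along(species)) {
      cell <- cells[[s + 1L]]
      if (!nzchar(trimws(cell))) next
      genes <- strsplit(trimws(cell), ",[[:space:]]*")[[1L]]
      genes <- genes[nzchar(genes)]
      for (g in genes) {
        if (!is.null(seen_genes[[g]]))
          stop_fmt("gene id %s appears in both %s and %s",
                   g, seen_genes[[g]], og_id)
        seen_genes[[g]] <- og_id
      }
      membership[[species[[s]]]] <- genes
    }
    if (length(membership) == 0L)
      stop_fmt("orthogroup %s has no member genes", og_id)
    ogs[[i]] <- list(og_id = og_id, membership = membership)
  }
  ogs
}

#' Write an orthogroup membership table
#'
#' @param orthogroups List of orthogroups as returned by [read_orthogroups()].
#' @param path Output path.
#' @param species Column order; defaults to the union of species seen, in
#'   first-appearance order.
#' @export
write_orthogroups <- function(orthogroups, path, species = NULL) {
  if (is.null(species))
    species <- unique(unlist(lapply(orthogroups,
                                    function(o) names(o$membership))))
  rows <- vapply(orthogroups, function(o) {
    cells <- vapply(species, function(s) {
      g <- o$membership[[s]]
      if (is.null(g)) "" else paste(g, collapse = ", ")
    }, character(1))
    paste(c(o$og_id, cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("Orthogroup", species), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a sexed expression table
#'
#' Expects tab-separated columns `gene_id`, `species_id`, `tissue`,
#' `m_fpkm`, `f_fpkm` (male- and female-sample FPKM).
#'
#' @param path Path to the TSV.
#' @return A data.frame in file order with numeric FPKM columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_fmt("expression file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("gene_id", "species_id", "tissue", "m_fpkm", "f_fpkm")
  if (!identical(names(df), need))
    stop_fmt("expression header must be: %s", paste(need, collapse = ", "))
  for (col in c("m_fpkm", "f_fpkm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_fmt("non-numeric %s at line %d: '%s'",
               col, bad[[1L]] + 1L, df[[col]][[bad[[1L]]]])
    neg <- which(v < 0)
    if (length(neg))
      stop_fmt("negative %s at line %d: %s", col, neg[[1L]] + 1L, v[[neg[[1L]]]])
    df[[col]] <- v
  }
  dup <- df$gene_id[duplicated(paste(df$gene_id, df$tissue, sep = "\r"))]
  if (length(dup))
    stop_fmt("duplicate (gene_id, tissue) row for gene %s", dup[[1L]])
  df
}

#' Write a sexed expression table
#' @param expression Data.frame with the canonical five columns.
#' @param path Output path.
#' @export
write_expression <- function(expression, path) {
  write_tsv_stable(expression[c("gene_id", "species_id", "tissue",
                                "m_fpkm", "f_fpkm")], path)
}

#' Read species metadata
#'
#' @param path TSV with columns `species_id`, `order_name`, `sex_system`,
#'   `display_name`.
#' @return Validated data.frame.
#' @export
read_species_meta <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("species_id", "order_name", "sex_system", "display_name")
  if (!identical(names(df), need))
    stop_fmt("species metadata header must be: %s", paste(need, collapse = ", "))
  validate_species_meta(df)
  df
}

validate_species_meta <- function(meta) {
  if (anyDuplicated(meta$species_id))
    stop_fmt("duplicate species_id in metadata: %s",
             meta$species_id[duplicated(meta$species_id)][[1L]])
  if (any(!nzchar(meta$order_name)))
    stop_fmt("empty order_name in species metadata")
  bad <- setdiff(unique(meta$sex_system), valid_sex_systems)
  if (length(bad))
    stop_fmt("unknown sex_system '%s' (expected %s)", bad[[1L]],
             paste(valid_sex_systems, collapse = "/"))
  invisible(meta)
}

#' Write species metadata
#' @param meta Species metadata data.frame.
#' @param path Output path.
#' @export
write_species_meta <- function(meta, path) {
  write_tsv_stable(meta[c("species_id", "order_name", "sex_system",
                          "display_name")], path)
}

#' Read a gene-to-chromosome-class map
#'
#' @param path TSV with columns `gene_id`, `chromosome_class`
#'   (X / Z / autosome / unknown).
#' @return Data.frame.
#' @export
read_chromosome_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("gene_id", "chromosome_class")
  if (!identical(names(df), need))
    stop_fmt("chromosome map header must be: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$chromosome_class), valid_chromosome_classes)
  if (length(bad))
    stop_fmt("unknown chromosome_class '%s'", bad[[1L]])
  if (anyDuplicated(df$gene_id))
    stop_fmt("duplicate gene_id in chromosome map")
  df
}

#' Read a Newick tree
#'
#' Thin, validating wrapper over [ape::read.tree()]. One tree per input;
#' unquoted labels; optional branch lengths (missing lengths become 0);
#' internal node labels tolerated.
#'
#' @param path Path to a Newick file (mutually exclusive with `text`).
#' @param text Newick string.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop_fmt("read_newick needs a path or text")
    if (!file.exists(path)) stop_fmt("newick file not found: %s", path)
    text <- paste(readLines(path, encoding = "UTF-8"), collapse = "")
  }
  check_newick_syntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop_fmt("could not parse newick string")
  if (inherits(tr, "multiPhylo"))
    stop_fmt("expected a single tree, got %d", length(tr))
  if (anyDuplicated(tr$tip.label))
    stop_fmt("duplicate leaf label: %s",
             tr$tip.label[duplicated(tr$tip.label)][[1L]])
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else {
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

# Balance / trailing-garbage scan so malformed input fails with a character
# offset instead of an opaque parser error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (!is.na(semi) && !grepl("^[[:space:]]$", ch))
      stop_fmt("trailing garbage after ';' at character %d", i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_fmt("unbalanced ')' at character %d", i)
    }
    if (ch == ";") {
      if (depth != 0L)
        stop_fmt("unbalanced parentheses at character %d (depth %d)", i, depth)
      semi <- i
    }
  }
  if (is.na(semi)) stop_fmt("missing terminal ';' in newick string")
  invisible(TRUE)
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
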