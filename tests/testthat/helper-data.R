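# Shared in-code fixtures for the suite.

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# additive quartet: ((A:1,B:2):1,(C:3,D:4));  path distances are exact
quartet_tree <- function() read_newick(text = "((A:1,B:2):1,(C:3,D:4):1);")

# same topology at substitution-scale branch lengths (no JC saturation)
quartet_tree_scaled <- function()
  read_newick(text = "((A:0.05,B:0.1):0.05,(C:0.15,D:0.2):0.05);")

# balanced 8-taxon tree, equal terminals, used by the acceleration screen
eight_taxon_tree <- function(terminal = 0.1, internal = 0.05) {
  txt <- sprintf(
    "(((A:%1$g,B:%1$g):%2$g,(C:%1$g,D:%1$g):%2$g):%2$g,((E:%1$g,F:%1$g):%2$g,(G:%1$g,H:%1$g):%2$g):%2$g);",
    terminal, internal)
  read_newick(text = txt)
}

expression_row <- function(gene, sp, m, f, tissue = "whole body") {
  data.frame(gene_id = gene, species_id = sp, tissue = tissue,
             m_fpkm = m, f_fpkm = f, stringsAsFactors = FALSE)
}

# Independent oracle used by recovery tests: derive the expected family
# classification directly from planted tip states, bypassing the bias
# caller and consensus code paths.
planted_classification <- function(truth_fam, species_meta) {
  ord <- species_meta$order_name[match(truth_fam$species_id,
                                       species_meta$species_id)]
  orders <- sort(unique(species_meta$order_name))
  dirs <- vapply(orders, function(o) {
    st <- truth_fam$planted_state[ord == o]
    if (length(st) == 0L) return("no_data")
    nm <- sum(st == "male"); nf <- sum(st == "female")
    if (nm > nf) "male" else if (nf > nm) "female" else "unbiased"
  }, character(1))
  n <- length(dirs)
  nm <- sum(dirs == "male"); nf <- sum(dirs == "female")
  label <-
    if (nm + nf < n) "unclassified"
    else if (nm == n) "consistent_male"
    else if (nf == n) "consistent_female"
    else if (nm == n - 1L && nf == 1L) "non_consistent_male"
    else if (nf == n - 1L && nm == 1L) "non_consistent_female"
    else "mixed"
  dev_sp <- character(0)
  if (startsWith(label, "non_consistent")) {
    dev_dir <- if (label == "non_consistent_male") "female" else "male"
    dev_order <- names(dirs)[dirs == dev_dir]
    dev_sp <- sort(truth_fam$species_id[ord == dev_order &
                                          truth_fam$planted_state == dev_dir])
  }
  list(label = label, deviating_species = dev_sp)
}
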