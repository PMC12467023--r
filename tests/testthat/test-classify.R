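test_that("orthogroup summaries count occupancy classes exactly", {
  meta <- default_species_meta()
  ogs <- list(
    list(og_id = "OG1", membership = list(Apis = c("a1", "a2"))),
    list(og_id = "OG2",
         membership = stats::setNames(as.list(paste0("b", 1:13)),
                                      meta$species_id)),
    list(og_id = "OG3", membership = list(Apis = "c1", Tcas = "c2",
                                          Bmor = "c3", Dmel = "c4")))
  s <- summarize_orthogroups(ogs, meta)
  expect_equal(s$n_orthogroups, 3L)
  expect_equal(s$n_species_specific, 1L)
  expect_equal(s$n_genes_in_species_specific, 2L)
  expect_equal(s$n_shared_by_all, 1L)
  # OG2 (all 13, single copy) and OG3 (one per order) qualify
  expect_equal(s$n_single_copy_qualifying, 2L)
})

test_that("single-copy selection honours order and species-count criteria", {
  meta <- default_species_meta()
  two_copy <- list(og_id = "OGa",
                   membership = list(Apis = "x1", Tcas = c("x2", "x3"),
                                     Bmor = "x4", Dmel = "x5"))
  per_order <- list(og_id = "OGb",
                    membership = list(Apis = "y1", Tcas = "y2",
                                      Bmor = "y3", Dmel = "y4"))
  dipt_only <- list(og_id = "OGc",
                    membership = stats::setNames(
                      as.list(paste0("z", 1:5)),
                      c("Dmel", "Dsim", "Dyak", "Dpse", "Dvir")))
  ogs <- list(two_copy, per_order, dipt_only)
  expect_equal(single_copy_families(ogs, meta), "OGb")
  # the plain species-count criterion replaces the order criterion:
  # a 4-species family misses the >=5 bar even though it spans 4 orders
  expect_equal(single_copy_families(ogs, meta, min_total_species = 5L),
               "OGc")
  expect_equal(single_copy_families(ogs, meta, min_total_species = 4L),
               c("OGb", "OGc"))
  expect_error(single_copy_families(ogs, meta, min_orders = 9L),
               "min_orders")
})

test_that("classification taxonomy covers every consensus pattern", {
  pat <- function(...) {
    stats::setNames(c(...), c("Coleoptera", "Diptera", "Hemiptera",
                              "Lepidoptera"))
  }
  expect_equal(classify_family(pat("male", "male", "male", "male"))$label,
               "consistent_male")
  expect_equal(classify_family(pat("female", "female", "female",
                                   "female"))$label, "consistent_female")
  ncf <- classify_family(pat("male", "female", "female", "female"))
  expect_equal(ncf$label, "non_consistent_female")
  expect_equal(ncf$deviating_order, "Coleoptera")
  ncm <- classify_family(pat("male", "female", "male", "male"))
  expect_equal(ncm$label, "non_consistent_male")
  expect_equal(ncm$deviating_order, "Diptera")
  expect_equal(classify_family(pat("female", "female", "male",
                                   "male"))$label, "mixed")
  expect_equal(classify_family(pat("female", "female", "female",
                                   "no_data"))$label, "unclassified")
  expect_equal(classify_family(pat("male", "male", "male",
                                   "unbiased"))$label, "unclassified")
})

test_that("classification labels partition the single-copy families", {
  fx <- consistency_fixture()
  rep <- run_pipeline(pipeline_config(fx$orthogroups, fx$expression,
                                      fx$species_meta))
  expect_equal(sum(rep$label_counts), length(rep$single_copy))
  expect_equal(rep$label_counts[names(fx$expected_labels)],
               fx$expected_labels, ignore_attr = FALSE)
  expect_equal(nrow(rep$classifications), 181L)
})

test_that("turnover counting attributes reversals per species", {
  fx <- turnover_fixture()
  calls <- call_bias_table(fx$expression)
  consensus <- build_consensus_table(fx$orthogroups, calls, fx$species_meta)
  cls <- classify_families(consensus, calls, fx$orthogroups, fx$species_meta)
  tab <- count_turnovers(cls, "female_biased", "strict", fx$species_meta)
  expect_equal(tab$total, 44L)
  expect_equal(tab$counts[names(fx$expected_counts)], fx$expected_counts)
  expect_equal(tab$counts[["Dmel"]], 0L)
  expect_length(tab$excluded, 0L)
  # lenient never counts less than strict
  len <- count_turnovers(cls, "female_biased", "lenient", fx$species_meta)
  expect_true(len$total >= tab$total)
  # empty input: all-zero table
  empty <- count_turnovers(cls[0, ], "female_biased", "strict",
                           fx$species_meta)
  expect_equal(empty$total, 0L)
  expect_true(all(empty$counts == 0L))
})

test_that("strict attribution excludes multi-species deviations", {
  cls <- data.frame(
    og_id = c("F1", "F2"), label = "non_consistent_female",
    deviating_order = "Diptera",
    deviating_species = c("Agam", "Agam,Aste"),
    n_deviating = c(1L, 2L), stringsAsFactors = FALSE)
  meta <- default_species_meta()
  strict <- count_turnovers(cls, "female_biased", "strict", meta)
  expect_equal(strict$total, 1L)
  expect_equal(strict$excluded, "F2")
  lenient <- count_turnovers(cls, "female_biased", "lenient", meta)
  expect_equal(lenient$total, 3L)
  expect_equal(lenient$counts[["Aste"]], 1L)
})

test_that("shares and excess reproduce the printed rounding", {
  counts <- stats::setNames(c(18L, 7L, 7L, 5L, 3L, 3L, 1L),
                            c("Tcas", "Bmor", "Agam", "Dpse", "Aalb",
                              "Apis", "Aste"))
  tab <- structure(list(context = "female_biased", counts = counts,
                        total = 44L, excluded = character(0),
                        attribution = "strict"), class = "turnover_table")
  sh <- turnover_shares(tab, other_total = 27L)
  expect_equal(sh$shares[["Tcas"]], 40.9)
  expect_equal(sh$excess_pct, 63L)
  zero <- tab; zero$counts[["Aste"]] <- 0L
  expect_equal(turnover_shares(zero)$shares[["Aste"]], 0)
  bad <- tab; bad$total <- 0L
  expect_error(turnover_shares(bad), "zero")
})

test_that("chromosome crosstab stratifies by sex system", {
  expr <- read_expression(sbg_example("og0001228_expression.tsv"))
  calls <- call_bias_table(expr)
  cmap <- read_chromosome_map(sbg_example("og0001228_chromosomes.tsv"))
  meta <- default_species_meta()
  tab <- chromosome_bias_crosstab(calls, cmap, meta)
  xy_fx <- tab$n[tab$sex_system == "XY" & tab$direction == "female" &
                   tab$chromosome_class == "X"]
  expect_equal(xy_fx, 4L)
  xy_ma <- tab$n[tab$sex_system == "XY" & tab$direction == "male" &
                   tab$chromosome_class == "autosome"]
  expect_equal(xy_ma, 1L)
  # empty map: everything lands in class unknown
  none <- chromosome_bias_crosstab(calls,
                                   data.frame(gene_id = character(0),
                                              chromosome_class = character(0)),
                                   meta)
  expect_true(all(none$chromosome_class == "unknown"))
  # permutation invariance
  tab2 <- chromosome_bias_crosstab(calls[rev(seq_len(nrow(calls))), ],
                                   cmap, meta)
  expect_equal(tab2, tab)
})

test_that("consistent species relabeling permutes outputs identically", {
  fx <- turnover_fixture()
  ren <- function(x) paste0("sp_", x)
  ogs2 <- lapply(fx$orthogroups, function(o) {
    names(o$membership) <- ren(names(o$membership)); o
  })
  expr2 <- fx$expression; expr2$species_id <- ren(expr2$species_id)
  meta2 <- fx$species_meta; meta2$species_id <- ren(meta2$species_id)
  r1 <- run_pipeline(pipeline_config(fx$orthogroups, fx$expression,
                                     fx$species_meta))
  r2 <- run_pipeline(pipeline_config(ogs2, expr2, meta2))
  c1 <- r1$turnover$female_biased$counts
  c2 <- r2$turnover$female_biased$counts
  expect_equal(stats::setNames(unname(c2), sub("^sp_", "", names(c2))), c1)
  expect_equal(r2$label_counts, r1$label_counts)
})
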