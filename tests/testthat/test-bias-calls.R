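test_that("bias calls match the published FPKM examples and edge rules", {
  # beetle gonad pair: strongly male-biased
  expect_equal(call_bias(59.295, 1.458)$direction, "male")
  # mosquito whole-body pair: female-biased
  expect_equal(call_bias(27.62, 73.823)$direction, "female")
  # a ratio as small as 1.18 is still a directional call at defaults
  expect_equal(call_bias(104.623, 122.974)$direction, "female")
  expect_equal(call_bias(5, 5)$direction, "unbiased")
  low <- call_bias(0.5, 0.9)
  expect_equal(low$direction, "unbiased")
  expect_false(low$passed_floor)
  expect_error(call_bias(-1, 2), "non-negative")
})

test_that("bias calling is scale-invariant and antisymmetric", {
  set.seed(31)
  m <- stats::rexp(200, 1 / 20)
  f <- stats::rexp(200, 1 / 20)
  base <- call_bias(m, f)
  for (c in c(3, 117)) {
    scaled <- call_bias(c * m, c * f)
    keep <- base$passed_floor & scaled$passed_floor
    expect_equal(scaled$direction[keep], base$direction[keep])
  }
  swapped <- call_bias(f, m)
  expect_equal(swapped$direction,
               ifelse(base$direction == "male", "female",
                      ifelse(base$direction == "female", "male", "unbiased")))
  expect_equal(swapped$fold_change, base$fold_change)
})

test_that("fold threshold and pseudocount behave as configured", {
  p2 <- call_params(fold_threshold = 2)
  expect_equal(call_bias(30, 20, p2)$direction, "unbiased")
  expect_equal(call_bias(45, 20, p2)$direction, "male")
  # pseudocount keeps zero-FPKM ratios finite
  z <- call_bias(10, 0)
  expect_true(is.finite(z$fold_change))
  expect_equal(z$direction, "male")
})

test_that("tissue priority selects one row per gene", {
  expr <- rbind(expression_row("g1", "SpA", 5, 50, tissue = "head"),
                expression_row("g1", "SpA", 50, 5, tissue = "whole body"),
                expression_row("g2", "SpA", 5, 50, tissue = "antenna"))
  calls <- call_bias_table(expr)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$tissue[calls$gene_id == "g1"], "whole body")
  expect_equal(calls$direction, c("male", "female"))
})

test_that("order consensus applies plurality, tie and unanimity rules", {
  meta <- default_species_meta()
  dipt <- meta$species_id[meta$order_name == "Diptera"]
  calls <- data.frame(
    species_id = dipt,
    direction = c(rep("female", 6), rep("male", 2), "unbiased"),
    stringsAsFactors = FALSE)
  maj <- order_consensus(calls, "Diptera", meta, "majority")
  expect_equal(maj$direction, "female")
  expect_equal(c(maj$n_male, maj$n_female, maj$n_unbiased), c(2L, 6L, 1L))
  expect_equal(order_consensus(calls, "Diptera", meta, "unanimity")$direction,
               "unbiased")

  tie <- data.frame(species_id = dipt[1:2],
                    direction = c("male", "female"))
  expect_equal(order_consensus(tie, "Diptera", meta, "majority")$direction,
               "unbiased")

  one <- data.frame(species_id = "Tcas", direction = "male")
  expect_equal(order_consensus(one, "Coleoptera", meta, "majority")$direction,
               "male")
  expect_equal(order_consensus(one, "Coleoptera", meta, "unanimity")$direction,
               "male")
  expect_error(order_consensus(one, "Diptera", meta, "majority"),
               "belongs to Coleoptera")
  none <- data.frame(species_id = character(0), direction = character(0))
  expect_equal(order_consensus(none, "Diptera", meta, "majority")$direction,
               "no_data")
})

test_that("adding a female call never flips a female majority to male", {
  meta <- default_species_meta()
  dipt <- meta$species_id[meta$order_name == "Diptera"]
  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    calls <- data.frame(
      species_id = dipt[seq_len(n)],
      direction = sample(c("male", "female", "unbiased"), n, replace = TRUE))
    before <- order_consensus(calls, "Diptera", meta, "majority")$direction
    more <- rbind(calls, data.frame(species_id = dipt[[n + 1L]],
                                    direction = "female"))
    after <- order_consensus(more, "Diptera", meta, "majority")$direction
    if (before == "female") expect_equal(after, "female")
  }
})

test_that("consensus table is order-independent and covers absent orders", {
  fx <- turnover_fixture()
  tab <- build_consensus_table(fx$orthogroups,
                               call_bias_table(fx$expression),
                               fx$species_meta)
  shuf <- fx$expression[sample(nrow(fx$expression)), ]
  tab2 <- build_consensus_table(fx$orthogroups, call_bias_table(shuf),
                                fx$species_meta)
  expect_equal(tab2, tab)

  # a family present in one order only: other orders are no_data
  og <- list(list(og_id = "OGX", membership = list(Dmel = "gx")))
  calls <- call_bias_table(expression_row("gx", "Dmel", 40, 10))
  t1 <- build_consensus_table(og, calls, fx$species_meta)
  expect_equal(t1$direction[t1$order == "Diptera"], "male")
  expect_equal(sum(t1$direction == "no_data"), 3L)
})
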