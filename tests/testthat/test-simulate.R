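test_that("bias-state simulation honours the no-evolution limit", {
  tree <- default_species_tree()
  set.seed(1)
  sim <- simulate_bias_states(tree, mu = 0)
  expect_length(sim$tip_states, 13L)
  expect_equal(length(unique(sim$tip_states)), 1L)
  expect_equal(sim$n_transitions, 0L)
  expect_error(simulate_bias_states(tree, mu = -1), "non-negative")
})

test_that("single-branch flip frequency matches the two-state closed form", {
  # two-leaf tree: the B branch has length 0, so tip B carries the root
  # state and A differs from B exactly when the t-branch flipped
  tree <- read_newick(text = "(A:0.4,B:0);")
  mu <- 0.5
  p_expect <- (1 - exp(-2 * mu * 0.4)) / 2
  set.seed(202)
  flips <- replicate(10000, {
    s <- simulate_bias_states(tree, mu)
    s$tip_states[["A"]] != s$tip_states[["B"]]
  })
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(mean(flips) - p_expect), 3 * se)
})

test_that("saturating branch lengths reach the Bernoulli(1/2) limit", {
  tree <- read_newick(text = "(A:50,B:50);")
  set.seed(77)
  states <- replicate(10000,
    simulate_bias_states(tree, mu = 1)$tip_states[["A"]])
  tab <- table(factor(states, levels = c("male", "female")))
  p <- stats::chisq.test(tab, p = c(0.5, 0.5))$p.value
  expect_gt(p, 0.01)
})

test_that("expression emission is exact without noise and unbiased in log2", {
  cfg <- sim_config(fpkm_log2_sd = 0, fpkm_log2_baseline = log2(10),
                    bias_effect_fold = 4)
  set.seed(3)
  rec <- emit_expression(c("male", "female"), cfg, c("g1", "g2"),
                         c("Tcas", "Apis"))
  expect_equal(rec$m_fpkm, c(40, 10))
  expect_equal(rec$f_fpkm, c(10, 40))
  expect_true(all(rec$m_fpkm > 0 & rec$f_fpkm > 0))

  cfg2 <- sim_config(fpkm_log2_sd = 1)
  set.seed(4)
  n <- 10000
  rec2 <- emit_expression(rep("female", n), cfg2, paste0("g", 1:n),
                          rep("Apis", n))
  gap <- mean(log2(rec2$f_fpkm)) - mean(log2(rec2$m_fpkm))
  se <- 1 * sqrt(2 / n)
  expect_lt(abs(gap - log2(4)), 3 * se)
})

test_that("membership occupancy follows the truncated binomial", {
  cfg <- sim_config(n_families = 10000, presence_prob = 1 / 13,
                    extra_copy_prob = 0)
  set.seed(9)
  ogs <- simulate_membership(cfg)
  n_occ <- vapply(ogs, function(o) length(o$membership), integer(1))
  p <- 1 / 13
  expected <- 13 * p * (1 - p)^12 / (1 - (1 - p)^13)
  obs <- mean(n_occ == 1L)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(obs - expected), 3 * se)

  # degenerate config: everything single-copy everywhere
  cfg1 <- sim_config(n_families = 50, presence_prob = 1, extra_copy_prob = 0)
  set.seed(10)
  all1 <- simulate_membership(cfg1)
  expect_true(all(vapply(all1, function(o)
    all(lengths(o$membership) == 1L) && length(o$membership) == 13L,
    logical(1))))
})

test_that("alignment mismatch fraction matches the JC expectation", {
  tree <- read_newick(text = "(A:0.15,B:0.15);")
  d <- 0.3
  p_expect <- 0.75 * (1 - exp(-4 * d / 3))
  set.seed(21)
  aln <- simulate_alignment(tree, 10000)
  p_obs <- mean(strsplit(aln[["A"]], "")[[1]] != strsplit(aln[["B"]], "")[[1]])
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(p_obs - p_expect), 3 * se)

  zero <- simulate_alignment(read_newick(text = "(A:0,B:0);"), 500)
  expect_equal(zero[["A"]], zero[["B"]])
  expect_error(simulate_alignment(tree, 0), "positive")
})

test_that("terminal acceleration inflates distances to every other taxon", {
  tree <- eight_taxon_tree()
  # expected JC distance A->B without acceleration
  base_d <- 0.1 + 0.1
  set.seed(31)
  d_acc <- replicate(100, {
    aln <- simulate_alignment(tree, 2000, acceleration_factor = 5,
                              focal_species = "A")
    jc_distance_matrix(aln[c("A", "B")])["A", "B"]
  })
  expect_gt(mean(d_acc > base_d), 0.95)
})

test_that("datasets are reproducible and carry a complete truth table", {
  cfg <- sim_config(n_families = 20, seed = 99, n_alignment_families = 2)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(cfg, d1)
  write_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 6L)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  truth <- utils::read.delim(file.path(d1, "truth.tsv"))
  expect_equal(length(unique(truth$og_id)), 20L)
  # re-read emitted files through the package readers
  ogs <- read_orthogroups(file.path(d1, "orthogroups.tsv"))
  expr <- read_expression(file.path(d1, "expression.tsv"))
  expect_length(ogs, 20L)
  expect_true(all(expr$m_fpkm > 0 & expr$f_fpkm > 0))
  val <- validate_dataset(ogs, expr,
                          read_species_meta(file.path(d1, "species_meta.tsv")))
  expect_length(val$errors, 0L)
  expect_length(val$warnings, 0L)
})
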