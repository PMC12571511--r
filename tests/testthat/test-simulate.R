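test_that("tree sampling yields the unique topology at n = 3 and uniform draws at n = 5", {
  expect_length(enumerate_trees(3), 1)
  t3 <- simulate_tree(3, seed = 1)
  expect_equal(t3$E, enumerate_trees(3)[[1]])

  oracle <- enumerate_trees(5)
  expect_length(oracle, 3)
  keys <- vapply(oracle, function(E) paste(which(E > 0), collapse = ","), character(1))
  set.seed(77)
  draws <- replicate(3000, {
    E <- simulate_tree(5)$E
    paste(which(E > 0), collapse = ",")
  })
  freq <- table(factor(draws, levels = keys)) / length(draws)
  se <- sqrt((1 / 3) * (2 / 3) / length(draws))
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("sampled trees always satisfy the node-convention invariants", {
  for (n in c(3L, 5L, 7L, 9L)) {
    for (s in 1:5) {
      tree <- simulate_tree(n, seed = 100L * n + s)
      expect_identical(validate_tree(tree), character(0))
    }
  }
  expect_error(simulate_tree(4), "odd")
})

test_that("with no segmental events, mutations sit at copy 1 across their gain subtree", {
  cfg <- sim_config(n = 5, m = 2, r = 3, l = 2, g = 3, cmax = 3,
                    cna_rate = 0, seed = 8)
  tree <- simulate_tree(5, seed = 8)
  gen <- simulate_genomes(tree, cfg, seed = 9)
  expect_true(all(gen$C[, segment_cols(gen$index)] == 1))
  for (b in seq_len(5)) {
    child <- gen$mutations$gain_child[b]
    subtree <- c(child, which(tree$A[child, ] > 0))
    expect_true(all(gen$C[subtree, b] == 1))
    expect_true(all(gen$C[setdiff(1:5, subtree), b] == 0))
  }
})

test_that("true genomes respect the assigned allele's segment copy-number bound", {
  for (s in 1:5) {
    sim <- tiny_sim(seed = s, n = 5, m = 2, r = 3, l = 4, g = 4, cmax = 4)
    idx <- sim$instance$index
    Ct <- sim$truth$C
    seg_of <- apply(idx$Q, 1, which.max)
    for (b in mutation_cols(idx)) {
      allele_col <- if (sim$truth$D[b] == 1) segment_cols(idx, "1")[seg_of[b]]
                    else segment_cols(idx, "2")[seg_of[b]]
      expect_true(all(Ct[, b] <= Ct[, allele_col]))
    }
    # no homozygous segment deletions: every segment keeps a copy
    tot <- Ct[, segment_cols(idx, "1")] + Ct[, segment_cols(idx, "2")]
    expect_true(all(tot >= 1))
  }
})

test_that("replaying the event log reproduces the true genomes exactly", {
  for (s in c(3, 14, 25)) {
    sim <- tiny_sim(seed = s, n = 5, m = 2, r = 4, l = 4, g = 4, cmax = 4)
    C_replayed <- replay_truth(sim$truth, sim$instance$index)
    expect_equal(C_replayed, sim$truth$C)
  }
})

test_that("noiseless mixtures satisfy F = UC and perfect ratio consistency", {
  sim <- tiny_sim(seed = 5, n = 5, m = 3, r = 3, l = 4, g = 4, cmax = 3)
  expect_equal(sim$instance$F, sim$truth$U %*% sim$truth$C)
  expect_lt(ratio_cost(sim$truth$U, sim$truth$C, sim$instance$F,
                       sim$instance$index), 1e-9)
})

test_that("additive noise has the folded-normal mean deviation", {
  cfg <- sim_config(n = 3, m = 20, r = 4, l = 4, g = 6, cmax = 4,
                    noise_sd = 0.1, seed = 6)
  sim <- simulate_instance(cfg)
  dev <- abs(sim$instance$F - sim$truth$U %*% sim$truth$C)
  expected <- 0.1 * sqrt(2 / pi)
  se <- 0.1 * sqrt(1 - 2 / pi) / sqrt(length(dev))
  expect_lt(abs(mean(dev) - expected), 3 * se)
})

test_that("the RNA matrix is the permuted segment block of the true genomes", {
  sim <- tiny_sim(seed = 31, n = 5, m = 2, r = 3, l = 2, g = 2, cmax = 3)
  seg <- sim$truth$C[, segment_cols(sim$instance$index)]
  for (i in seq_len(5)) {
    expect_equal(sim$instance$C_RNA[sim$truth$true_map[i], ], seg[i, ],
                 ignore_attr = TRUE)
  }
})

test_that("RNA perturbation flips interior entries at the configured rate and clips", {
  cfg <- sim_config(n = 5, m = 2, r = 10, l = 2, g = 2, cmax = 4,
                    rna_flip_prob = 0.5, seed = 17)
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n)
  gen <- simulate_genomes(tree, cfg)
  rna <- simulate_rna(gen$C, gen$index, cfg)
  orig <- gen$C[, segment_cols(gen$index)]
  # unperturbed RNA matrix: true segment blocks in RNA row order
  aligned <- orig
  for (i in seq_len(5)) aligned[rna$true_map[i], ] <- orig[i, ]
  interior <- aligned > 0 & aligned < cfg$cmax
  changed <- rna$C_RNA != aligned
  n_int <- sum(interior)
  phat <- sum(changed[interior]) / n_int
  se <- sqrt(0.25 / n_int)
  expect_lt(abs(phat - 0.5), 3 * se)
  expect_true(all(rna$C_RNA >= 0 & rna$C_RNA <= cfg$cmax))
  # entries only ever move by one copy
  expect_true(all(abs(rna$C_RNA - aligned) <= 1))
})

test_that("every generated instance validates, across configurations", {
  configs <- list(
    sim_config(seed = 1),
    sim_config(n = 7, m = 4, seed = 2),
    sim_config(n = 3, m = 1, r = 2, l = 2, g = 1, cmax = 2, seed = 3),
    sim_config(noise_sd = 0.2, seed = 4),
    sim_config(nr = 3, n = 5, seed = 5),
    sim_config(rna_flip_prob = 0.3, seed = 6))
  for (cfg in configs) {
    sim <- simulate_instance(cfg)
    expect_identical(validate_instance(sim$instance), character(0))
  }
})
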