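test_that("clone matching inverts a row permutation at zero cost", {
  sim <- tiny_sim(seed = 3, n = 5, m = 3, r = 3, l = 2, g = 3, cmax = 3)
  Ct <- sim$truth$C; Ut <- sim$truth$U
  perm_true <- c(3, 1, 4, 5, 2)
  C_est <- Ct[perm_true, ]
  U_est <- Ut[, perm_true]
  perm <- match_clones(C_est, U_est, Ct, Ut)
  expect_equal(perm, perm_true)
  expect_equal(rmse_U(U_est, Ut, perm), 0)
})

test_that("4x4 matching agrees with exhaustive search over all permutations", {
  set.seed(19)
  for (rep in 1:5) {
    C_est <- matrix(sample(0:3, 4 * 6, replace = TRUE), 4)
    C_true <- matrix(sample(0:3, 4 * 6, replace = TRUE), 4)
    U_est <- init_U(2, 4, seed = rep)
    U_true <- init_U(2, 4, seed = rep + 50)
    perm <- match_clones(C_est, U_est, C_true, U_true)
    cost <- function(p) sum(vapply(1:4, function(i)
      sum(abs(C_est[i, ] - C_true[p[i], ])), numeric(1)))
    brute <- min(vapply(all_perms(4), cost, numeric(1)))
    expect_equal(cost(perm), brute)
  }
})

test_that("padding matches a smaller estimate against all true clones", {
  sim <- tiny_sim(seed = 4, n = 5, m = 3, r = 2, l = 2, g = 2, cmax = 2)
  idx <- sim$instance$index
  C_est <- sim$truth$C[c(1, 2, 5), ]
  U_est <- sim$truth$U[, c(1, 2, 5)]
  U_est <- U_est / rowSums(U_est)
  perm <- match_clones(C_est, U_est, sim$truth$C, sim$truth$U, index = idx)
  expect_length(perm, 5)
  expect_setequal(perm, 1:5)
  expect_equal(perm[1:3], c(1L, 2L, 5L))  # true rows recovered exactly
})

test_that("mixture RMSE matches hand computations and is permutation-symmetric", {
  U_true <- matrix(c(1, 0), 1)
  U_est <- matrix(c(0.5, 0.5), 1)
  expect_equal(rmse_U(U_est, U_true, 1:2), 0.5)  # sqrt((0.25 + 0.25)/2)
  expect_equal(rmse_U(U_true, U_true, 1:2), 0)
  U_a <- init_U(3, 4, seed = 1); U_b <- init_U(3, 4, seed = 2)
  p <- c(2L, 4L, 1L, 3L)
  expect_equal(rmse_U(U_a, U_b, 1:4), rmse_U(U_a[, p], U_b[, p], 1:4))
})

test_that("variant-block RMSE matches hand computations and recombines", {
  sim <- tiny_sim(seed = 6, n = 3, m = 2, r = 2, l = 2, g = 2, cmax = 3)
  idx <- sim$instance$index
  Ct <- sim$truth$C
  expect_equal(rmse_variants(Ct, Ct, 1:3, "sv", idx), 0)
  C_off <- Ct
  C_off[2, snv_cols(idx)[1]] <- C_off[2, snv_cols(idx)[1]] + 2
  expect_equal(rmse_variants(C_off, Ct, 1:3, "snv", idx),
               2 / sqrt(3 * 2))                      # one entry off by 2 in n x g
  # block RMSEs recombine (weighted by column counts) into the whole-matrix RMSE
  per_block <- c(sv = rmse_variants(C_off, Ct, 1:3, "sv", idx)^2 * 2,
                 snv = rmse_variants(C_off, Ct, 1:3, "snv", idx)^2 * 2,
                 seg = rmse_variants(C_off, Ct, 1:3, "segment", idx)^2 * 4)
  whole <- sqrt(mean((C_off - Ct)^2))
  expect_equal(sqrt(sum(per_block) / 8), whole)
})

test_that("the exhaustive oracle refuses oversized search spaces", {
  sim <- tiny_sim(seed = 2, n = 7, m = 2, r = 4, l = 4, g = 6, cmax = 4)
  expect_error(oracle_solve(sim$instance, sim$truth$U), "too large")
})

test_that("the oracle optimum is bounded by the feasible truth on noiseless data", {
  for (s in 1:3) {
    sim <- tiny_sim(seed = s, n = 3, m = 2, r = 1, l = 2, g = 1, cmax = 2,
                    cna_rate = 1)
    inst <- sim$instance
    M <- map_to_M(sim$truth$true_map, 3, 3)
    truth_terms <- evaluate_objective(inst, sim$truth$U, sim$truth$C,
                                      sim$truth$tree$E, M)
    orc <- oracle_solve(inst, sim$truth$U)
    expect_lte(orc$objective, truth_terms$total + 1e-9)
    expect_gte(orc$n_optima, 1)
  }
})
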