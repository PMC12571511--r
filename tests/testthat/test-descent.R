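test_that("default regularization weights follow the size-ratio formulas", {
  expect_error(compute_lambdas(0, 0, 2, 2, 3), "no mutations")
  lam <- compute_lambdas(l = 2, g = 2, r = 2, m = 3, n = 3)
  expect_equal(lam$lambda2, 0.5 * 8 / 4)        # = 1.0
  expect_equal(lam$lambda1, 0.5 * (8 * 3) / (4 * 3))
  # lambda1 is linear in the sample count at fixed variant counts
  lam2 <- compute_lambdas(l = 2, g = 2, r = 2, m = 6, n = 3)
  expect_equal(lam2$lambda1, 2 * lam$lambda1)
  expect_equal(lam2$lambda2, lam$lambda2)
  # edge-count variant of the size constant
  lam_e <- compute_lambdas(l = 2, g = 2, r = 2, m = 3, n = 3, edges = TRUE)
  expect_equal(lam_e$lambda1, 0.5 * (8 * 3) / (4 * 2))
})

test_that("mixture initialization is flat-Dirichlet and reproducible", {
  expect_equal(init_U(3, 1, seed = 1), matrix(1, 3, 1))
  expect_identical(init_U(4, 3, seed = 9), init_U(4, 3, seed = 9))
  expect_false(identical(init_U(4, 3, seed = 9), init_U(4, 3, seed = 10)))
  U <- init_U(10000, 3, seed = 2)
  expect_true(all(abs(rowSums(U) - 1) < 1e-12))
  # flat Dirichlet coordinate mean 1/3, var 1/18
  se <- sqrt(1 / 18 / 10000)
  expect_true(all(abs(colMeans(U) - 1 / 3) < 3 * se))
})

test_that("the U-step recovers a pure sample and the 50/50 mix of two clones", {
  sim <- tiny_sim(seed = 21, n = 3, m = 1, r = 2, l = 2, g = 2, cmax = 2)
  inst <- sim$instance
  C <- sim$truth$C
  # make the sample exactly clone 1
  inst$F <- C[1, , drop = FALSE]
  U <- solve_U(inst, C, ratio_in_ustep = FALSE)
  expect_equal(as.numeric(U), c(1, 0, 0), tolerance = 1e-6)
  expect_true(all(abs(rowSums(U) - 1) < 1e-6))

  # two-clone mix against a grid-search oracle on the 1-simplex
  C2 <- rbind(c(2, 0, 2, 1, 1, 1), c(0, 0, 1, 1, 1, 1))
  idx2 <- variant_index(l = 0, g = 2, r = 2, Q = rbind(c(1, 0), c(0, 1)),
                        G = matrix(0, 0, 0))
  F2 <- 0.5 * C2[1, , drop = FALSE] + 0.5 * C2[2, , drop = FALSE]
  inst2 <- problem_instance(F = F2, C_RNA = C2[, 3:6], index = idx2, n = 2,
                            cmax = 2)
  grid <- seq(0, 1, by = 1e-3)
  obj <- vapply(grid, function(u) {
    sum(abs(F2 - (u * C2[1, ] + (1 - u) * C2[2, ])))
  }, numeric(1))
  u_star <- grid[which.min(obj)]
  U2 <- solve_U(inst2, C2, ratio_in_ustep = FALSE)
  expect_equal(U2[1, 1], u_star, tolerance = 1e-3)
  expect_equal(as.numeric(U2), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("the C-step never scores worse than the known feasible truth", {
  for (s in c(31, 32)) {
    sim <- tiny_sim(seed = s, n = 3, m = 3, r = 2, l = 2, g = 2, cmax = 3)
    inst <- sim$instance
    M <- map_to_M(sim$truth$true_map, inst$n, inst$nr)
    truth_terms <- evaluate_objective(inst, sim$truth$U, sim$truth$C,
                                      sim$truth$tree$E, M)
    res <- solve_C(inst, sim$truth$U, run_config(mode = "joint", restarts = 1))
    expect_lte(res$objective, truth_terms$total + 1e-8)
  }
})

test_that("the joint C-step is at least as good as the two-stage C-step", {
  for (s in c(41, 42)) {
    sim <- tiny_sim(seed = s, n = 3, m = 2, r = 2, l = 2, g = 2, cmax = 2)
    inst <- sim$instance
    U <- init_U(inst$m, inst$n, seed = s)
    joint <- solve_C(inst, U, run_config(mode = "joint", restarts = 1))
    two <- solve_C(inst, U, run_config(mode = "two_stage", restarts = 1))
    terms_j <- evaluate_objective(inst, U, joint$C, joint$E, joint$M)
    terms_t <- evaluate_objective(inst, U, two$C, two$E, two$M)
    expect_lte(terms_j$total, terms_t$total + 1e-8)
  }
})

test_that("the full run is reproducible and logs one row per iteration", {
  sim <- tiny_sim(seed = 51)
  cfg <- run_config(iterations = 2, restarts = 2, seed = 4)
  sol1 <- run_deconvolution(sim$instance, cfg)
  sol2 <- run_deconvolution(sim$instance, cfg)
  expect_identical(sol1$U, sol2$U)
  expect_identical(sol1$C, sol2$C)
  expect_identical(sol1$tree$E, sol2$tree$E)
  log <- attr(sol1, "log")
  expect_equal(nrow(log), 2 * 2)
  expect_equal(unname(table(log$restart)), c(2L, 2L), ignore_attr = TRUE)
})

test_that("a noiseless tiny instance is deconvolved to a perfect fit", {
  sim <- tiny_sim(seed = 61, n = 3, m = 3, r = 2, l = 2, g = 2, cmax = 2)
  sol <- run_deconvolution(sim$instance,
                           run_config(iterations = 3, restarts = 2, seed = 1))
  expect_lt(sol$objective_terms$fit, 1e-6)
  expect_identical(validate_solution(sol, sim$instance), character(0))
})
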