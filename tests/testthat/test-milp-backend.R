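test_that("the MILP bridge solves a small integer program to its enumerated optimum", {
  # knapsack: max 5a+4b+3c st 2a+3b+c <= 4, binary; brute force over 8 points
  vals <- c(5, 4, 3); wts <- c(2, 3, 1)
  best <- -Inf
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    x <- c(a, b, cc)
    if (sum(wts * x) <= 4) best <- max(best, sum(vals * x))
  }
  m <- clonedecon:::milp_model()
  idx <- clonedecon:::milp_add_vars(m, "x", 3, type = "binary")
  clonedecon:::milp_add_constr(m, idx, wts, ub = 4)
  clonedecon:::milp_set_obj(m, idx, -vals)          # minimize the negation
  res <- clonedecon:::milp_solve(m)
  expect_identical(res$status, "optimal")
  expect_equal(-res$objective, best)
})

test_that("the bridge reports infeasibility and solves pure LPs", {
  m <- clonedecon:::milp_model()
  idx <- clonedecon:::milp_add_vars(m, "x", 1, lb = 0, ub = 1)
  clonedecon:::milp_add_constr(m, idx, 1, lb = 2)   # x >= 2 with x <= 1
  expect_identical(clonedecon:::milp_solve(m)$status, "infeasible")

  m2 <- clonedecon:::milp_model()
  idx2 <- clonedecon:::milp_add_vars(m2, "x", 2, lb = 0, ub = 10)
  clonedecon:::milp_add_constr(m2, idx2, c(1, 1), lb = 3)
  clonedecon:::milp_set_obj(m2, idx2, c(2, 1))
  res <- clonedecon:::milp_solve(m2)
  expect_equal(res$objective, 3)                    # all mass on the cheap var
  expect_equal(res$x[idx2], c(0, 3))
})
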