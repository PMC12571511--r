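test_that("well-formed simulated instances validate cleanly", {
  for (s in 1:3) {
    sim <- tiny_sim(seed = s)
    expect_identical(validate_instance(sim$instance), character(0))
  }
})

test_that("validate_instance names the violated invariant", {
  sim <- tiny_sim(seed = 1)
  inst <- sim$instance

  bad_n <- inst; bad_n$n <- 4L
  v <- validate_instance(bad_n)
  expect_length(v, 1)
  expect_match(v, "odd")

  bad_q <- inst
  bad_q$index$Q[1, ] <- 0
  v <- validate_instance(bad_q)
  expect_length(v, 1)
  expect_match(v, "Q row 1")

  bad_g <- inst
  bad_g$index$G[1, ] <- 0
  expect_true(any(grepl("G", validate_instance(bad_g))))

  bad_f <- inst
  bad_f$F[1, 1] <- -0.1
  expect_true(any(grepl("negative", validate_instance(bad_f))))
})

test_that("transitive closure matches hand-derived ancestries", {
  E3 <- matrix(0, 3, 3); E3[3, 1] <- E3[3, 2] <- 1
  A3 <- transitive_closure(E3)
  expect_equal(A3, E3)  # depth-1 tree: ancestry equals adjacency

  E5 <- matrix(0, 5, 5)
  E5[5, 4] <- E5[5, 3] <- E5[4, 1] <- E5[4, 2] <- 1
  A5 <- transitive_closure(E5)
  expected <- E5
  expected[5, 1] <- expected[5, 2] <- 1   # grandchildren via node 4
  expect_equal(A5, expected)
})

test_that("transitive closure rejects cycles and non-trees", {
  E <- matrix(0, 3, 3)
  E[1, 2] <- E[2, 3] <- E[3, 1] <- 1       # 3-cycle
  expect_error(transitive_closure(E), "cyclic|tree")
  E2 <- matrix(0, 3, 3)
  E2[1, 3] <- E2[2, 3] <- 1                # two parents
  expect_error(transitive_closure(E2), "more than one parent")
})

test_that("transitive closure agrees with matrix-power reachability", {
  for (n in c(3L, 5L, 7L)) {
    for (s in 1:10) {
      tree <- simulate_tree(n, seed = 1000L * n + s)
      expect_equal(tree$A, reachability_by_powers(tree$E))
    }
  }
})

test_that("a clone tree round-trips through its edge list", {
  tree <- simulate_tree(7, seed = 42)
  p <- parent_vector(tree$E)
  E2 <- matrix(0, 7, 7)
  for (j in which(!is.na(p))) E2[p[j], j] <- 1
  expect_equal(E2, tree$E)
  expect_identical(validate_tree(clone_tree(E2)), character(0))
})

test_that("solution invariants are enforced by validate_solution", {
  sim <- tiny_sim(seed = 5)
  inst <- sim$instance
  truth <- sim$truth
  M <- map_to_M(truth$true_map, inst$n, inst$nr)
  sol <- clone_solution(U = truth$U, C = truth$C,
                        C_prime = truth$C[, segment_cols(inst$index)],
                        M = M, tree = truth$tree, W = truth$W, D = truth$D,
                        objective_terms = list())
  expect_identical(validate_solution(sol, inst), character(0))
  bad <- sol
  bad$U[1, 1] <- bad$U[1, 1] + 0.5
  expect_true(any(grepl("sum to 1", validate_solution(bad, inst))))
})
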