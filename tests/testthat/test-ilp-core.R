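# enumerate every feasible adjacency matrix of the ILP tree block by
# repeatedly solving and adding a no-good cut on the E cells
enumerate_trees_ilp <- function(n, max_count = 50L) {
  sim <- tiny_sim(seed = 1, n = n, m = 1, r = 1, l = 0, g = 1, cmax = 1)
  inst <- sim$instance
  U <- matrix(1 / n, 1, n)
  found <- list()
  cm <- cstep_model(inst, U)
  add_tree_constraints(cm)
  add_ancestry_constraints(cm)
  repeat {
    res <- clonedecon:::milp_solve(cm$model)
    if (res$status != "optimal") break
    E <- clonedecon:::round_integral(
      clonedecon:::milp_block(cm$model, res$x, "E", dim = c(n, n)))
    found[[length(found) + 1L]] <- E
    on_idx <- integer(0); off_idx <- integer(0)
    for (k in seq_len(nrow(cm$pairs))) {
      id <- clonedecon:::e_idx(cm, cm$pairs$i[k], cm$pairs$j[k])
      if (E[cm$pairs$i[k], cm$pairs$j[k]] > 0) on_idx <- c(on_idx, id)
      else off_idx <- c(off_idx, id)
    }
    clonedecon:::milp_add_constr(cm$model, c(on_idx, off_idx),
                                 c(rep(-1, length(on_idx)), rep(1, length(off_idx))),
                                 lb = 1 - length(on_idx))
    if (length(found) >= max_count) break
  }
  found
}

tree_key <- function(E) paste(which(E > 0), collapse = ",")

test_that("the ILP tree block admits exactly the brute-force feasible trees", {
  for (n in c(3L, 5L)) {
    ilp_trees <- enumerate_trees_ilp(n)
    oracle_trees <- enumerate_trees(n)
    expect_setequal(vapply(ilp_trees, tree_key, character(1)),
                    vapply(oracle_trees, tree_key, character(1)))
    for (E in ilp_trees) expect_equal(sum(E), n - 1)  # in-degree sum
  }
})

test_that("the ancestry block pins A to the transitive closure of every feasible tree", {
  n <- 5L
  sim <- tiny_sim(seed = 1, n = n, m = 1, r = 1, l = 0, g = 1, cmax = 1)
  U <- matrix(1 / n, 1, n)
  for (E in enumerate_trees(n)) {
    cm <- cstep_model(sim$instance, U)
    add_tree_constraints(cm)
    add_ancestry_constraints(cm)
    clonedecon:::milp_fix_vars(cm$model, cm$model$blocks$E, as.numeric(E))
    res <- clonedecon:::milp_solve(cm$model)
    expect_identical(res$status, "optimal")
    A <- clonedecon:::round_integral(
      clonedecon:::milp_block(cm$model, res$x, "A", dim = c(n, n)))
    expect_equal(A, transitive_closure(E))
    expect_equal(diag(A), rep(0, n))
  }
})

test_that("solved solutions have a normal root, and cmax = 0 is infeasible", {
  sim <- tiny_sim(seed = 3)
  inst <- sim$instance
  cm <- build_cstep_model(inst, sim$truth$U, mode = "joint")
  res <- solve_cstep(cm)
  idx <- inst$index
  expect_equal(max(res$C[inst$n, mutation_cols(idx)]), 0)
  expect_equal(unique(res$C[inst$n, segment_cols(idx)]), 1)

  inst0 <- inst
  inst0$cmax <- 0L
  cm0 <- cstep_model(inst0, sim$truth$U)
  # rebuild the copy-number bounds at cmax = 0, then require a normal root
  cm0$model$ub[cm0$model$blocks$C] <- 0
  add_tree_constraints(cm0); add_root_and_bounds(cm0)
  expect_identical(clonedecon:::milp_solve(cm0$model)$status, "infeasible")
})

test_that("the RNA mapping term equals the enumerated minimum over mappings", {
  sim <- tiny_sim(seed = 7, n = 3, m = 2, r = 2, l = 0, g = 2, cmax = 3)
  inst <- sim$instance
  truth <- sim$truth
  # perturb one RNA entry so the best mapping cost is nonzero
  inst$C_RNA[1, 1] <- max(0, inst$C_RNA[1, 1] - 1)
  cm <- build_cstep_model(inst, truth$U, mode = "joint")
  fix_model_to_truth(cm, inst, truth)
  # free M again: only the mapping is optimized, everything else is truth
  Mblk <- cm$model$blocks$M
  cm$model$lb[Mblk] <- 0; cm$model$ub[Mblk] <- 1
  res <- solve_cstep(cm)
  Cseg <- truth$C[, segment_cols(inst$index)]
  rna_direct <- sapply(clonedecon:::injective_maps(3, 3), function(mp) {
    sum(abs(Cseg - map_to_M(mp, 3, 3) %*% inst$C_RNA))
  })
  got <- evaluate_objective(inst, truth$U, res$C, res$E, res$M)
  expect_equal(got$rna, min(rna_direct))
  expect_true(all(rowSums(res$M) == 1) && all(colSums(res$M) <= 1))
})

test_that("a perfectly matched RNA matrix yields a zero RNA term and a permutation M", {
  sim <- tiny_sim(seed = 11, n = 3, m = 3, r = 2, l = 2, g = 2, cmax = 3)
  cm <- build_cstep_model(sim$instance, sim$truth$U, mode = "joint")
  res <- solve_cstep(cm)
  terms <- evaluate_objective(sim$instance, sim$truth$U, res$C, res$E, res$M)
  expect_equal(terms$rna, 0)
  expect_equal(res$C_prime, res$C[, segment_cols(sim$instance$index)])
  expect_true(all(colSums(res$M) <= 1))
})

test_that("a mutation confined to one leaf is gained on that leaf's edge", {
  # hand-built noiseless instance: n = 3, one SNV present only in leaf 1
  C_true <- rbind(c(1, 1, 1), c(0, 1, 1), c(0, 1, 1))
  idx <- variant_index(l = 0, g = 1, r = 1,
                       Q = matrix(1, 1, 1), G = matrix(0, 0, 0))
  U <- diag(3)
  inst <- problem_instance(F = U %*% C_true, C_RNA = C_true[, 2:3],
                           index = idx, n = 3, cmax = 2)
  cm <- build_cstep_model(inst, U, mode = "joint")
  res <- solve_cstep(cm)
  expect_equal(res$C, C_true, ignore_attr = TRUE)
  expect_equal(res$W[3, 1, 1], 1)   # gained on root -> leaf 1
  expect_equal(sum(res$W), 1)
})

test_that("presence in two subtrees without loss support is infeasible", {
  C_bad <- rbind(c(1, 1, 1), c(1, 1, 1), c(0, 1, 1))  # SNV in both leaves
  idx <- variant_index(l = 0, g = 1, r = 1,
                       Q = matrix(1, 1, 1), G = matrix(0, 0, 0))
  U <- diag(3)
  inst <- problem_instance(F = U %*% C_bad, C_RNA = C_bad[, 2:3],
                           index = idx, n = 3, cmax = 1)
  cm <- build_cstep_model(inst, U, mode = "joint")
  # pin the copy numbers: segments all 1 (no loss support anywhere), the
  # mutation present in both leaves, which would need two gains
  clonedecon:::milp_fix_vars(cm$model, cm$model$blocks$C, as.numeric(C_bad))
  expect_error(solve_cstep(cm), "infeasible")
})

test_that("solutions respect the assigned allele's segment copy-number bound", {
  for (s in c(2, 9)) {
    sim <- tiny_sim(seed = s, n = 3, m = 3, r = 2, l = 2, g = 2, cmax = 3)
    inst <- sim$instance
    cm <- build_cstep_model(inst, sim$truth$U, mode = "joint")
    res <- solve_cstep(cm)
    idx <- inst$index
    seg_of <- apply(idx$Q, 1, which.max)
    for (b in mutation_cols(idx)) {
      allele_col <- if (res$D[b] == 1) segment_cols(idx, "1")[seg_of[b]]
                    else segment_cols(idx, "2")[seg_of[b]]
      expect_true(all(res$C[, b] <= res$C[, allele_col]))
    }
    # paired breakends share allele and gain edge
    expect_equal(res$D[1], res$D[2])
    expect_equal(res$W[, , 1], res$W[, , 2])
  }
})

test_that("dropping the allele bound never increases the optimum objective", {
  sim <- tiny_sim(seed = 13, n = 3, m = 2, r = 2, l = 2, g = 1, cmax = 2)
  full <- solve_cstep(build_cstep_model(sim$instance, sim$truth$U, mode = "joint"))
  ablated <- solve_cstep(build_cstep_model(sim$instance, sim$truth$U,
                                           mode = "joint", allele_bound = FALSE))
  expect_lte(ablated$objective, full$objective + 1e-9)
})

test_that("the solver objective matches the direct term-by-term evaluation", {
  for (s in 4:6) {
    sim <- tiny_sim(seed = s, n = 3, m = 2, r = 2, l = 2, g = 2, cmax = 2)
    inst <- sim$instance
    U <- init_U(inst$m, inst$n, seed = s)
    cm <- build_cstep_model(inst, U, mode = "joint")
    res <- solve_cstep(cm)
    terms <- evaluate_objective(inst, U, res$C, res$E, res$M)
    expect_equal(res$objective, terms$total, tolerance = 1e-8)
    expect_equal(terms$total,
                 terms$fit + terms$rna + terms$weighted_phylo + terms$weighted_ratio)
  }
})

test_that("ground truth is always feasible in the joint model", {
  for (s in 1:4) {
    sim <- tiny_sim(seed = s, n = 5, m = 2, r = 3, l = 2, g = 3, cmax = 3)
    inst <- sim$instance
    cm <- build_cstep_model(inst, sim$truth$U, mode = "joint")
    fix_model_to_truth(cm, inst, sim$truth)
    res <- clonedecon:::milp_solve(cm$model)
    expect_identical(res$status, "optimal")
    M <- map_to_M(sim$truth$true_map, inst$n, inst$nr)
    terms <- evaluate_objective(inst, sim$truth$U, sim$truth$C,
                                sim$truth$tree$E, M)
    expect_equal(res$objective, terms$total, tolerance = 1e-8)
  }
})
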