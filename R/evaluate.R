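#' @name evaluate
#' @title Scoring against ground truth and the exhaustive oracle
#'
#' @description
#' Inferred and true clones carry arbitrary labels, so all error metrics
#' are computed after a minimum-cost one-to-one matching of clones (cost:
#' L1 distance between genotype rows, ties broken by mixture-column
#' distance, then by index). The module also provides an exhaustive
#' enumeration oracle for tiny instances that evaluates the exact objective
#' over every feasible (tree, copy-number assignment, allele assignment,
#' gain placement, RNA mapping), used to certify the ILP encoding.
NULL

#' Enumerate all feasible clone-tree adjacency matrices
#'
#' Brute force: every way to place `n - 1` edges on the admissible cells
#' (parent internal-or-root, child non-root), kept iff the root/leaf
#' degree constraints hold, there are no two-node cycles among internal
#' nodes, and the result is acyclic.
#'
#' @param n clone count (odd; practical up to n = 7)
#' @return list of binary adjacency matrices
#' @export
enumerate_trees <- function(n) {
  np <- n_leaves(n)
  cells <- expand.grid(i = seq.int(np + 1L, n), j = seq_len(n - 1L))
  cells <- cells[cells$i != cells$j, , drop = FALSE]
  combos <- utils::combn(nrow(cells), n - 1L)
  out <- list()
  for (k in seq_len(ncol(combos))) {
    E <- matrix(0, n, n)
    E[cbind(cells$i[combos[, k]], cells$j[combos[, k]])] <- 1
    if (any(E[, n] != 0)) next
    if (any(rowSums(E)[seq.int(np + 1L, n)] != 2)) next
    if (any(colSums(E)[seq_len(n - 1L)] != 1)) next
    if (n - 1L >= np + 1L) {
      internal <- seq.int(np + 1L, n - 1L)
      if (any(E[internal, internal] * t(E[internal, internal]) > 0)) next
    }
    ok <- tryCatch({ transitive_closure(E); TRUE }, error = function(e) FALSE)
    if (!ok) next
    out[[length(out) + 1L]] <- E
  }
  out
}

#' Match estimated clones to true clones
#'
#' Minimum-cost one-to-one assignment (Hungarian algorithm via
#' [clue::solve_LSAP()]) with cost the L1 distance between clonal
#' copy-number rows; ties are broken by the L1 distance between mixture
#' columns, then by lowest index. When the clone counts differ, the
#' smaller side is padded with normal-clone rows (requires `index`) and
#' zero-frequency mixture columns.
#'
#' @param C_est,C_true clonal copy-number matrices
#' @param U_est,U_true mixture matrices
#' @param index a [variant_index()]; needed only when padding
#' @return integer vector `perm`: estimated clone `i` matches true clone
#'   `perm[i]`
#' @export
match_clones <- function(C_est, U_est, C_true, U_true, index = NULL) {
  pad <- function(C, U, n_target) {
    if (nrow(C) >= n_target) return(list(C = C, U = U))
    if (is.null(index)) stop("clone counts differ; `index` is required for padding")
    extra <- n_target - nrow(C)
    normal <- c(rep(0, index$l + index$g), rep(1, 2 * index$r))
    C <- rbind(C, matrix(normal, nrow = extra, ncol = ncol(C), byrow = TRUE))
    U <- cbind(U, matrix(0, nrow(U), extra))
    list(C = C, U = U)
  }
  n <- max(nrow(C_est), nrow(C_true))
  e <- pad(C_est, U_est, n); t_ <- pad(C_true, U_true, n)
  cost1 <- matrix(0, n, n); cost2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cost1[i, j] <- sum(abs(e$C[i, ] - t_$C[j, ]))
    cost2[i, j] <- sum(abs(e$U[, i] - t_$U[, j]))
  }
  idxpen <- outer(seq_len(n), seq_len(n), function(i, j) (i - 1) * n + (j - 1))
  scale2 <- 1e-4 / (max(cost2) + 1)
  combined <- cost1 + scale2 * cost2 + 1e-10 * idxpen / (n * n)
  as.integer(clue::solve_LSAP(combined))
}

#' Root-mean-square error of mixture fractions after clone matching
#'
#' @param U_est,U_true mixture matrices (same shape after padding)
#' @param permutation from [match_clones()]
#' @export
rmse_U <- function(U_est, U_true, permutation) {
  if (!all(dim(U_est) == dim(U_true))) stop("shape mismatch")
  sqrt(mean((U_est - U_true[, permutation, drop = FALSE])^2))
}

#' Root-mean-square error of a clonal copy-number block after matching
#'
#' @param C_est,C_true clonal copy-number matrices
#' @param permutation from [match_clones()]
#' @param which `"sv"`, `"snv"` or `"segment"` column block
#' @param index a [variant_index()]
#' @export
rmse_variants <- function(C_est, C_true, permutation,
                          which = c("sv", "snv", "segment"), index) {
  which <- match.arg(which)
  cols <- switch(which,
                 sv = breakpoint_cols(index),
                 snv = snv_cols(index),
                 segment = segment_cols(index))
  if (!length(cols)) return(NA_real_)
  a <- C_est[, cols, drop = FALSE]
  b <- C_true[permutation, cols, drop = FALSE]
  sqrt(mean((a - b)^2))
}

#' Exhaustively solve a tiny instance to the global optimum
#'
#' Enumerates every feasible tree, every integer copy-number assignment
#' with a normal root and entries in `[0, cmax]`, every allele assignment
#' and gain placement satisfying the loss-supported Dollo rules and the
#' allele copy-number bound, and every injective DNA-to-RNA mapping, and
#' evaluates the exact objective with `U` fixed. Independent of the ILP
#' path; intended for instances with `n = 3`, `r <= 2`, `l + g <= 3`,
#' `cmax <= 2`.
#'
#' @param instance a [problem_instance()]
#' @param U the fixed mixture matrix
#' @param ratio_snvs include SNVs in the ratio cost
#' @param cap refuse when the candidate count (trees times copy-number
#'   assignments) exceeds this
#' @return list with `objective` (global minimum), `n_optima`, and
#'   `optimum` (one witness: `C`, `E`, `map`)
#' @export
oracle_solve <- function(instance, U, ratio_snvs = TRUE, cap = 1e6) {
  idx <- instance$index
  n <- instance$n; cmax <- instance$cmax
  nm <- idx$l + idx$g; ncolC <- n_cols(idx)
  trees <- enumerate_trees(n)
  n_cand <- (cmax + 1)^((n - 1) * ncolC) * length(trees)
  if (n_cand > cap) {
    stop(sprintf("search space too large: %.3g candidate (tree, C) pairs exceed cap %.3g",
                 n_cand, cap))
  }
  seg_of <- if (nm > 0) apply(idx$Q, 1L, which.max) else integer(0)
  s1 <- segment_cols(idx, "1"); s2 <- segment_cols(idx, "2")
  # mutation groups: breakend mate pairs share allele and gain edge
  groups <- list()
  if (idx$l > 0) {
    seen <- rep(FALSE, idx$l)
    for (b in seq_len(idx$l)) {
      if (seen[b]) next
      mate <- which(idx$G[b, ] > 0)
      groups[[length(groups) + 1L]] <- c(b, mate)
      seen[c(b, mate)] <- TRUE
    }
  }
  for (b in idx$l + seq_len(idx$g)) groups[[length(groups) + 1L]] <- b

  # all candidate C matrices: free rows 1..n-1 flattened column-major,
  # root row fixed to the normal clone
  nfree <- (n - 1L) * ncolC
  K <- (cmax + 1)^nfree
  digits <- matrix(0L, K, nfree)
  v <- seq_len(K) - 1L
  for (d in seq_len(nfree)) {
    digits[, d] <- v %% (cmax + 1L)
    v <- v %/% (cmax + 1L)
  }
  root_row <- c(rep(0, nm), rep(1, 2 * idx$r))
  # per-candidate column access: column `col`, clone `i` (i < n)
  cval <- function(i, col) digits[, (col - 1L) * (n - 1L) + i]

  # terms independent of the tree: fit and ratio
  fit <- numeric(K); rat <- numeric(K)
  pi_mat <- observed_ratios(instance$F, idx)
  rcols <- if (ratio_snvs) mutation_cols(idx) else breakpoint_cols(idx)
  for (i in seq_len(instance$m)) {
    for (col in seq_len(ncolC)) {
      uc <- U[i, n] * root_row[col]
      for (k in seq_len(n - 1L)) uc <- uc + U[i, k] * cval(k, col)
      fit <- fit + abs(instance$F[i, col] - uc)
    }
    for (b in rcols) {
      ucb <- U[i, n] * root_row[b]
      ucs <- U[i, n] * (root_row[s1[seg_of[b]]] + root_row[s2[seg_of[b]]])
      for (k in seq_len(n - 1L)) {
        ucb <- ucb + U[i, k] * cval(k, b)
        ucs <- ucs + U[i, k] * (cval(k, s1[seg_of[b]]) + cval(k, s2[seg_of[b]]))
      }
      rat <- rat + abs(ucb - pi_mat[i, b] * ucs)
    }
  }
  # minimum RNA term over injective DNA-to-RNA maps (M enumeration)
  maps <- injective_maps(n, instance$nr)
  rna_best <- rep(Inf, K); map_best <- rep(1L, K)
  for (mi in seq_along(maps)) {
    mp <- maps[[mi]]
    tot <- numeric(K)
    for (j in seq_len(2 * idx$r)) {
      tot <- tot + abs(root_row[segment_cols(idx)[j]] - instance$C_RNA[mp[n], j])
      for (k in seq_len(n - 1L)) {
        tot <- tot + abs(cval(k, segment_cols(idx)[j]) - instance$C_RNA[mp[k], j])
      }
    }
    upd <- tot < rna_best - 1e-12
    rna_best[upd] <- tot[upd]; map_best[upd] <- mi
  }

  best_obj <- Inf; n_opt <- 0L; witness <- NULL
  for (tree_i in seq_along(trees)) {
    E <- trees[[tree_i]]
    edges <- which(E > 0, arr.ind = TRUE)
    # phylogenetic cost per candidate
    phylo <- numeric(K)
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; cc <- edges[e, 2]
      for (scol in segment_cols(idx)) {
        pv <- if (p == n) rep(root_row[scol], K) else cval(p, scol)
        cv <- if (cc == n) rep(root_row[scol], K) else cval(cc, scol)
        phylo <- phylo + abs(pv - cv)
      }
    }
    # Dollo + allele feasibility: each mutation group needs some
    # (allele, gain edge) under which every candidate row is consistent
    feas <- rep(TRUE, K)
    for (grp in groups) {
      grp_ok <- rep(FALSE, K)
      for (allele in 1:2) {
        # allele copy-number bound for every clone and group member
        bound_ok <- rep(TRUE, K)
        for (b in grp) {
          sc_a <- if (allele == 1) s1[seg_of[b]] else s2[seg_of[b]]
          for (k in seq_len(n - 1L)) {
            bound_ok <- bound_ok & (cval(k, b) <= cval(k, sc_a))
          }
        }
        for (e in seq_len(nrow(edges))) {
          combo_ok <- bound_ok
          for (b in grp) {
            x <- matrix(FALSE, K, n)          # presence per clone
            for (k in seq_len(n - 1L)) x[, k] <- cval(k, b) > 0
            # presence appears only at the gain edge; losses need the
            # assigned allele's segment at zero in the child
            for (e2 in seq_len(nrow(edges))) {
              p <- edges[e2, 1]; cc <- edges[e2, 2]
              xp <- x[, p]; xc <- x[, cc]
              if (e2 != e) combo_ok <- combo_ok & !(xc & !xp)
              sc_a <- if (allele == 1) s1[seg_of[b]] else s2[seg_of[b]]
              segc <- if (cc == n) rep(root_row[sc_a], K) else cval(cc, sc_a)
              combo_ok <- combo_ok & !(xp & !xc & segc > 0)
            }
          }
          grp_ok <- grp_ok | combo_ok
        }
      }
      feas <- feas & grp_ok
    }
    total <- fit + rna_best + instance$lambda1 * phylo + instance$lambda2 * rat
    total[!feas] <- Inf
    tmin <- min(total)
    if (tmin < best_obj - 1e-9) {
      best_obj <- tmin
      n_opt <- sum(total <= tmin + 1e-9)
      kbest <- which.min(total)
      Cw <- rbind(matrix(digits[kbest, ], nrow = n - 1L), root_row)
      witness <- list(C = Cw, E = E, map = maps[[map_best[kbest]]])
    } else if (tmin <= best_obj + 1e-9) {
      n_opt <- n_opt + sum(total <= best_obj + 1e-9)
    }
  }
  if (!is.finite(best_obj)) stop("no feasible assignment found")
  list(objective = best_obj, n_optima = n_opt, optimum = witness)
}

# all injective maps from 1..n into 1..nr as integer vectors
injective_maps <- function(n, nr) {
  if (nr < n) stop("nr < n: no injective DNA-to-RNA map exists")
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in remaining) recurse(c(prefix, v), setdiff(remaining, v))
  }
  recurse(integer(0), seq_len(nr))
  out
}

#' Full evaluation report of a solution against ground truth
#'
#' @param solution a [clone_solution()]
#' @param truth a `ground_truth` from [simulate_instance()]
#' @param index the instance's [variant_index()]
#' @return list with the matching permutation and RMSEs (`u`, `sv`, `snv`,
#'   `segment`)
#' @export
evaluate_solution <- function(solution, truth, index) {
  perm <- match_clones(solution$C, solution$U, truth$C, truth$U, index = index)
  list(permutation = perm,
       rmse_u = rmse_U(solution$U, truth$U, perm),
       rmse_sv = rmse_variants(solution$C, truth$C, perm, "sv", index),
       rmse_snv = rmse_variants(solution$C, truth$C, perm, "snv", index),
       rmse_segment = rmse_variants(solution$C, truth$C, perm, "segment", index))
}
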