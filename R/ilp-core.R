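#' @name ilp_core
#' @title ILP encoding of the copy-number step
#'
#' @description
#' The C-step of the coordinate descent solves, with the mixture matrix `U`
#' held fixed, an integer linear program over the clonal copy-number matrix
#' `C`, the RNA-estimated segment block `C'`, the DNA-to-RNA clone mapping
#' `M`, the tree adjacency `E` and ancestry `A`, the mutation gain
#' placements `W`, and the allele assignment `D`. Each constraint family is
#' added by its own builder so the blocks can be tested (and ablated)
#' independently:
#'
#' * tree constraints: root has no incoming edge, leaves no outgoing edge,
#'   internal nodes and the root have out-degree 2, non-root nodes in-degree
#'   1, no two-node cycles among internal nodes;
#' * ancestry constraints: `A` is forced to be exactly the transitive
#'   closure of `E` (which also excludes longer cycles, since a cycle would
#'   imply a self-ancestor);
#' * root normality and copy-number bounds: the root is a normal clone (zero
#'   mutation copies, one copy per allele per segment), all copy numbers at
#'   most `cmax`;
#' * RNA mapping: `M` assigns each DNA clone exactly one RNA clone and each
#'   RNA clone to at most one DNA clone, with L1 slack variables measuring
#'   `|C' - M C_RNA|` and `C'` tied to the segment block of `C`;
#' * loss-supported Dollo constraints with per-mutation allele assignment:
#'   each mutation is gained on exactly one tree edge, presence can only
#'   appear at the gain edge, a parent-present/child-absent loss is allowed
#'   only when the child's copy of the assigned allele's segment is zero,
#'   and a mutation's copy number never exceeds its assigned allele's
#'   segment copy number; paired breakends share allele and gain edge;
#' * the phylogenetic cost `R` and the ratio-consistency cost `S`,
#'   linearized with slack variables and edge-activated big-M rows.
NULL

#' Create an empty C-step model for an instance with U fixed
#'
#' @param instance a [problem_instance()]
#' @param U the fixed `m x n` mixture matrix
#' @return an environment of class `cstep_model` wrapping a MILP model plus
#'   the instance, the edge-candidate list and bookkeeping
#' @export
cstep_model <- function(instance, U) {
  if (instance$nr < instance$n) {
    stop("nr < n: each DNA clone needs its own RNA clone (mapping rows sum ",
         "to 1 while columns sum to <= 1); merge RNA clones or lower n")
  }
  cm <- new.env(parent = emptyenv())
  cm$instance <- instance
  cm$U <- as.matrix(U)
  cm$model <- milp_model()
  n <- instance$n
  np <- n_leaves(n)
  # candidate directed edges: parent internal-or-root, child non-root
  pairs <- expand.grid(i = seq.int(np + 1L, n), j = seq_len(n - 1L))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  rownames(pairs) <- NULL
  cm$pairs <- pairs
  idx <- instance$index
  nm <- idx$l + idx$g
  ncolC <- n_cols(idx)
  # core variable blocks shared by every stage
  milp_add_vars(cm$model, "C", n * ncolC, lb = 0, ub = instance$cmax, type = "integer")
  milp_add_vars(cm$model, "E", n * n, lb = 0, ub = 0, type = "binary")
  milp_add_vars(cm$model, "A", n * n, lb = 0, ub = 0, type = "binary")
  # open only the admissible cells of E and A
  for (k in seq_len(nrow(pairs))) {
    cm$model$ub[e_idx(cm, pairs$i[k], pairs$j[k])] <- 1
  }
  anc <- seq.int(np + 1L, n)                   # only internal/root can be ancestors
  for (i in anc) for (j in seq_len(n - 1L)) {
    if (i != j) cm$model$ub[a_idx(cm, i, j)] <- 1
  }
  # segment-of-mutation lookup (each Q row selects exactly one segment)
  cm$seg_of <- if (nm > 0) apply(idx$Q, 1L, which.max) else integer(0)
  class(cm) <- "cstep_model"
  cm
}

# --- index helpers over the flattened blocks (column-major, like R matrices)
c_idx <- function(cm, i, col) cm$model$blocks$C[(col - 1L) * cm$instance$n + i]
e_idx <- function(cm, i, j) cm$model$blocks$E[(j - 1L) * cm$instance$n + i]
a_idx <- function(cm, i, j) cm$model$blocks$A[(j - 1L) * cm$instance$n + i]

#' Add the rooted-binary-tree constraints on the adjacency matrix E
#'
#' Encodes: no edge into the root; no edge out of a leaf (enforced by the
#' variable bounds set at model creation); out-degree exactly 2 for internal
#' nodes and the root; in-degree exactly 1 for every non-root node; no
#' two-node cycles among internal nodes.
#'
#' @param cm a [cstep_model()]
#' @return the model, invisibly (constraints are added in place)
#' @export
add_tree_constraints <- function(cm) {
  n <- cm$instance$n
  np <- n_leaves(n)
  rows <- list()
  for (i in seq.int(np + 1L, n)) {      # out-degree 2
    js <- setdiff(seq_len(n - 1L), i)
    rows[[length(rows) + 1L]] <- list(idx = e_idx(cm, i, js), coef = rep(1, length(js)),
                                      lb = 2, ub = 2)
  }
  for (j in seq_len(n - 1L)) {          # in-degree 1
    is <- setdiff(seq.int(np + 1L, n), j)
    rows[[length(rows) + 1L]] <- list(idx = e_idx(cm, is, j), coef = rep(1, length(is)),
                                      lb = 1, ub = 1)
  }
  if (n - 1L >= np + 1L) {              # no 2-cycles among internal nodes
    internal <- seq.int(np + 1L, n - 1L)
    for (i in internal) for (j in internal) {
      if (i < j) rows[[length(rows) + 1L]] <-
          list(idx = c(e_idx(cm, i, j), e_idx(cm, j, i)), coef = c(1, 1), ub = 1)
    }
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Add the ancestry constraints tying A to the transitive closure of E
#'
#' A parent is an ancestor, and a child inherits all of its parent's
#' ancestors (a two-sided sandwich per candidate edge). Together with the
#' fixed zeros (no ancestor of the root, no self-ancestry, leaves are never
#' ancestors) this pins `A` to exactly the transitive closure of any
#' feasible `E`, and excludes directed cycles outright.
#'
#' @param cm a [cstep_model()]
#' @export
add_ancestry_constraints <- function(cm) {
  n <- cm$instance$n
  rows <- list()
  for (k in seq_len(nrow(cm$pairs))) {
    i <- cm$pairs$i[k]; j <- cm$pairs$j[k]
    rows[[length(rows) + 1L]] <- list(idx = c(a_idx(cm, i, j), e_idx(cm, i, j)),
                                      coef = c(1, -1), lb = 0)
    for (kk in seq_len(n)) {
      if (kk == i) next
      # A[kk,j] >= A[kk,i] + E[i,j] - 1   and   A[kk,j] <= A[kk,i] - E[i,j] + 1
      rows[[length(rows) + 1L]] <- list(
        idx = c(a_idx(cm, kk, j), a_idx(cm, kk, i), e_idx(cm, i, j)),
        coef = c(1, -1, -1), lb = -1)
      rows[[length(rows) + 1L]] <- list(
        idx = c(a_idx(cm, kk, j), a_idx(cm, kk, i), e_idx(cm, i, j)),
        coef = c(1, -1, 1), ub = 1)
    }
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Fix the root row to a normal clone and bound all copy numbers
#'
#' The root carries no mutations and one copy per allele of every segment;
#' every copy number is bounded by `cmax` (already imposed through the
#' variable bounds at creation, restated here for the root row).
#'
#' @param cm a [cstep_model()]
#' @export
add_root_and_bounds <- function(cm) {
  idx <- cm$instance$index
  n <- cm$instance$n
  mut <- mutation_cols(idx)
  if (length(mut)) milp_fix_vars(cm$model, c_idx(cm, n, mut), rep(0, length(mut)))
  seg <- segment_cols(idx)
  sidx <- c_idx(cm, n, seg)
  # equality at 1, but never relaxing the cmax variable bound, so cmax = 0
  # is correctly infeasible
  cm$model$lb[sidx] <- 1
  cm$model$ub[sidx] <- pmin(cm$model$ub[sidx], 1)
  invisible(cm)
}

#' Add the DNA-to-RNA clone mapping and its L1 consistency term
#'
#' Creates `M` (binary, rows sum to 1, columns sum to at most 1), the
#' RNA-estimated segment block `C'` tied entrywise to the segment columns of
#' `C`, and slack variables whose sum equals `|C' - M C_RNA|` at the
#' optimum.
#'
#' @param cm a [cstep_model()]
#' @export
add_rna_mapping <- function(cm) {
  inst <- cm$instance
  idx <- inst$index
  n <- inst$n; nr <- inst$nr; r2 <- 2L * idx$r
  M <- milp_add_vars(cm$model, "M", n * nr, type = "binary")
  Cp <- milp_add_vars(cm$model, "Cp", n * r2, lb = 0, ub = inst$cmax, type = "integer")
  Cdel <- milp_add_vars(cm$model, "Cdel", n * r2, lb = 0, ub = MILP_INF)
  m_idx <- function(i, k) M[(k - 1L) * n + i]
  cp_idx <- function(i, j) Cp[(j - 1L) * n + i]
  cd_idx <- function(i, j) Cdel[(j - 1L) * n + i]
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- list(idx = m_idx(i, seq_len(nr)), coef = rep(1, nr),
                                      lb = 1, ub = 1)
  }
  for (k in seq_len(nr)) {
    rows[[length(rows) + 1L]] <- list(idx = m_idx(seq_len(n), k), coef = rep(1, n),
                                      ub = 1)
  }
  seg <- segment_cols(idx)
  for (i in seq_len(n)) for (j in seq_len(r2)) {
    # C' tied to the segment block of C
    rows[[length(rows) + 1L]] <- list(idx = c(cp_idx(i, j), c_idx(cm, i, seg[j])),
                                      coef = c(1, -1), lb = 0, ub = 0)
    # Cdel >= +/- (C' - (M C_RNA)) entrywise
    mk <- m_idx(i, seq_len(nr))
    cr <- inst$C_RNA[, j]
    rows[[length(rows) + 1L]] <- list(idx = c(cd_idx(i, j), cp_idx(i, j), mk),
                                      coef = c(1, -1, cr), lb = 0)
    rows[[length(rows) + 1L]] <- list(idx = c(cd_idx(i, j), cp_idx(i, j), mk),
                                      coef = c(1, 1, -cr), lb = 0)
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Add the loss-supported Dollo constraints and allele assignment
#'
#' Introduces the gain placements `W` (one per candidate edge and mutation),
#' the allele assignment `D`, and presence indicators `x` linked to `C` by
#' `x <= C <= cmax * x`. Presence propagates only through the single gain
#' edge, losses require the child's assigned-allele segment copy number to
#' be zero, mutation copy numbers are bounded by the assigned allele's
#' segment copy number, and paired breakends share both allele and gain
#' edge.
#'
#' @param cm a [cstep_model()]
#' @param allele_bound keep the allele copy-number bound (the constraint
#'   that a mutation's copy number cannot exceed its assigned allele's
#'   segment copy number); `FALSE` drops it, for ablation studies
#' @export
add_dollo_and_allele <- function(cm, allele_bound = TRUE) {
  inst <- cm$instance
  idx <- inst$index
  n <- inst$n; nm <- idx$l + idx$g; cmax <- inst$cmax
  if (nm == 0) return(invisible(cm))
  npair <- nrow(cm$pairs)
  W <- milp_add_vars(cm$model, "W", npair * nm, type = "binary")
  D <- milp_add_vars(cm$model, "D", nm, type = "binary")
  X <- milp_add_vars(cm$model, "X", n * nm, type = "binary")
  w_idx <- function(p, b) W[(b - 1L) * npair + p]
  x_idx <- function(i, b) X[(b - 1L) * n + i]
  milp_fix_vars(cm$model, x_idx(n, seq_len(nm)), rep(0, nm))  # root carries nothing
  s1 <- segment_cols(idx, "1"); s2 <- segment_cols(idx, "2")
  rows <- list()
  for (b in seq_len(nm)) {
    # gained exactly once, and only on an actual edge
    rows[[length(rows) + 1L]] <- list(idx = w_idx(seq_len(npair), b),
                                      coef = rep(1, npair), lb = 1, ub = 1)
    sb <- cm$seg_of[b]
    for (p in seq_len(npair)) {
      i <- cm$pairs$i[p]; j <- cm$pairs$j[p]
      rows[[length(rows) + 1L]] <- list(idx = c(w_idx(p, b), e_idx(cm, i, j)),
                                        coef = c(1, -1), ub = 0)
      # presence appears only at the gain edge: x_j <= x_i + W + (1 - E)
      rows[[length(rows) + 1L]] <- list(
        idx = c(x_idx(j, b), x_idx(i, b), w_idx(p, b), e_idx(cm, i, j)),
        coef = c(1, -1, -1, 1), ub = 1)
      # loss support: E=1, parent present, child absent => child's
      # assigned-allele segment copy number is zero
      rows[[length(rows) + 1L]] <- list(
        idx = c(c_idx(cm, j, s1[sb]), e_idx(cm, i, j), x_idx(i, b), x_idx(j, b), D[b]),
        coef = c(1, cmax, cmax, -cmax, cmax), ub = 3 * cmax)
      rows[[length(rows) + 1L]] <- list(
        idx = c(c_idx(cm, j, s2[sb]), e_idx(cm, i, j), x_idx(i, b), x_idx(j, b), D[b]),
        coef = c(1, cmax, cmax, -cmax, -cmax), ub = 2 * cmax)
    }
    for (i in seq_len(n)) {
      # presence indicator: x <= C <= cmax * x
      rows[[length(rows) + 1L]] <- list(idx = c(x_idx(i, b), c_idx(cm, i, b)),
                                        coef = c(1, -1), ub = 0)
      rows[[length(rows) + 1L]] <- list(idx = c(c_idx(cm, i, b), x_idx(i, b)),
                                        coef = c(1, -cmax), ub = 0)
      if (allele_bound) {
        # allele bound: C[i,b] <= seg_allele1 + (1-D)cmax ; <= seg_allele2 + D cmax
        rows[[length(rows) + 1L]] <- list(
          idx = c(c_idx(cm, i, b), c_idx(cm, i, s1[sb]), D[b]),
          coef = c(1, -1, cmax), ub = cmax)
        rows[[length(rows) + 1L]] <- list(
          idx = c(c_idx(cm, i, b), c_idx(cm, i, s2[sb]), D[b]),
          coef = c(1, -1, -cmax), ub = 0)
      }
    }
  }
  # paired breakends share allele assignment and gain edge
  if (idx$l > 0) {
    for (b in seq_len(idx$l)) {
      mate <- which(idx$G[b, ] > 0)
      if (length(mate) == 1 && mate > b) {
        rows[[length(rows) + 1L]] <- list(idx = c(D[b], D[mate]), coef = c(1, -1),
                                          lb = 0, ub = 0)
        for (p in seq_len(npair)) {
          rows[[length(rows) + 1L]] <- list(idx = c(w_idx(p, b), w_idx(p, mate)),
                                            coef = c(1, -1), lb = 0, ub = 0)
        }
      }
    }
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Add the linearized phylogenetic cost R
#'
#' Per candidate edge, auxiliary variables bound the per-segment-column
#' absolute copy-number differences, and an edge-activated row (big-M equal
#' to `2r * cmax`, the tightest valid bound) accumulates them into a
#' per-edge cost that is zero on non-edges.
#'
#' @param cm a [cstep_model()]
#' @export
add_phylo_cost <- function(cm) {
  inst <- cm$instance
  idx <- inst$index
  r2 <- 2L * idx$r
  npair <- nrow(cm$pairs)
  bigM <- r2 * inst$cmax
  Dv <- milp_add_vars(cm$model, "phylo_d", npair * r2, lb = 0, ub = MILP_INF)
  rho <- milp_add_vars(cm$model, "phylo_rho", npair, lb = 0, ub = MILP_INF)
  d_idx <- function(p, s) Dv[(s - 1L) * npair + p]
  seg <- segment_cols(idx)
  rows <- list()
  for (p in seq_len(npair)) {
    i <- cm$pairs$i[p]; j <- cm$pairs$j[p]
    for (s in seq_len(r2)) {
      rows[[length(rows) + 1L]] <- list(
        idx = c(d_idx(p, s), c_idx(cm, i, seg[s]), c_idx(cm, j, seg[s])),
        coef = c(1, -1, 1), lb = 0)
      rows[[length(rows) + 1L]] <- list(
        idx = c(d_idx(p, s), c_idx(cm, i, seg[s]), c_idx(cm, j, seg[s])),
        coef = c(1, 1, -1), lb = 0)
    }
    # rho >= sum_s d - bigM * (1 - E)
    rows[[length(rows) + 1L]] <- list(
      idx = c(rho[p], d_idx(p, seq_len(r2)), e_idx(cm, i, j)),
      coef = c(1, rep(-1, r2), -bigM), lb = -bigM)
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Add the ratio-consistency slack variables for the S term
#'
#' For each sample and each mutation column in scope, a slack variable
#' bounds the absolute difference between the estimated mixture copy number
#' at the mutation and the observed ratio times the estimated mixture copy
#' number of its containing segment. The observed ratios are constants
#' computed from `F` (zero when a segment has zero observed copies).
#'
#' @param cm a [cstep_model()]
#' @param ratio_snvs include SNV columns (default) or breakpoints only
#' @export
add_ratio_term <- function(cm, ratio_snvs = TRUE) {
  inst <- cm$instance
  idx <- inst$index
  cols <- if (ratio_snvs) mutation_cols(idx) else breakpoint_cols(idx)
  cm$ratio_cols <- cols
  if (!length(cols)) return(invisible(cm))
  m <- inst$m; n <- inst$n
  pi_mat <- observed_ratios(inst$F, idx)
  S <- milp_add_vars(cm$model, "sslack", m * length(cols), lb = 0, ub = MILP_INF)
  s_idx <- function(i, bpos) S[(bpos - 1L) * m + i]
  s1 <- segment_cols(idx, "1"); s2 <- segment_cols(idx, "2")
  rows <- list()
  for (bpos in seq_along(cols)) {
    b <- cols[bpos]
    sb <- cm$seg_of[b]
    for (i in seq_len(m)) {
      u <- cm$U[i, ]
      # slack >= +/- ( (UC)[i,b] - pi * ((UC)[i,seg1] + (UC)[i,seg2]) )
      vidx <- c(c_idx(cm, seq_len(n), b),
                c_idx(cm, seq_len(n), s1[sb]), c_idx(cm, seq_len(n), s2[sb]))
      vcoef <- c(u, -pi_mat[i, b] * u, -pi_mat[i, b] * u)
      rows[[length(rows) + 1L]] <- list(idx = c(s_idx(i, bpos), vidx),
                                        coef = c(1, -vcoef), lb = 0)
      rows[[length(rows) + 1L]] <- list(idx = c(s_idx(i, bpos), vidx),
                                        coef = c(1, vcoef), lb = 0)
    }
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Add the deconvolution-fit slack variables for |F - UC|
#'
#' @param cm a [cstep_model()]
#' @param cols variant columns to include (defaults to all)
#' @export
add_fit_term <- function(cm, cols = NULL) {
  inst <- cm$instance
  if (is.null(cols)) cols <- seq_len(n_cols(inst$index))
  cm$fit_cols <- cols
  if (!length(cols)) return(invisible(cm))
  m <- inst$m; n <- inst$n
  Fs <- milp_add_vars(cm$model, "fslack", m * length(cols), lb = 0, ub = MILP_INF)
  f_idx <- function(i, cpos) Fs[(cpos - 1L) * m + i]
  rows <- list()
  for (cpos in seq_along(cols)) {
    col <- cols[cpos]
    cvars <- c_idx(cm, seq_len(n), col)
    for (i in seq_len(m)) {
      u <- cm$U[i, ]
      f <- inst$F[i, col]
      rows[[length(rows) + 1L]] <- list(idx = c(f_idx(i, cpos), cvars),
                                        coef = c(1, u), lb = f)
      rows[[length(rows) + 1L]] <- list(idx = c(f_idx(i, cpos), cvars),
                                        coef = c(1, -u), lb = -f)
    }
  }
  milp_add_constrs(cm$model, rows)
  invisible(cm)
}

#' Assemble the weighted objective from the slack blocks present
#'
#' Objective = sum of fit slacks + sum of RNA mapping slacks
#' + lambda1 * sum of per-edge phylogenetic costs
#' + lambda2 * sum of ratio slacks; blocks that were not added contribute
#' nothing.
#'
#' @param cm a [cstep_model()]
#' @export
assemble_objective <- function(cm) {
  b <- cm$model$blocks
  inst <- cm$instance
  if (!is.null(b$fslack)) milp_set_obj(cm$model, b$fslack, rep(1, length(b$fslack)))
  if (!is.null(b$Cdel)) milp_set_obj(cm$model, b$Cdel, rep(1, length(b$Cdel)))
  if (!is.null(b$phylo_rho)) milp_set_obj(cm$model, b$phylo_rho,
                                          rep(inst$lambda1, length(b$phylo_rho)))
  if (!is.null(b$sslack)) milp_set_obj(cm$model, b$sslack,
                                       rep(inst$lambda2, length(b$sslack)))
  invisible(cm)
}

#' Build a complete C-step model
#'
#' @param instance a [problem_instance()]
#' @param U fixed mixture matrix
#' @param mode `"joint"` builds the full model (tree, ancestry, root, RNA
#'   mapping, Dollo, phylogenetic and ratio costs, full fit term);
#'   `"segment"` builds the first stage only (no Dollo/ratio, fit restricted
#'   to segment columns, mutation copy numbers pinned to zero).
#' @param ratio_snvs include SNVs in the ratio term (see [add_ratio_term()])
#' @param allele_bound see [add_dollo_and_allele()]
#' @return a [cstep_model()] ready to solve
#' @export
build_cstep_model <- function(instance, U, mode = c("joint", "segment"),
                              ratio_snvs = TRUE, allele_bound = TRUE) {
  mode <- match.arg(mode)
  cm <- cstep_model(instance, U)
  add_tree_constraints(cm)
  add_ancestry_constraints(cm)
  add_root_and_bounds(cm)
  add_rna_mapping(cm)
  add_phylo_cost(cm)
  idx <- instance$index
  if (mode == "joint") {
    add_dollo_and_allele(cm, allele_bound = allele_bound)
    add_ratio_term(cm, ratio_snvs = ratio_snvs)
    add_fit_term(cm)
  } else {
    mut <- mutation_cols(idx)
    if (length(mut)) {
      for (i in seq_len(instance$n)) {
        milp_fix_vars(cm$model, c_idx(cm, i, mut), rep(0, length(mut)))
      }
    }
    add_fit_term(cm, cols = segment_cols(idx))
  }
  assemble_objective(cm)
  cm
}

#' Fix tree, mapping and segment copy numbers from a first-stage result
#'
#' Used by the two-stage C-step: the second stage rebuilds the joint model
#' and pins `E`, `A`, `M`, `C'` and the segment columns of `C` to the
#' first-stage solution, leaving only the mutation columns, gain placements
#' and allele assignments free.
#'
#' @param cm a joint [cstep_model()]
#' @param stage1 the extracted first-stage solution (list with `E`, `A`,
#'   `M`, `C_seg`)
#' @export
fix_stage1 <- function(cm, stage1) {
  inst <- cm$instance
  n <- inst$n
  milp_fix_vars(cm$model, cm$model$blocks$E, as.numeric(stage1$E))
  milp_fix_vars(cm$model, cm$model$blocks$A, as.numeric(stage1$A))
  milp_fix_vars(cm$model, cm$model$blocks$M, as.numeric(stage1$M))
  milp_fix_vars(cm$model, cm$model$blocks$Cp, as.numeric(stage1$C_seg))
  seg <- segment_cols(inst$index)
  for (j in seq_along(seg)) {
    milp_fix_vars(cm$model, c_idx(cm, seq_len(n), seg[j]), stage1$C_seg[, j])
  }
  invisible(cm)
}

#' Solve a C-step model and extract the decision matrices
#'
#' @param cm a [cstep_model()]
#' @param time_limit wall-clock limit in seconds (`NULL` for none)
#' @return a list with `C`, `C_prime`, `M`, `E`, `A`, `W` (array, `NULL`
#'   when the Dollo block is absent), `D`, `X`, solver `status`, `objective`
#'   and `mip_gap`
#' @export
solve_cstep <- function(cm, time_limit = NULL) {
  res <- milp_solve(cm$model, time_limit = time_limit)
  if (is.null(res$x)) {
    stop("C-step ", res$status, ": no incumbent solution (", res$message, ")")
  }
  inst <- cm$instance
  idx <- inst$index
  n <- inst$n; nm <- idx$l + idx$g
  x <- res$x
  C <- round_integral(milp_block(cm$model, x, "C", dim = c(n, n_cols(idx))))
  E <- round_integral(milp_block(cm$model, x, "E", dim = c(n, n)))
  A <- round_integral(milp_block(cm$model, x, "A", dim = c(n, n)))
  M <- round_integral(milp_block(cm$model, x, "M", dim = c(n, inst$nr)))
  Cp <- round_integral(milp_block(cm$model, x, "Cp", dim = c(n, 2L * idx$r)))
  W <- NULL; D <- NULL; X <- NULL
  if (!is.null(cm$model$blocks$W) && nm > 0) {
    wflat <- round_integral(milp_block(cm$model, x, "W"))
    W <- array(0, dim = c(n, n, nm))
    npair <- nrow(cm$pairs)
    for (b in seq_len(nm)) for (p in seq_len(npair)) {
      W[cm$pairs$i[p], cm$pairs$j[p], b] <- wflat[(b - 1L) * npair + p]
    }
    D <- round_integral(milp_block(cm$model, x, "D"))
    X <- round_integral(milp_block(cm$model, x, "X", dim = c(n, nm)))
  }
  list(C = C, C_prime = Cp, M = M, E = E, A = A, W = W, D = D, X = X,
       status = res$status, objective = res$objective, mip_gap = res$mip_gap)
}
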