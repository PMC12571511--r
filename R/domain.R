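#' @name domain
#' @title Shared data model and index conventions
#'
#' @description
#' The whole package works over one fixed column layout for the variant axis:
#' columns `1..l` are SV breakpoint ends, `l+1..l+g` are SNVs,
#' `l+g+1..l+g+r` are allele-1 segment copy numbers and
#' `l+g+r+1..l+g+2r` are allele-2 segment copy numbers. Clone (tree node)
#' indices are also fixed: with `n` clones and `n' = (n+1)/2`, nodes
#' `1..n'` are leaves, `n'+1..n-1` internal, and node `n` is the root (the
#' normal clone). These conventions make every matrix in the model directly
#' comparable across modules.
NULL

#' Variant index: column layout, segment membership and breakend pairing
#'
#' @param l number of SV breakpoint ends (must be even; mates are paired in
#'   `G`)
#' @param g number of SNVs
#' @param r number of genomic segments
#' @param Q binary `(l+g) x r` matrix; `Q[i,j] = 1` iff breakpoint/SNV `i`
#'   lies in segment `j`
#' @param G binary symmetric `l x l` matrix pairing breakend mates
#'   (zero diagonal, one mate per row); may be a 0 x 0 matrix when `l = 0`
#' @param segment_coords data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per segment
#' @param variant_ids character identifiers for all `l+g+2r` columns;
#'   generated when `NULL`
#' @return an object of class `variant_index`
#' @export
variant_index <- function(l, g, r, Q, G,
                          segment_coords = NULL, variant_ids = NULL) {
  l <- as.integer(l); g <- as.integer(g); r <- as.integer(r)
  Q <- as.matrix(Q); storage.mode(Q) <- "double"
  G <- as.matrix(G); storage.mode(G) <- "double"
  if (is.null(segment_coords)) {
    segment_coords <- data.frame(
      chrom = rep("chr1", r),
      start = (seq_len(r) - 1L) * 1e6,
      end = seq_len(r) * 1e6
    )
  }
  if (is.null(variant_ids)) {
    variant_ids <- c(
      if (l > 0) paste0("bp", seq_len(l)) else character(0),
      if (g > 0) paste0("snv", seq_len(g)) else character(0),
      paste0("seg", seq_len(r), "_a1"),
      paste0("seg", seq_len(r), "_a2")
    )
  }
  structure(
    list(l = l, g = g, r = r, Q = Q, G = G,
         segment_coords = segment_coords, variant_ids = variant_ids),
    class = "variant_index"
  )
}

#' Column index helpers for the fixed variant layout
#'
#' @param index a `variant_index`
#' @return integer column positions of the requested block
#' @export
mutation_cols <- function(index) seq_len(index$l + index$g)

#' @rdname mutation_cols
#' @export
breakpoint_cols <- function(index) seq_len(index$l)

#' @rdname mutation_cols
#' @export
snv_cols <- function(index) index$l + seq_len(index$g)

#' @rdname mutation_cols
#' @export
segment_cols <- function(index, allele = c("both", "1", "2")) {
  allele <- match.arg(allele)
  base <- index$l + index$g
  switch(allele,
         "1" = base + seq_len(index$r),
         "2" = base + index$r + seq_len(index$r),
         both = base + seq_len(2L * index$r))
}

#' Total number of variant columns (l + g + 2r)
#' @param index a `variant_index`
#' @export
n_cols <- function(index) index$l + index$g + 2L * index$r

#' Problem instance: all constant inputs of one deconvolution run
#'
#' @param F nonnegative `m x (l+g+2r)` matrix of average variant copy numbers
#'   per sample
#' @param C_RNA nonnegative integer `nr x 2r` matrix of clone-level
#'   allele-specific segment copy numbers derived from scRNA-seq
#' @param index a [variant_index()]
#' @param n requested DNA clone count (odd, >= 3)
#' @param cmax maximum copy number bound
#' @param lambda1,lambda2 regularization weights; computed with
#'   [compute_lambdas()] when `NULL`
#' @return an object of class `problem_instance`
#' @export
problem_instance <- function(F, C_RNA, index, n, cmax = 4,
                             lambda1 = NULL, lambda2 = NULL) {
  F <- as.matrix(F); storage.mode(F) <- "double"
  C_RNA <- as.matrix(C_RNA); storage.mode(C_RNA) <- "double"
  if (is.null(lambda1) || is.null(lambda2)) {
    lam <- compute_lambdas(index$l, index$g, index$r, nrow(F), n)
    if (is.null(lambda1)) lambda1 <- lam$lambda1
    if (is.null(lambda2)) lambda2 <- lam$lambda2
  }
  structure(
    list(F = F, C_RNA = C_RNA, index = index,
         n = as.integer(n), m = nrow(F), nr = nrow(C_RNA),
         cmax = as.integer(cmax),
         lambda1 = lambda1, lambda2 = lambda2),
    class = "problem_instance"
  )
}

#' Number of leaves n' = (n+1)/2 of the rooted binary clone tree
#' @param n clone count (odd)
#' @export
n_leaves <- function(n) (n + 1L) %/% 2L

#' Clone tree: adjacency and ancestry under the fixed node convention
#'
#' @param E binary `n x n` adjacency; `E[i,j] = 1` iff clone `i` is the
#'   parent of clone `j`. Leaves are `1..n'`, internal nodes `n'+1..n-1`,
#'   the root is node `n`.
#' @param A optional ancestry matrix; computed as the transitive closure of
#'   `E` when `NULL`.
#' @return an object of class `clone_tree` with elements `E`, `A`, `n`
#' @export
clone_tree <- function(E, A = NULL) {
  E <- as.matrix(E); storage.mode(E) <- "double"
  n <- nrow(E)
  if (is.null(A)) A <- transitive_closure(E)
  structure(list(E = E, A = A, n = as.integer(n)), class = "clone_tree")
}

#' Transitive closure of a tree adjacency matrix
#'
#' Returns the ancestry matrix `A` with `A[i,j] = 1` iff a directed path
#' `i -> ... -> j` exists in `E`. Errors on cyclic or non-tree input.
#'
#' @param E binary `n x n` adjacency matrix
#' @return binary `n x n` ancestry matrix
#' @export
transitive_closure <- function(E) {
  E <- as.matrix(E)
  n <- nrow(E)
  if (n != ncol(E)) stop("adjacency matrix must be square")
  if (any(E != 0 & E != 1)) stop("adjacency matrix must be binary")
  if (any(colSums(E) > 1)) stop("not a tree: a node has more than one parent")
  # Warshall over boolean reachability
  A <- E > 0
  for (k in seq_len(n)) {
    A <- A | (A[, k] %o% A[k, ] > 0)
  }
  if (any(diag(A))) stop("cyclic adjacency: not a tree")
  storage.mode(A) <- "double"
  A
}

#' Parent lookup vector from an adjacency matrix
#'
#' @param E binary adjacency
#' @return integer vector `p` with `p[j]` the parent of `j` (`NA` for the
#'   root)
#' @export
parent_vector <- function(E) {
  n <- nrow(E)
  p <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    par <- which(E[, j] > 0)
    if (length(par) > 1) stop("node ", j, " has multiple parents")
    if (length(par) == 1) p[j] <- par
  }
  p
}

#' Assemble a full solution object
#'
#' @param U `m x n` mixture matrix
#' @param C integer `n x (l+g+2r)` clonal copy-number matrix
#' @param C_prime integer `n x 2r` RNA-estimated segment copy numbers
#' @param M binary `n x nr` DNA-to-RNA clone mapping
#' @param tree a [clone_tree()]
#' @param W binary `n x n x (l+g)` array of mutation gain placements
#' @param D binary length-`l+g` allele assignment vector
#' @param objective_terms named list with elements `fit`, `rna`, `phylo`,
#'   `ratio`, `total`
#' @return an object of class `clone_solution`
#' @export
clone_solution <- function(U, C, C_prime, M, tree, W, D, objective_terms) {
  structure(
    list(U = U, C = C, C_prime = C_prime, M = M, tree = tree,
         W = W, D = D, objective_terms = objective_terms),
    class = "clone_solution"
  )
}

#' Validate a problem instance
#'
#' Checks every structural invariant of the instance and its variant index
#' and returns a character vector of violations (empty when valid). This is
#' a reporting operation: it never throws.
#'
#' @param instance a [problem_instance()]
#' @return character vector of violation messages; `character(0)` when valid
#' @export
validate_instance <- function(instance) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  idx <- instance$index
  l <- idx$l; g <- idx$g; r <- idx$r
  n <- instance$n

  if (n < 3 || n %% 2 == 0) {
    add(sprintf("n must be odd and >= 3 (rooted binary tree with (n+1)/2 leaves); got n=%d", n))
  }
  if (l %% 2 != 0) add(sprintf("l must be even (breakends come in mate pairs); got l=%d", l))

  if (!all(dim(idx$Q) == c(l + g, r))) {
    add(sprintf("Q must be (l+g) x r = %d x %d; got %d x %d",
                l + g, r, nrow(idx$Q), ncol(idx$Q)))
  } else {
    bad <- which(rowSums(idx$Q) != 1)
    for (i in bad) add(sprintf("Q row %d must sum to exactly 1 (one containing segment); sums to %g",
                               i, sum(idx$Q[i, ])))
  }
  if (!all(dim(idx$G) == c(l, l))) {
    add(sprintf("G must be l x l = %d x %d; got %d x %d", l, l, nrow(idx$G), ncol(idx$G)))
  } else if (l > 0) {
    if (!isTRUE(all.equal(idx$G, t(idx$G)))) add("G must be symmetric")
    if (any(diag(idx$G) != 0)) add("G must have a zero diagonal")
    bad <- which(rowSums(idx$G) != 1)
    for (i in bad) add(sprintf("G row %d must sum to exactly 1 (one mate per breakend); sums to %g",
                               i, sum(idx$G[i, ])))
  }

  if (ncol(instance$F) != l + g + 2 * r) {
    add(sprintf("F must have l+g+2r = %d columns; got %d", l + g + 2 * r, ncol(instance$F)))
  }
  if (any(instance$F < 0)) add("F has negative entries")
  if (ncol(instance$C_RNA) != 2 * r) {
    add(sprintf("C_RNA must have 2r = %d columns; got %d", 2 * r, ncol(instance$C_RNA)))
  }
  if (any(instance$C_RNA < 0)) add("C_RNA has negative entries")
  if (any(instance$C_RNA > instance$cmax)) add("C_RNA has entries exceeding cmax")
  if (any(instance$C_RNA != round(instance$C_RNA))) add("C_RNA must be integer-valued")
  if (instance$cmax < 1) add("cmax must be >= 1 (the root is diploid per allele)")
  if (!is.finite(instance$lambda1) || instance$lambda1 <= 0) add("lambda1 must be > 0")
  if (!is.finite(instance$lambda2) || instance$lambda2 <= 0) add("lambda2 must be > 0")
  v
}

#' Validate a clone tree against the node-convention invariants
#'
#' @param tree a [clone_tree()]
#' @return character vector of violations; empty when valid
#' @export
validate_tree <- function(tree) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  E <- tree$E; n <- tree$n; np <- n_leaves(n)
  if (any(E[, n] != 0)) add("root (node n) must have no incoming edge")
  if (np >= 1 && any(E[seq_len(np), ] != 0)) add("leaves (nodes 1..n') must have no outgoing edge")
  internal <- seq.int(np + 1L, n)
  for (i in internal) {
    if (sum(E[i, ]) != 2) add(sprintf("node %d must have out-degree 2; has %g", i, sum(E[i, ])))
  }
  for (j in seq_len(n - 1L)) {
    if (sum(E[, j]) != 1) add(sprintf("node %d must have in-degree 1; has %g", j, sum(E[, j])))
  }
  A <- tryCatch(transitive_closure(E), error = function(e) NULL)
  if (is.null(A)) {
    add("adjacency is cyclic or not a tree")
  } else {
    if (!isTRUE(all.equal(A, tree$A))) add("A is not the transitive closure of E")
    if (any(diag(tree$A) != 0)) add("A must have a zero diagonal")
    if (any(tree$A * t(tree$A) != 0)) add("A has a mutual ancestor pair")
  }
  v
}

#' Validate a solution against the structural invariants
#'
#' @param solution a [clone_solution()]
#' @param instance the [problem_instance()] it solves
#' @param tol numeric tolerance for the mixture simplex constraint
#' @return character vector of violations; empty when valid
#' @export
validate_solution <- function(solution, instance, tol = 1e-6) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  idx <- instance$index
  n <- instance$n
  U <- solution$U; C <- solution$C

  if (any(abs(rowSums(U) - 1) > tol)) add("U rows must sum to 1")
  if (any(U < -tol | U > 1 + tol)) add("U entries must lie in [0, 1]")
  if (any(C != round(C))) add("C must be integer-valued")
  if (any(C < 0 | C > instance$cmax)) add("C entries must lie in [0, cmax]")
  if (any(C[n, mutation_cols(idx)] != 0)) add("root row of C must be 0 on mutation columns")
  if (any(C[n, segment_cols(idx)] != 1)) add("root row of C must be 1 on segment columns")
  if (any(abs(rowSums(solution$M) - 1) > tol)) add("M rows must sum to 1")
  if (any(colSums(solution$M) > 1 + tol)) add("M columns must sum to <= 1")
  v <- c(v, validate_tree(solution$tree))
  nm <- idx$l + idx$g
  if (nm > 0) {
    E <- solution$tree$E
    for (b in seq_len(nm)) {
      gains <- sum(solution$W[, , b] * E)
      if (gains != 1) add(sprintf("mutation %d must be gained on exactly one edge; gained %g times", b, gains))
    }
  }
  v
}

#' @export
print.variant_index <- function(x, ...) {
  cat(sprintf("variant_index: %d breakends, %d SNVs, %d segments (%d columns)\n",
              x$l, x$g, x$r, n_cols(x)))
  invisible(x)
}

#' @export
print.problem_instance <- function(x, ...) {
  cat(sprintf(paste0("problem_instance: m=%d samples, n=%d clones requested, ",
                     "nr=%d RNA clones\n"), x$m, x$n, x$nr))
  print(x$index)
  cat(sprintf("  cmax=%d, lambda1=%.4g, lambda2=%.4g\n", x$cmax, x$lambda1, x$lambda2))
  invisible(x)
}

#' @export
print.clone_tree <- function(x, ...) {
  p <- parent_vector(x$E)
  edges <- paste(sprintf("%d->%d", p[!is.na(p)], which(!is.na(p))), collapse = ", ")
  cat(sprintf("clone_tree on %d nodes (root %d): %s\n", x$n, x$n, edges))
  invisible(x)
}

#' @export
print.clone_solution <- function(x, ...) {
  cat(sprintf("clone_solution: %d clones x %d variant columns, %d samples\n",
              nrow(x$C), ncol(x$C), nrow(x$U)))
  ot <- x$objective_terms
  cat(sprintf("  objective %.6g = fit %.6g + rna %.6g + lambda1*phylo %.6g + lambda2*ratio %.6g\n",
              ot$total, ot$fit, ot$rna, ot$weighted_phylo, ot$weighted_ratio))
  invisible(x)
}
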