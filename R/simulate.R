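#' @name simulate
#' @title Ground-truth instance simulator
#'
#' @description
#' Generates instances with known ground truth: a uniformly random labeled
#' rooted binary clone tree, clonal genomes evolved along its edges by
#' segmental copy-number events with SNV/breakend gains that respect
#' loss-supported Dollo semantics by construction, Dirichlet mixture
#' fractions, a bulk matrix `F = U C` with optional truncated Gaussian
#' noise, and an RNA copy-number matrix equal to a (optionally perturbed,
#' optionally subsetted and always row-permuted) segment block of the true
#' clone genotypes.
NULL

#' Simulation configuration
#'
#' @param n clone count (odd, >= 3)
#' @param m bulk sample count
#' @param r genomic segment count
#' @param l SV breakend count (even; `l/2` SVs)
#' @param g SNV count
#' @param cmax maximum copy number
#' @param cna_rate expected segmental copy-number events per tree edge
#'   (Poisson)
#' @param cna_len_mean mean length, in segments, of one event's contiguous
#'   run (geometric, support >= 1)
#' @param dirichlet_conc symmetric Dirichlet concentration for the mixture
#'   rows
#' @param noise_sd standard deviation of additive Gaussian noise on `F`
#'   (truncated at 0); 0 for noiseless
#' @param nr number of RNA clones (must be <= n; defaults to n)
#' @param rna_flip_prob per-entry probability of a +/-1 perturbation of the
#'   RNA copy-number matrix (clipped to `[0, cmax]`)
#' @param seed RNG seed for the whole instance
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n = 5L, m = 3L, r = 4L, l = 4L, g = 6L, cmax = 4L,
                       cna_rate = 2, cna_len_mean = 2, dirichlet_conc = 1,
                       noise_sd = 0, nr = n, rna_flip_prob = 0, seed = 1L) {
  stopifnot(n %% 2 == 1, n >= 3, l %% 2 == 0, l >= 0, g >= 0, r >= 1,
            cmax >= 1, noise_sd >= 0, rna_flip_prob >= 0, rna_flip_prob <= 1,
            nr <= n, nr >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample a uniformly random labeled clone tree
#'
#' Topologies are drawn uniformly over all rooted binary trees obeying the
#' node convention (leaves `1..n'`, internal `n'+1..n-1`, root `n`): leaves
#' are inserted sequentially at a uniformly chosen attachment position
#' (any edge, or above the current root), which yields each leaf-labeled
#' shape exactly once, and the internal non-root labels are then assigned
#' by a uniform random permutation.
#'
#' @param n clone count (odd)
#' @param seed optional RNG seed (`NULL` uses the current RNG state)
#' @return a [clone_tree()]
#' @export
simulate_tree <- function(n, seed = NULL) {
  if (n %% 2 == 0 || n < 3) stop("n must be odd and >= 3")
  if (!is.null(seed)) set.seed(seed)
  np <- n_leaves(n)
  # temporary node ids: leaves 1..np, internals np + 1, np + 2, ...
  next_internal <- np
  new_internal <- function() { next_internal <<- next_internal + 1L; next_internal }
  root <- new_internal()
  parent <- c(rep(NA_integer_, np), NA_integer_)  # grows as internals appear
  parent[1:2] <- root
  for (leaf in seq_len(np)[-(1:2)]) {
    nodes <- seq_len(next_internal)
    has_parent <- nodes[!is.na(parent[nodes])]
    # positions: every edge (child side) plus one slot above the root
    pick <- sample.int(length(has_parent) + 1L, 1L)
    v <- new_internal()
    parent <- c(parent, NA_integer_)
    if (pick > length(has_parent)) {        # new root above the old one
      parent[root] <- v
      root <- v
    } else {                                # split the chosen edge
      child <- has_parent[pick]
      parent[v] <- parent[child]
      parent[child] <- v
    }
    parent[leaf] <- v
  }
  # map temporary internal ids to final labels: root -> n, others a random
  # permutation of n'+1 .. n-1
  internals <- setdiff(seq.int(np + 1L, next_internal), root)
  lab <- integer(next_internal)
  lab[seq_len(np)] <- seq_len(np)
  lab[root] <- n
  if (length(internals)) {
    pool <- seq.int(np + 1L, n - 1L)
    # guard the length-one case: sample(x, ...) with scalar x means 1:x
    lab[internals] <- if (length(pool) == 1L) pool else sample(pool)
  }
  E <- matrix(0, n, n)
  for (v in seq_len(next_internal)) {
    if (!is.na(parent[v])) E[lab[parent[v]], lab[v]] <- 1
  }
  clone_tree(E)
}

#' Evolve clonal genomes along a tree
#'
#' The root is a normal clone (no mutations, one copy per allele per
#' segment). On each edge, a Poisson number of segmental events occurs;
#' each event picks an allele, a direction (+1 gain or -1 loss), a uniform
#' start segment and a geometric run length, and is applied to every
#' segment of the run whose current copy number is positive (a fully lost
#' segment has no template left to gain back, and cannot lose further),
#' clipped to `[0, cmax]`. Each SNV/breakend is assigned a uniform segment,
#' a uniform gain edge and a uniform allele (breakend mates share edge and
#' allele); its copy number in every clone where it is present equals its
#' assigned allele's segment copy number, and it is present exactly in the
#' clones of the gain subtree reachable without the allele's segment copy
#' number hitting zero - so every loss is supported by a segment loss.
#'
#' @param tree a [clone_tree()]
#' @param config a [sim_config()]
#' @param seed optional RNG seed
#' @return a list with `C` (the true `n x (l+g+2r)` matrix), `index` (a
#'   [variant_index()]), `W` (true gain placements), `D` (true allele
#'   assignment), `events` (segmental event log) and `mutations` (per-
#'   mutation assignment table)
#' @export
simulate_genomes <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- tree$n
  l <- config$l; g <- config$g; r <- config$r; cmax <- config$cmax
  nm <- l + g
  parent <- parent_vector(tree$E)
  # visit parents before children
  order_down <- order(colSums(tree$A))
  seg <- array(0, dim = c(n, r, 2))
  seg[n, , ] <- 1
  events <- list()
  for (v in order_down) {
    p <- parent[v]
    if (is.na(p)) next
    seg[v, , ] <- seg[p, , ]
    nev <- stats::rpois(1, config$cna_rate)
    for (k in seq_len(nev)) {
      allele <- sample.int(2L, 1L)
      dir <- sample(c(1, -1), 1L)
      start <- sample.int(r, 1L)
      len <- 1L + stats::rgeom(1L, prob = 1 / config$cna_len_mean)
      run <- start:min(r, start + len - 1L)
      live <- run[seg[v, run, allele] > 0]
      if (dir < 0) {
        # losses must leave at least one total copy of the segment: allele
        # loss to zero (LOH) is allowed, homozygous deletion is not, so
        # every clone keeps an observable genome
        other <- 3L - allele
        live <- live[seg[v, live, allele] + seg[v, live, other] >= 2]
      }
      seg[v, live, allele] <- pmin(cmax, pmax(0, seg[v, live, allele] + dir))
      events[[length(events) + 1L]] <- data.frame(
        parent = p, child = v, allele = allele, dir = dir,
        start = start, len = len)
    }
  }
  # mutation assignments: breakend mates (2k-1, 2k) share edge and allele
  edges <- which(tree$E > 0, arr.ind = TRUE)      # (n-1) x 2, parent/child
  mut <- data.frame(b = seq_len(nm),
                    type = rep(c("bp", "snv"), c(l, g)),
                    seg = NA_integer_, gain_parent = NA_integer_,
                    gain_child = NA_integer_, allele = NA_integer_)
  if (nm > 0) {
    if (l > 0) {
      for (sv in seq_len(l %/% 2)) {
        e <- sample.int(nrow(edges), 1L)
        al <- sample.int(2L, 1L)
        for (b in c(2L * sv - 1L, 2L * sv)) {
          mut$seg[b] <- sample.int(r, 1L)
          mut$gain_parent[b] <- edges[e, 1]
          mut$gain_child[b] <- edges[e, 2]
          mut$allele[b] <- al
        }
      }
    }
    for (b in l + seq_len(g)) {
      e <- sample.int(nrow(edges), 1L)
      mut$seg[b] <- sample.int(r, 1L)
      mut$gain_parent[b] <- edges[e, 1]
      mut$gain_child[b] <- edges[e, 2]
      mut$allele[b] <- sample.int(2L, 1L)
    }
  }
  # presence by top-down propagation from each gain child
  Cmut <- matrix(0, n, nm)
  W <- array(0, dim = c(n, n, max(nm, 1)))[, , seq_len(nm), drop = FALSE]
  D <- integer(nm)
  children_of <- lapply(seq_len(n), function(i) which(tree$E[i, ] > 0))
  for (b in seq_len(nm)) {
    al <- mut$allele[b]
    D[b] <- as.integer(al == 1L)
    W[mut$gain_parent[b], mut$gain_child[b], b] <- 1
    s <- mut$seg[b]
    stack <- mut$gain_child[b]
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (seg[v, s, al] > 0) {
        Cmut[v, b] <- seg[v, s, al]
        stack <- c(stack, children_of[[v]])
      }
    }
  }
  Q <- matrix(0, nm, r)
  if (nm > 0) Q[cbind(seq_len(nm), mut$seg)] <- 1
  G <- matrix(0, l, l)
  if (l > 0) {
    for (sv in seq_len(l %/% 2)) {
      G[2L * sv - 1L, 2L * sv] <- 1
      G[2L * sv, 2L * sv - 1L] <- 1
    }
  }
  # synthetic genomic coordinates: r segments of 1 Mb on one chromosome,
  # variant positions uniform within their assigned segment
  seg_coords <- data.frame(chrom = "chr1",
                           start = (seq_len(r) - 1) * 1e6, end = seq_len(r) * 1e6)
  pos <- if (nm > 0) {
    seg_coords$start[mut$seg] + sample.int(1e6 - 2L, nm, replace = TRUE)
  } else integer(0)
  mut$pos <- pos
  index <- variant_index(l, g, r, Q, G, segment_coords = seg_coords)
  C <- cbind(Cmut, seg[, , 1], seg[, , 2])
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(parent = integer(0), child = integer(0), allele = integer(0),
               dir = numeric(0), start = integer(0), len = integer(0))
  list(C = C, index = index, W = W, D = D, events = ev, mutations = mut)
}

#' Sample mixture fractions and the bulk matrix F
#'
#' @param C_true the true clonal copy-number matrix
#' @param m sample count
#' @param config a [sim_config()]
#' @param seed optional RNG seed
#' @return list with `U` (rows Dirichlet-distributed) and `F`
#'   (`U C` plus optional Gaussian noise truncated at 0)
#' @export
simulate_mixture <- function(C_true, m, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(C_true)
  U <- matrix(stats::rgamma(m * n, shape = config$dirichlet_conc), nrow = m)
  U <- U / rowSums(U)
  F <- U %*% C_true
  if (config$noise_sd > 0) {
    F <- pmax(F + matrix(stats::rnorm(length(F), sd = config$noise_sd),
                         nrow = m), 0)
  }
  list(U = U, F = F)
}

#' Derive the RNA copy-number matrix from the true clones
#'
#' Selects `nr` clones (all of them when `nr = n`, otherwise a uniform
#' subset without replacement), takes their allele-specific segment block
#' in a random row order, and optionally perturbs entries by +/-1 with a
#' per-entry flip probability, clipping to `[0, cmax]`.
#'
#' @param C_true the true clonal copy-number matrix
#' @param index the instance's [variant_index()]
#' @param config a [sim_config()]
#' @param seed optional RNG seed
#' @return list with `C_RNA` (`nr x 2r`) and `true_map` (length-`n` integer
#'   vector: row of `C_RNA` representing each DNA clone, `NA` when the
#'   clone was not selected)
#' @export
simulate_rna <- function(C_true, index, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(C_true)
  if (config$nr > n) stop("nr > n: RNA clones derive from DNA clones")
  chosen <- sample.int(n, config$nr)           # random subset, random order
  C_RNA <- C_true[chosen, segment_cols(index), drop = FALSE]
  if (config$rna_flip_prob > 0) {
    flip <- matrix(stats::runif(length(C_RNA)) < config$rna_flip_prob,
                   nrow = nrow(C_RNA))
    delta <- matrix(sample(c(-1, 1), length(C_RNA), replace = TRUE),
                    nrow = nrow(C_RNA))
    C_RNA[flip] <- C_RNA[flip] + delta[flip]
    C_RNA <- pmin(pmax(C_RNA, 0), config$cmax)
  }
  true_map <- match(seq_len(n), chosen)
  list(C_RNA = C_RNA, true_map = true_map)
}

#' Simulate a complete instance with ground truth
#'
#' @param config a [sim_config()]
#' @return a list with `instance` (a [problem_instance()]) and `truth`
#'   (class `ground_truth`: true tree, `C`, `U`, `W`, `D`, DNA-to-RNA map,
#'   event log and config echo)
#' @export
simulate_instance <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n)
  gen <- simulate_genomes(tree, config)
  mix <- simulate_mixture(gen$C, config$m, config)
  rna <- simulate_rna(gen$C, gen$index, config)
  instance <- problem_instance(F = mix$F, C_RNA = rna$C_RNA,
                               index = gen$index, n = config$n,
                               cmax = config$cmax)
  truth <- structure(
    list(tree = tree, C = gen$C, U = mix$U, W = gen$W, D = gen$D,
         true_map = rna$true_map, events = gen$events,
         mutations = gen$mutations, config = config),
    class = "ground_truth")
  list(instance = instance, truth = truth)
}
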