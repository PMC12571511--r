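# Shared fixtures and independent oracles for the test suite.

# small simulated instance with ground truth
tiny_sim <- function(seed = 1L, n = 3L, m = 2L, r = 2L, l = 2L, g = 2L,
                     cmax = 2L, ...) {
  simulate_instance(sim_config(n = n, m = m, r = r, l = l, g = g,
                               cmax = cmax, seed = seed, ...))
}

# mapping vector (DNA clone -> RNA clone row) to a binary matrix
map_to_M <- function(map, n, nr) {
  M <- matrix(0, n, nr)
  for (i in seq_len(n)) M[i, map[i]] <- 1
  M
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# reachability oracle: A[i,j] = 1 iff some power of E has a nonzero (i,j)
reachability_by_powers <- function(E) {
  n <- nrow(E)
  A <- matrix(0, n, n)
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- P %*% E
    A <- A + P
  }
  (A > 0) + 0
}

# independent replay of a simulator event log: rebuilds the clonal
# copy-number matrix from the recorded segmental events and mutation
# assignments alone
replay_truth <- function(truth, index) {
  n <- truth$tree$n
  r <- index$r
  cmax <- truth$config$cmax
  parent <- parent_vector(truth$tree$E)
  seg <- array(0, dim = c(n, r, 2))
  seg[n, , ] <- 1
  ev <- truth$events
  for (v in order(colSums(truth$tree$A))) {
    p <- parent[v]
    if (is.na(p)) next
    seg[v, , ] <- seg[p, , ]
    rows <- which(ev$parent == p & ev$child == v)
    for (k in rows) {
      run <- ev$start[k]:min(r, ev$start[k] + ev$len[k] - 1L)
      al <- ev$allele[k]
      live <- run[seg[v, run, al] > 0]
      if (ev$dir[k] < 0) {
        live <- live[seg[v, live, al] + seg[v, live, 3L - al] >= 2]
      }
      seg[v, live, al] <- pmin(cmax, pmax(0, seg[v, live, al] + ev$dir[k]))
    }
  }
  mut <- truth$mutations
  nm <- nrow(mut)
  Cmut <- matrix(0, n, nm)
  children_of <- lapply(seq_len(n), function(i) which(truth$tree$E[i, ] > 0))
  for (b in seq_len(nm)) {
    al <- mut$allele[b]; s <- mut$seg[b]
    stack <- mut$gain_child[b]
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (seg[v, s, al] > 0) {
        Cmut[v, b] <- seg[v, s, al]
        stack <- c(stack, children_of[[v]])
      }
    }
  }
  cbind(Cmut, seg[, , 1], seg[, , 2])
}

# fix every decision variable of a joint C-step model to a ground truth,
# leaving only slack variables free; used as a feasibility oracle
fix_model_to_truth <- function(cm, instance, truth) {
  n <- instance$n
  idx <- instance$index
  nm <- idx$l + idx$g
  Cseg <- truth$C[, segment_cols(idx), drop = FALSE]
  milp_fix <- clonedecon:::milp_fix_vars
  milp_fix(cm$model, cm$model$blocks$C, as.numeric(truth$C))
  milp_fix(cm$model, cm$model$blocks$E, as.numeric(truth$tree$E))
  milp_fix(cm$model, cm$model$blocks$A, as.numeric(truth$tree$A))
  M <- map_to_M(truth$true_map, n, instance$nr)
  milp_fix(cm$model, cm$model$blocks$M, as.numeric(M))
  milp_fix(cm$model, cm$model$blocks$Cp, as.numeric(Cseg))
  if (nm > 0) {
    npair <- nrow(cm$pairs)
    wflat <- numeric(npair * nm)
    for (b in seq_len(nm)) for (p in seq_len(npair)) {
      wflat[(b - 1L) * npair + p] <- truth$W[cm$pairs$i[p], cm$pairs$j[p], b]
    }
    milp_fix(cm$model, cm$model$blocks$W, wflat)
    milp_fix(cm$model, cm$model$blocks$D, as.numeric(truth$D))
    X <- (truth$C[, seq_len(nm), drop = FALSE] > 0) + 0
    milp_fix(cm$model, cm$model$blocks$X, as.numeric(X))
  }
  invisible(cm)
}

# minimal VCF writer for read_bulk fixtures
write_test_vcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele fraction">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, records), path)
}

vcf_snv_record <- function(chrom, pos, id, af) {
  sprintf("%s\t%d\t%s\tA\tT\t.\tPASS\tAF=%g", chrom, pos, id, af)
}

vcf_bnd_record <- function(chrom, pos, id, mate_id, af,
                           mate_chrom = chrom, mate_pos = pos + 1000L) {
  sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s;AF=%g",
          chrom, pos, id, mate_chrom, mate_pos, mate_id, af)
}

write_test_segments <- function(path, segs) {
  utils::write.table(segs, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
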