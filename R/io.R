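#' @name io
#' @title Reading bulk variant calls and writing solutions
#'
#' @description
#' Two input paths exist. The VCF path ([read_bulk()]) reads per-sample
#' VCFs (SNVs plus BND-style SV breakends with `MATEID` mates and an `AF`
#' INFO field) together with per-sample tab-separated segment tables, and
#' assembles the observed matrix `F`: each mutation column holds the
#' allele fraction times the total (allele 1 + allele 2) mean copy number
#' of its containing segment in that sample, and the segment columns hold
#' the two allele-specific mean copy numbers. The direct path
#' ([read_instance()]) reads an `F` matrix CSV plus companion tables as
#' written by [write_instance()], bypassing VCF parsing entirely -
#' convenient for simulator output and precomputed `F` matrices.
#' Genomic coordinates are 0-based half-open internally; VCF's 1-based
#' positions are converted on read.
NULL

#' Read per-sample bulk VCFs and segment tables into (F, VariantIndex)
#'
#' All samples must share an identical variant universe (same SNVs, same
#' breakends, same segment grid). Variants are ordered canonically within
#' each class (breakends first, then SNVs) by chromosome, position, then
#' record ID, so record order inside a VCF does not matter.
#'
#' @param vcf_paths character vector of per-sample VCF files
#' @param segment_paths per-sample segment tables (TSV with header
#'   `chrom start end cn_allele1 cn_allele2`; coordinates 0-based
#'   half-open)
#' @return list with `F` and `index` (a [variant_index()])
#' @export
read_bulk <- function(vcf_paths, segment_paths) {
  stopifnot(length(vcf_paths) == length(segment_paths), length(vcf_paths) >= 1)
  m <- length(vcf_paths)
  segs <- lapply(segment_paths, function(p) {
    s <- utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "cn_allele1", "cn_allele2")
    if (!all(need %in% names(s))) stop("segment table ", p, " lacks columns: ",
                                       paste(setdiff(need, names(s)), collapse = ", "))
    if (any(s$cn_allele1 < 0 | s$cn_allele2 < 0)) stop("negative mean copy number in ", p)
    s[order(s$chrom, s$start), , drop = FALSE]
  })
  grid <- segs[[1]][, c("chrom", "start", "end")]
  for (k in seq_len(m)[-1]) {
    if (!identical(grid, segs[[k]][, c("chrom", "start", "end")])) {
      stop("segment grids differ between samples 1 and ", k,
           "; a shared grid is required (re-segment upstream)")
    }
  }
  calls <- lapply(vcf_paths, parse_vcf_calls)
  key <- function(d) paste(d$type, d$chrom, d$pos, d$id)
  universe <- calls[[1]]
  for (k in seq_len(m)[-1]) {
    if (!setequal(key(universe), key(calls[[k]]))) {
      stop("variant universe differs between samples 1 and ", k,
           "; all samples must report the same SNVs and breakends")
    }
  }
  # canonical order: breakends, then SNVs, each by (chrom, pos, id)
  ord <- order(universe$type != "bnd", universe$chrom, universe$pos, universe$id)
  universe <- universe[ord, , drop = FALSE]
  bnd <- universe[universe$type == "bnd", , drop = FALSE]
  snv <- universe[universe$type == "snv", , drop = FALSE]
  l <- nrow(bnd); g <- nrow(snv); r <- nrow(grid)
  if (l %% 2 != 0) stop("odd number of breakend records; every breakend needs a mate")
  G <- matrix(0, l, l)
  if (l > 0) {
    for (b in seq_len(l)) {
      mate <- which(bnd$id == bnd$mate_id[b])
      if (length(mate) != 1) stop("breakend ", bnd$id[b], ": mate ", bnd$mate_id[b],
                                  " not found (pairing error)")
      G[b, mate] <- 1
    }
    if (any(rowSums(G) != 1) || any(diag(G) != 0) || !isTRUE(all.equal(G, t(G)))) {
      stop("inconsistent breakend mate pairing")
    }
  }
  locate <- function(chrom, pos0) {
    hit <- which(grid$chrom == chrom & grid$start <= pos0 & pos0 < grid$end)
    if (length(hit) != 1) stop("position ", chrom, ":", pos0 + 1,
                               " falls in ", length(hit), " segments (mapping error)")
    hit
  }
  all_mut <- rbind(bnd, snv)
  seg_of <- mapply(locate, all_mut$chrom, all_mut$pos)
  Q <- matrix(0, l + g, r)
  if (l + g > 0) Q[cbind(seq_len(l + g), seg_of)] <- 1
  F <- matrix(0, m, l + g + 2 * r)
  for (k in seq_len(m)) {
    ck <- calls[[k]]
    ck <- ck[match(key(universe), key(ck)), , drop = FALSE]
    cn1 <- segs[[k]]$cn_allele1; cn2 <- segs[[k]]$cn_allele2
    if (l + g > 0) {
      F[k, seq_len(l + g)] <- ck$af * (cn1[seg_of] + cn2[seg_of])
    }
    F[k, l + g + seq_len(r)] <- cn1
    F[k, l + g + r + seq_len(r)] <- cn2
  }
  ids <- c(all_mut$id, paste0("seg", seq_len(r), "_a1"), paste0("seg", seq_len(r), "_a2"))
  index <- variant_index(l, g, r, Q, G,
                         segment_coords = grid, variant_ids = ids)
  list(F = F, index = index)
}

# parse one VCF into a data.frame of SNV and breakend calls (0-based pos)
parse_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  info_field <- function(field) {
    out <- vcfR::extract.info(v, element = field)
    if (length(out) < nrow(fix)) out <- rep(out, length.out = nrow(fix))
    out
  }
  af <- suppressWarnings(as.numeric(info_field("AF")))
  svtype <- info_field("SVTYPE")
  mateid <- info_field("MATEID")
  if (any(is.na(af))) stop("VCF ", path, ": every record needs an AF INFO field")
  if (any(af < 0 | af > 1)) stop("VCF ", path, ": allele fractions must lie in [0,1]")
  type <- ifelse(!is.na(svtype) & svtype == "BND", "bnd", "snv")
  data.frame(id = fix$ID, chrom = fix$CHROM,
             pos = as.integer(fix$POS) - 1L,       # to 0-based
             type = type, af = af,
             mate_id = ifelse(type == "bnd", mateid, NA_character_),
             stringsAsFactors = FALSE)
}

#' Read a clone-level RNA copy-number matrix
#'
#' @param path CSV file. In `per_clone` mode: one row per RNA clone, `2r`
#'   numeric columns (allele-1 segment block then allele-2), optional row
#'   names in the first column. In `per_cell` mode: a `cluster` column
#'   followed by the `2r` numeric columns; cells are averaged within each
#'   cluster and the means rounded half-up.
#' @param mode `"per_clone"` or `"per_cell"`
#' @param cmax copy numbers are clipped to `[0, cmax]`
#' @return integer matrix `nr x 2r`
#' @export
read_rna_cn <- function(path, mode = c("per_clone", "per_cell"), cmax = 4) {
  mode <- match.arg(mode)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (mode == "per_clone") {
    if (!is.numeric(d[[1]])) {
      rn <- d[[1]]; d <- d[, -1, drop = FALSE]; rownames(d) <- rn
    }
    M <- as.matrix(d)
  } else {
    if (!"cluster" %in% names(d)) stop("per-cell RNA CSV needs a `cluster` column")
    cl <- d$cluster
    num <- as.matrix(d[, setdiff(names(d), "cluster"), drop = FALSE])
    M <- do.call(rbind, lapply(split(seq_len(nrow(num)), cl), function(ix) {
      colMeans(num[ix, , drop = FALSE])
    }))
    M <- floor(M + 0.5)          # round half-up to integer copy numbers
  }
  if (any(is.na(M))) stop("RNA copy-number matrix contains non-numeric entries")
  if (any(M < 0)) stop("RNA copy-number matrix has negative entries")
  M <- pmin(M, cmax)
  storage.mode(M) <- "double"
  M
}

#' Randomly subsample variants, keeping breakend mates together
#'
#' @param instance a [problem_instance()]
#' @param max_sv maximum number of breakend columns to keep (rounded down
#'   to even; mates are kept or dropped as pairs)
#' @param max_snv maximum number of SNV columns to keep
#' @param seed RNG seed
#' @return list with `instance` (rebuilt) and `column_map` (original
#'   column index of every retained column)
#' @export
subsample_variants <- function(instance, max_sv, max_snv, seed = 1L) {
  idx <- instance$index
  l <- idx$l; g <- idx$g; r <- idx$r
  max_sv <- 2L * (as.integer(max_sv) %/% 2L)
  if (max_sv > l) { warning("max_sv capped at l = ", l); max_sv <- l }
  if (max_snv > g) { warning("max_snv capped at g = ", g); max_snv <- as.integer(g) }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  keep_bp <- integer(0)
  if (l > 0) {
    pairs <- which(upper.tri(idx$G) & idx$G > 0, arr.ind = TRUE)   # one row per SV
    chosen <- sort(sample.int(nrow(pairs), max_sv %/% 2L))
    keep_bp <- sort(as.vector(pairs[chosen, , drop = FALSE]))
  }
  keep_snv <- if (g > 0) l + sort(sample.int(g, max_snv)) else integer(0)
  keep_mut <- c(keep_bp, keep_snv)
  column_map <- c(keep_mut, segment_cols(idx))
  l2 <- length(keep_bp); g2 <- length(keep_snv)
  Q2 <- idx$Q[keep_mut, , drop = FALSE]
  G2 <- idx$G[keep_bp, keep_bp, drop = FALSE]
  index2 <- variant_index(l2, g2, r, Q2, G2,
                          segment_coords = idx$segment_coords,
                          variant_ids = idx$variant_ids[column_map])
  inst2 <- problem_instance(F = instance$F[, column_map, drop = FALSE],
                            C_RNA = instance$C_RNA, index = index2,
                            n = instance$n, cmax = instance$cmax)
  list(instance = inst2, column_map = column_map)
}

write_labeled_matrix <- function(M, path, row_names, col_names) {
  dimnames(M) <- list(row_names, col_names)
  utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
}

read_labeled_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}

#' Write a solution to a directory of diffable text files
#'
#' Writes `U.tsv`, `C.tsv`, `C_prime.tsv`, `M.tsv` (labeled matrices),
#' `tree.edgelist` (`parent TAB child TAB gained-variant-ids`), `tree.dot`,
#' and `run_summary.json` (objective term breakdown recomputed from the
#' written matrices, config echo, iteration log).
#'
#' @param solution a [clone_solution()]
#' @param instance the [problem_instance()] it solves (for labels and the
#'   objective recomputation)
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_solution <- function(solution, instance, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  idx <- instance$index
  n <- instance$n
  clones <- paste0("clone", seq_len(n))
  samples <- paste0("sample", seq_len(instance$m))
  write_labeled_matrix(solution$U, file.path(out_dir, "U.tsv"), samples, clones)
  write_labeled_matrix(solution$C, file.path(out_dir, "C.tsv"), clones, idx$variant_ids)
  write_labeled_matrix(solution$C_prime, file.path(out_dir, "C_prime.tsv"),
                       clones, idx$variant_ids[segment_cols(idx)])
  write_labeled_matrix(solution$M, file.path(out_dir, "M.tsv"), clones,
                       paste0("rna_clone", seq_len(instance$nr)))
  p <- parent_vector(solution$tree$E)
  nm <- idx$l + idx$g
  edge_lines <- character(0)
  dot_lines <- c("digraph clone_tree {")
  for (j in seq_len(n)) {
    if (is.na(p[j])) next
    gained <- if (nm > 0) which(solution$W[p[j], j, ] > 0) else integer(0)
    lab <- if (length(gained)) paste(idx$variant_ids[gained], collapse = ",") else "."
    edge_lines <- c(edge_lines, paste(p[j], j, lab, sep = "\t"))
    dot_lines <- c(dot_lines, sprintf('  %d -> %d [label="%s"];', p[j], j,
                                      if (length(gained)) lab else ""))
  }
  dot_lines <- c(dot_lines, "}")
  writeLines(edge_lines, file.path(out_dir, "tree.edgelist"))
  writeLines(dot_lines, file.path(out_dir, "tree.dot"))
  cfg <- attr(solution, "config")
  log <- attr(solution, "log")
  terms <- evaluate_objective(instance, solution$U, solution$C,
                              solution$tree$E, solution$M,
                              ratio_snvs = if (is.null(cfg)) TRUE else cfg$ratio_snvs)
  summary <- list(
    objective = terms,
    lambda1 = instance$lambda1, lambda2 = instance$lambda2,
    n = n, m = instance$m, nr = instance$nr,
    l = idx$l, g = idx$g, r = idx$r, cmax = instance$cmax,
    config = if (is.null(cfg)) NULL else unclass(cfg),
    iterations = if (is.null(log)) NULL else log
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(out_dir)
}

#' Write an instance (and optional ground truth) as CSV/TSV/JSON files
#'
#' Emits `F.csv`, `C_RNA.csv`, `segments.tsv`, `variants.tsv` (id, type,
#' segment and mate of every mutation column) and `meta.json`; with a
#' `truth`, also `ground_truth.json`. [read_instance()] round-trips these.
#'
#' @param instance a [problem_instance()]
#' @param out_dir output directory
#' @param truth optional `ground_truth` from [simulate_instance()]
#' @return `out_dir`, invisibly
#' @export
write_instance <- function(instance, out_dir, truth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  idx <- instance$index
  F <- instance$F
  dimnames(F) <- list(paste0("sample", seq_len(nrow(F))), idx$variant_ids)
  utils::write.csv(F, file.path(out_dir, "F.csv"), quote = FALSE)
  CR <- instance$C_RNA
  dimnames(CR) <- list(paste0("rna_clone", seq_len(nrow(CR))),
                       idx$variant_ids[segment_cols(idx)])
  utils::write.csv(CR, file.path(out_dir, "C_RNA.csv"), quote = FALSE)
  utils::write.table(idx$segment_coords, file.path(out_dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nm <- idx$l + idx$g
  mate <- rep(NA_character_, nm)
  if (idx$l > 0) {
    for (b in seq_len(idx$l)) mate[b] <- idx$variant_ids[which(idx$G[b, ] > 0)]
  }
  variants <- data.frame(
    id = if (nm > 0) idx$variant_ids[seq_len(nm)] else character(0),
    type = rep(c("bp", "snv"), c(idx$l, idx$g)),
    segment = if (nm > 0) apply(idx$Q, 1, which.max) else integer(0),
    mate = mate)
  utils::write.table(variants, file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(l = idx$l, g = idx$g, r = idx$r, n = instance$n,
                            m = instance$m, nr = instance$nr,
                            cmax = instance$cmax,
                            lambda1 = instance$lambda1,
                            lambda2 = instance$lambda2),
                       file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(E = truth$tree$E, C = truth$C, U = truth$U, D = truth$D,
           true_map = truth$true_map, config = unclass(truth$config),
           events = truth$events, mutations = truth$mutations),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null")
  }
  invisible(out_dir)
}

#' Read an instance written by [write_instance()]
#'
#' @param dir instance directory
#' @param n,cmax optional overrides of the stored clone count and copy
#'   number bound
#' @return a [problem_instance()]
#' @export
read_instance <- function(dir, n = NULL, cmax = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (is.null(n)) n <- meta$n
  if (is.null(cmax)) cmax <- meta$cmax
  F <- as.matrix(utils::read.csv(file.path(dir, "F.csv"), row.names = 1,
                                 check.names = FALSE))
  CR <- as.matrix(utils::read.csv(file.path(dir, "C_RNA.csv"), row.names = 1,
                                  check.names = FALSE))
  segs <- utils::read.table(file.path(dir, "segments.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  variants <- utils::read.table(file.path(dir, "variants.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  l <- meta$l; g <- meta$g; r <- meta$r
  Q <- matrix(0, l + g, r)
  if (l + g > 0) Q[cbind(seq_len(l + g), variants$segment)] <- 1
  G <- matrix(0, l, l)
  if (l > 0) {
    for (b in seq_len(l)) {
      G[b, match(variants$mate[b], variants$id)] <- 1
    }
  }
  index <- variant_index(l, g, r, Q, G, segment_coords = segs,
                         variant_ids = colnames(F))
  problem_instance(F = F, C_RNA = CR, index = index, n = n, cmax = cmax)
}

#' Read a ground truth written by [write_instance()]
#'
#' @param dir instance directory containing `ground_truth.json`
#' @return a `ground_truth` list (tree, `C`, `U`, `D`, map, event log)
#' @export
read_ground_truth <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  structure(
    list(tree = clone_tree(gt$E), C = gt$C, U = gt$U, D = gt$D,
         true_map = gt$true_map, events = gt$events,
         mutations = gt$mutations, config = gt$config),
    class = "ground_truth")
}
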