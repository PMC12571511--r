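#' @name objective
#' @title Direct evaluation of the deconvolution objective
#'
#' @description
#' The model minimizes, over the mixture matrix `U`, clonal copy-number
#' matrix `C`, and DNA-to-RNA clone mapping `M`,
#'
#'   `|F - U C| + |C' - M C_RNA| + lambda1 * R + lambda2 * S`
#'
#' where all norms are entrywise L1, `C'` is the segment block of `C`,
#' `R` is the phylogenetic cost (sum over tree edges of the L1 segment
#' copy-number distance between parent and child), and `S` penalizes
#' disagreement between the observed breakpoint/SNV-to-segment mixture
#' copy-number ratios and the ones implied by `(U, C)`. The functions here
#' evaluate those terms directly from matrices, independently of the ILP
#' encoding, so solver output can always be cross-checked.
NULL

#' Observed breakpoint/SNV-to-segment mixture copy-number ratios
#'
#' For sample `i` and mutation column `b`, the ratio is
#' `F[i,b] / sum_s Q[b,s] * (F[i, seg1_s] + F[i, seg2_s])`, with the
#' convention that a zero denominator yields ratio 0 (a zero-copy segment
#' cannot carry mutation mass).
#'
#' @param F the `m x (l+g+2r)` observed matrix
#' @param index a [variant_index()]
#' @return an `m x (l+g)` matrix of ratios
#' @export
observed_ratios <- function(F, index) {
  nm <- index$l + index$g
  if (nm == 0) return(matrix(0, nrow(F), 0))
  seg_tot <- F[, segment_cols(index, "1"), drop = FALSE] +
    F[, segment_cols(index, "2"), drop = FALSE]          # m x r
  denom <- seg_tot %*% t(index$Q)                        # m x (l+g)
  pi_mat <- F[, mutation_cols(index), drop = FALSE] / denom
  pi_mat[!is.finite(pi_mat)] <- 0
  pi_mat[denom == 0] <- 0
  pi_mat
}

#' Phylogenetic cost R of a (tree, C) pair
#'
#' Sum over directed tree edges of the L1 distance between the parent's and
#' child's allele-specific segment copy-number rows.
#'
#' @param E binary adjacency matrix
#' @param C clonal copy-number matrix
#' @param index a [variant_index()]
#' @export
phylo_cost <- function(E, C, index) {
  seg <- segment_cols(index)
  total <- 0
  for (i in seq_len(nrow(E))) {
    for (j in which(E[i, ] > 0)) {
      total <- total + sum(abs(C[i, seg] - C[j, seg]))
    }
  }
  total
}

#' Ratio-consistency cost S of a (U, C) pair
#'
#' @param U mixture matrix (fixed)
#' @param C clonal copy-number matrix
#' @param F observed matrix (source of the ratio constants)
#' @param index a [variant_index()]
#' @param ratio_snvs apply the penalty to SNV columns as well as
#'   breakpoints (default) or to breakpoints only
#' @export
ratio_cost <- function(U, C, F, index, ratio_snvs = TRUE) {
  cols <- if (ratio_snvs) mutation_cols(index) else breakpoint_cols(index)
  if (length(cols) == 0) return(0)
  pi_mat <- observed_ratios(F, index)
  UC <- U %*% C
  est_seg_tot <- UC[, segment_cols(index, "1"), drop = FALSE] +
    UC[, segment_cols(index, "2"), drop = FALSE]
  est_denom <- est_seg_tot %*% t(index$Q)     # m x (l+g)
  dev <- UC[, mutation_cols(index), drop = FALSE] - pi_mat * est_denom
  sum(abs(dev[, cols, drop = FALSE]))
}

#' Evaluate all four objective terms at a candidate point
#'
#' @param instance a [problem_instance()]
#' @param U mixture matrix
#' @param C clonal copy-number matrix
#' @param E tree adjacency
#' @param M DNA-to-RNA mapping matrix
#' @param ratio_snvs see [ratio_cost()]
#' @return named list `fit`, `rna`, `phylo`, `ratio`, `weighted_phylo`,
#'   `weighted_ratio`, `total`
#' @export
evaluate_objective <- function(instance, U, C, E, M, ratio_snvs = TRUE) {
  idx <- instance$index
  fit <- sum(abs(instance$F - U %*% C))
  C_prime <- C[, segment_cols(idx), drop = FALSE]
  rna <- sum(abs(C_prime - M %*% instance$C_RNA))
  phylo <- phylo_cost(E, C, idx)
  ratio <- ratio_cost(U, C, instance$F, idx, ratio_snvs = ratio_snvs)
  list(fit = fit, rna = rna, phylo = phylo, ratio = ratio,
       weighted_phylo = instance$lambda1 * phylo,
       weighted_ratio = instance$lambda2 * ratio,
       total = fit + rna + instance$lambda1 * phylo + instance$lambda2 * ratio)
}
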