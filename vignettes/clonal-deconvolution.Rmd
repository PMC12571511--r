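---
title: "Joint clonal deconvolution of bulk DNA-seq guided by single-cell RNA copy numbers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint clonal deconvolution of bulk DNA-seq guided by single-cell RNA copy numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedecon)
```

## The problem

A bulk tumor sample is a mixture of cell subpopulations (clones) that share
an evolutionary history. Bulk DNA sequencing observes only the mixture:
for each variant we see an *average* copy number across all cells of the
sample. Single-cell RNA sequencing, by contrast, resolves clones well but
covers the genome poorly — it can support clone-level segmental copy-number
calls, but not SNV or structural-variant (SV) genotypes. `clonedecon`
combines the two: it deconvolves multi-sample bulk measurements of SNVs,
allele-specific segmental copy-number alterations (CNAs), and SV breakpoint
ends into integer clonal genotypes, a rooted binary clonal phylogeny, and
per-sample clone mixture fractions, using clone-level copy numbers derived
from scRNA-seq as a guide.

### Data representation

All matrices share one column layout over `l + g + 2r` variant columns:
`l` SV breakend columns, then `g` SNV columns, then `r` allele-1 segment
columns, then `r` allele-2 segment columns. The inputs are:

* `F` (`m x (l+g+2r)`): the observed average copy number of each variant
  in each of `m` bulk samples. SNV and breakend entries are allele fraction
  times the total copy number of the containing segment; segment entries
  are allele-specific mean copy numbers.
* `C_RNA` (`nr x 2r`): integer allele-specific segment copy numbers of the
  `nr` RNA-derived clones.
* `Q` (`(l+g) x r`): which segment contains each breakend/SNV (one per row).
* `G` (`l x l`): which breakend is which other's mate (SVs contribute two
  paired ends).

The method estimates the mixture matrix `U` (`m x n`, rows on the
probability simplex), the integer clonal genotype matrix `C`
(`n x (l+g+2r)`, entries in `[0, cmax]`), the RNA-estimated segment block
`C'` (tied to the segment columns of `C`), and a binary matrix `M`
assigning each DNA clone to exactly one RNA clone (each RNA clone used at
most once).

## The objective and its constraint system

Everything is scored by one objective, minimized over `U`, `C` and `M`:

$$\min_{U, C, M}\; |F - UC| \;+\; |C' - M\,C_{\mathrm{RNA}}| \;+\;
\lambda_1 R \;+\; \lambda_2 S$$

with all norms entrywise L1. The first term measures deconvolution fit;
the second, agreement between the deconvolved segment copy numbers and the
RNA-derived ones under the chosen clone mapping. `R` is a phylogenetic
parsimony cost: the sum over tree edges of the L1 distance between parent
and child segment copy-number rows. `S` penalizes disagreement between the
observed ratio of a mutation's mixture copy number to its segment's total
mixture copy number and the same ratio implied by `(U, C)`; a zero
observed segment total defines a ratio of zero, so any estimated mutation
mass there is penalized.

The clone tree is a rooted binary tree over `n` nodes under a fixed
labeling: leaves `1..(n+1)/2`, internal nodes next, root last (`n` must be
odd). The root is a normal clone: zero mutation copies, one copy per
allele of every segment. Mutations follow a loss-supported Dollo model:
each SNV/breakend is gained on exactly one tree edge, may be lost any
number of times, and each loss must be supported by loss of the containing
segment on the mutation's assigned allele — a binary assignment `D`
shared between breakend mates, which also share their gain edge. A
mutation's copy number can never exceed its assigned allele's segment copy
number.

### ILP encoding choices

The copy-number side is solved as an integer linear program. Choices that
the formulation above does not pin down, and how this package makes them:

* **Presence indicators.** Dollo logic needs presence/absence while the
  model works in integer copy numbers, so binary `x` with
  `x <= C <= cmax * x` links the two.
* **Single-gain propagation.** For every candidate edge `(i, j)` and
  mutation `b`: `x[j,b] <= x[i,b] + W[i,j,b] + (1 - E[i,j])`. Presence can
  only appear at the gain edge; with the root fixed absent and each
  mutation gaining exactly once, the presence set is exactly the gain
  subtree minus lost subtrees.
* **Ancestry.** The edge-propagation sandwich (`A[k,j]` equal to `A[k,i]`
  across each edge `i -> j`, plus `A >= E`) is completed with explicit
  zeros — no ancestor of the root, no self-ancestry, leaves are never
  ancestors — which pins `A` to exactly the transitive closure of `E` and
  rules out directed cycles (a cycle would force a self-ancestor).
* **Big-M constants** are the tightest valid bounds: `cmax` in the
  allele-bound and loss-support rows, `2r * cmax` per edge in the
  linearization of `R`.
* **Scope of `S`.** The ratio penalty applies to SNVs as well as
  breakends by default (`ratio_snvs = FALSE` restricts it to breakends
  for ablation).

## Coordinate descent

The objective is bilinear in `(U, C)`, so it is minimized by alternating
two exact linear programs from a random start:

1. **C-step** (integer, `U` fixed). Default is the two-stage form: first
   the tree, segment copy numbers, `C'` and `M` (objective: segment fit +
   RNA term + `lambda1 * R`); then, with tree and segments pinned, the
   mutation columns, gain placements `W` and alleles `D` (objective:
   mutation fit + `lambda2 * S`). `mode = "joint"` solves everything in
   one ILP — slower but an exact coordinate-descent step.
2. **U-step** (continuous, `C` fixed). Minimizes `|F - UC|` plus, by
   default, `lambda2 * S` — the only other objective term that depends on
   `U`. Including it keeps each full iteration a descent step on the
   shared objective, so in joint mode the objective trajectory is
   non-increasing; `ratio_in_ustep = FALSE` restores the narrower fit-only
   U-step.

Random restarts (`restarts`, default 3) guard against local minima; each
restart draws its initial `U` from a flat Dirichlet with seed
`seed + restart - 1`. The iteration count is fixed (`iterations`, default
3, matching the regime the method is normally run in) with an optional
early stop on absolute improvement below `early_stop_tol`. In two-stage
mode the tree is fixed after stage one within each C-step and re-solved at
the next iteration; each stage receives half the per-iteration time limit.
The best restart by final total objective wins, ties going to the lowest
restart index.

### Regularization weights

Defaults scale the regularizers to the size of the fit term:

$$\lambda_1 = \frac12\,\frac{(l+g+2r)\,m}{2r\,N}, \qquad
\lambda_2 = \frac12\,\frac{l+g+2r}{l+g},$$

`lambda1` is the ratio of the fit term's entry count to the phylogenetic
cost's (about `2r` per edge across the tree). Whether `N` counts nodes or
edges is a convention; the package uses the node count `n` by default and
exposes `edges = TRUE` for `n - 1`. `lambda2` requires `l + g > 0`: with
no mutations to place there is nothing for `S` to regularize and
configuration fails fast.

### Solver backend

The integer programs are solved with HiGHS through a bundled SciPy bridge
script run as a subprocess (single-threaded, relative MIP gap 0, optional
wall-clock limit per solve), which makes runs deterministic for fixed
seeds. Solutions are extracted from the incumbent, rounded to exact
integers (deviations beyond 1e-5 warn), validated against every
structural invariant, and re-scored by a direct term-by-term evaluator
independent of the ILP encoding — the reported objective never relies on
solver bookkeeping.

## The simulator

`simulate_instance()` generates ground-truth instances used throughout the
tests:

* **Tree**: uniformly random over all labeled rooted binary topologies
  (sequential leaf insertion — every edge or a new root slot chosen
  uniformly — then a uniform random assignment of internal labels).
* **Genomes**: the root is diploid-normal. Each edge receives a Poisson
  number (`cna_rate`, default 2) of segmental events; an event picks an
  allele, a direction (single-copy gain or loss), a uniform start segment
  and a geometric run length (`cna_len_mean`, default 2 segments), applied
  where the allele has template left and clipped to `[0, cmax]`. Losses
  never drive a segment's *total* copy number below one: allele loss to
  zero (LOH) is what supports Dollo mutation losses, but homozygous
  whole-segment deletion is excluded so every clone keeps an observable
  genome — without this, small instances can produce clones with
  an all-zero genome whose mixture fractions are unidentifiable.
* **Mutations**: each SNV/breakend gets a uniform segment, gain edge and
  allele (mates share edge and allele). Where present, its copy number
  equals its allele's segment copy number, and it disappears exactly where
  that allele's copy number hits zero — loss-supported Dollo holds by
  construction, and the event log suffices to replay the genomes exactly.
* **Mixtures**: `U` rows are symmetric-Dirichlet (`dirichlet_conc`,
  default 1, i.e. flat); `F = U C`, optionally plus Gaussian noise of
  standard deviation `noise_sd` truncated at zero.
* **RNA matrix**: the segment block of all (or a uniform subset of) true
  clones in random row order, optionally perturbed by ±1 per entry with
  probability `rna_flip_prob`, clipped to `[0, cmax]`.

What the simulator does *not* emulate: read-level noise (F noise is
Gaussian on the copy-number scale, not binomial read sampling), caller
segmentation error (all samples share the exact segment grid), subclonal
copy-number states within a clone, and RNA clones that do not correspond
to any DNA clone. Passing tests therefore certify the optimization and
its encoding, not robustness to real-data artifacts upstream of the
model's inputs.

## Numerical and validation choices

* Mixture rows are renormalized after the U-step LP and checked to 1e-6;
  copy numbers are rounded to integers with a 1e-5 tolerance warning.
* An exhaustive oracle (`oracle_solve()`) enumerates every feasible
  (tree, integer `C`, allele assignment, gain placement, injective `M`)
  on tiny instances and evaluates the exact objective; the test suite
  requires the joint-mode ILP to match its optimum exactly over seeded
  instances (n = 3, one segment, three mutations, `cmax` 2). It refuses
  search spaces beyond its cap rather than running forever.
* Clone matching for evaluation solves a linear assignment problem on
  L1 genotype distances, with mixture distance and then index as
  tie-breaks; RMSEs are reported over whole matrices (matrix-wise, not
  per-clone averages). When clone counts differ the smaller side is
  padded with normal clones at zero frequency.
* Noise-robustness comparisons pair noise levels by common random
  numbers: one standard-normal draw per seed, scaled by each sigma, so
  the comparison across noise levels is not confounded by resampling.
* Test and example problem sizes (n of 3 to 7, a few segments and ten or
  so mutations, iterations 2-3, restarts 1-3) are chosen so the whole
  suite runs on a single CPU in minutes; they are the scales at which the
  exhaustive oracle can certify exactness, and the qualitative behavior
  (exact noiseless recovery, graceful degradation with noise and clone
  count) is already visible there.

## Known limitations

* `nr < n` is rejected (each DNA clone needs its own RNA clone under the
  mapping constraints); merge RNA clusters upstream or lower `n`.
* The model selects no clone count: sweep `n` externally and compare
  objectives.
* Mixed-ploidy and sex chromosomes are treated like autosomes.
* ILP cost grows quickly with `n` and the number of variants; the
  variant subsampler (`subsample_variants()`, mate-pair aware) is the
  intended control, mirroring how such methods are run in practice.

## A worked example

```{r example, eval = FALSE}
library(clonedecon)

sim <- simulate_instance(sim_config(n = 5, m = 3, r = 4, l = 4, g = 6,
                                    cmax = 4, seed = 7))
sol <- run_deconvolution(sim$instance,
                         run_config(iterations = 3, restarts = 1, seed = 7))
sol
evaluate_solution(sol, sim$truth, sim$instance$index)
```
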