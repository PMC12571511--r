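# clonedecon

Joint clonal deconvolution and phylogeny inference from multi-sample bulk
DNA sequencing, guided by single-cell RNA copy numbers.

## What it does, and for whom

Bulk DNA-seq sees every variant class — SNVs, allele-specific segmental
copy-number alterations (CNAs), structural-variant (SV) breakpoint ends —
but only as mixture averages over the clones in a sample. scRNA-seq
resolves clones but supports only segmental copy-number calls. For cancer
genomics analyses that have both (e.g. matched bulk WES/WGS and scRNA-seq
of the same tumor), `clonedecon` reconstructs:

* integer clonal genotypes `C` over all three variant classes,
* a rooted binary clonal phylogeny under a loss-supported Dollo model
  (mutations gained once, lost only with loss of their segment allele),
* per-sample clone mixture fractions `U`, and
* a one-to-one mapping `M` of DNA clones to scRNA-derived copy-number
  clones.

All are estimated jointly by minimizing, with entrywise L1 norms,

```
min over U, C, M of  |F − U·C| + |C′ − M·C_RNA| + λ₁·R + λ₂·S
```

where `F` (m samples × (l+g+2r) variant columns) holds observed average
copy numbers, `C_RNA` the clone-level allele-specific segment copy numbers
from scRNA-seq, `C′` the segment block of `C`, `R` the sum of L1 segment
copy-number distances along tree edges (a minimum-evolution cost), and `S`
a consistency penalty between observed and estimated
breakpoint-to-segment mixture copy-number ratios. Optimization is by
coordinate descent: a continuous linear program for `U` alternates with an
integer linear program for `C`, the tree, and the mapping (solved with
HiGHS through a bundled SciPy bridge). Defaults
`λ₁ = ((l+g+2r)·m) / (2·(2r)·n)` and `λ₂ = (l+g+2r) / (2·(l+g))` scale the
regularizers to the fit term.

The package also ships a ground-truth simulator (`simulate_instance()`),
an exhaustive small-instance oracle (`oracle_solve()`) certifying the ILP
encoding, evaluation utilities (clone matching + RMSEs), VCF/TSV/CSV
readers and writers, and a command-line entry point.

## Worked example

```r
library(clonedecon)

# simulate 5 clones, 3 bulk samples, 4 segments, 2 SVs, 6 SNVs
sim <- simulate_instance(sim_config(n = 5, m = 3, r = 4, l = 4, g = 6,
                                    cmax = 4, seed = 7))
sol <- run_deconvolution(sim$instance,
                         run_config(iterations = 3, restarts = 1, seed = 7,
                                    time_limit = 120))
sol
#> clone_solution: 5 clones x 18 variant columns, 3 samples
#>   objective 6.06292 = fit 0.348905 + rna 0 + lambda1*phylo 5.4 + lambda2*ratio 0.314015

evaluate_solution(sol, sim$truth, sim$instance$index)[-1]
#> $rmse_u        [1] 0.1349...   # clone-matched mixture-fraction RMSE
#> $rmse_sv       [1] 0           # SV copy numbers recovered exactly
#> $rmse_snv      [1] 0.516...
#> $rmse_segment  [1] 0
```

The printed breakdown is the four objective terms: deconvolution fit
`|F − UC|`, RNA consistency `|C′ − M·C_RNA|`, and the weighted
phylogenetic (`λ₁R`) and ratio (`λ₂S`) regularizers. A zero RNA term
means the deconvolved segment copy numbers agree exactly with the
scRNA-derived clones under the inferred mapping. `write_solution()`
exports `U.tsv`, `C.tsv`, `C_prime.tsv`, `M.tsv`, `tree.edgelist`,
`tree.dot` and a `run_summary.json` with the full iteration log.

From a shell, the same workflow is:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "clonedecon", package = "clonedecon"))')
Rscript $CLI simulate --out inst_dir --clones 5 --samples 3 --seed 7
Rscript $CLI run --instance inst_dir --out run_dir --iterations 3 --restarts 3 --seed 7
Rscript $CLI evaluate --solution run_dir --truth inst_dir --out eval.json
```

Real data enter through `read_bulk()` (per-sample VCFs with `AF` INFO
fields and BND-style breakend mates, plus shared-grid segment tables) and
`read_rna_cn()` (per-clone or per-cell CSV), or directly as an `F` matrix
via `read_instance()`. `subsample_variants()` thins large variant sets
without separating breakend mates.

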