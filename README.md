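# cfdecon

Can DNA released by a rare dying cell type be detected in plasma cell-free
DNA (cfDNA) by whole genome bisulfite sequencing (WGBS)? `cfdecon` is an R
package for answering that question end to end, motivated by the search
for a motor-neuron (MN) specific biomarker of amyotrophic lateral
sclerosis. It is aimed at computational biologists working on liquid
biopsy, methylation-based tissue-of-origin deconvolution, and biomarker
feasibility analysis.

The package provides:

* **Synthetic WGBS data with known ground truth** — cell-type reference
  methylomes with planted cell-type-specific hypomethylated blocks
  (target-vs-rest propensity gap 0.8 by default), fragment sampling at
  2.5-30x coverage with bisulfite miscall noise, and cfDNA mixtures with
  spike-in fractions of 0-10% defined over CpG calls. Fragment-level data
  travel as 4-column PAT records (`chrom, start, pattern, count`).
* **Co-methylated block segmentation** — a greedy homogeneity scan
  (`min_cpg >= 4`, `max_bp <= 5000`, mean absolute difference <= 0.25),
  block methylation tables with depth-based missingness (NA below 10x for
  clustering, below 5 calls for marker selection), top-1%-variance
  filtering, and average-linkage / city-block sample clustering.
* **Marker selection** — per cell type against the rest: blocks with more
  than 1/3 NA in either group removed, candidates kept when the
  group-mean difference is >= 0.3 with Welch t-test p <= 0.05, ranked by
  the margin between the background 2.5th and target 75th percentile,
  top k in {25, ..., 500} retained.
* **Fragment-level U/X/M deconvolution** — fragments classified as
  mostly-Unmethylated / miXed / mostly-Methylated over each marker
  (thresholds 0.25/0.75, >= 3 in-marker calls), a markers x cell-types
  U-fraction atlas, and non-negative least squares
  `min ||Ax - b||, x >= 0` with proportions normalised to sum to one.
* **Spike-in evaluation** — seeded grids over fraction x coverage x
  marker count, with detection probability, Mann-Whitney AUC, recovery
  linearity (OLS of estimated on true fraction) and a false-positive
  model of detected-cell-type count on coverage and marker count.
* **A closed-form detectability bound** — the steady-state infusion
  model `C = d * k0 * t1/2 / (ln 2 * Vd)` with `k0 = n_cells *
  genome_mass / duration`, its inverse (required death rate for a target
  cfDNA fraction), and duration x availability scenario grids.

## Worked example

```r
library(cfdecon)

# a small synthetic world: 3 cell types, 3000 CpGs, 12 planted blocks each
cfg  <- sim_config(n_cell_types = 3, n_cpgs = 3000, blocks_per_cell_type = 12,
                   coverage = 30, seed = 55)
map  <- build_cpg_map(cfg)
refs <- simulate_reference_methylomes(map, cfg)

# three replicate reference samples per cell type
samples <- list()
for (ct in refs$cell_types) for (r in 1:3) {
  samples[[paste0(ct, "_r", r)]] <-
    sample_fragments(refs, cell_type = ct, seed = 55 + 100 * match(ct, refs$cell_types) + r)
}
groups <- split(names(samples), sub("_r[0-9]+$", "", names(samples)))

# segment, tabulate, select markers, build the atlas
beta   <- vapply(samples, function(s) {
  t <- cfdecon:::per_cpg_tally(s, nrow(map)); ifelse(t$total > 0, t$meth / t$total, NA)
}, numeric(nrow(map)))
blocks <- segment_genome(beta, map)
tab    <- block_methylation_table(blocks, samples, min_depth = 5)
sel    <- select_all_markers(tab, groups, marker_config(k = 12))
pool   <- function(ct) fragment_collection(
  do.call(rbind, lapply(samples[groups[[ct]]], as.data.frame)), n_cpgs = nrow(map))
atlas  <- build_atlas(lapply(setNames(nm = names(groups)), pool), sel)

# spike 10% of ct01 into a ct02/ct03 background at 20x and deconvolve
bg  <- mix_fragments(pool("ct02"), pool("ct03"), 0.5, 20, seed = 322)
spk <- sample_fragments(refs, cell_type = "ct01", coverage = 20, seed = 321)
fit <- deconvolve(mix_fragments(bg, spk, 0.10, 20, seed = 7), atlas)
print(fit)
#> U/X/M deconvolution fit: 36 markers, 1120 fragments, residual 0.5273
#> Estimated proportions (non-zero):
#>   ct03   ct02   ct01
#> 0.4603 0.4176 0.1221

# the theoretical ceiling: all 500,000 MN dying over 24 h, optimistic d = 3%
print(steady_state_concentration(pk_params()))
#> Steady-state result
#>   infusion rate k0 = 2243 pg/min
#>   concentration C = 0.003689 pg/ul
#>   fraction of total cfDNA = 1.242e-05 (0.001242%)
```

The deconvolution sees the 10% spike at 12.2% (36 small markers give a
coarse estimate; the spike-in grids quantify how precision scales with
marker count and coverage) with the remainder split between the two
background cell types, and the pharmacokinetic bound shows
that even a catastrophic 24-hour loss of every lower motor neuron would
contribute ~0.0012% of plasma cfDNA — orders of magnitude below the ~1%
WGBS detection limit measured by the spike-in experiments.

A YAML-configured end-to-end run (`run_pipeline()`) and a thin CLI
(`inst/cli/cfdecon`, subcommands `run-all`, `spike-eval`, `pk`, ...) wrap
the same functions.

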