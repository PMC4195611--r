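# mxsplice

Quantitative profiling of **mutually exclusive alternative splicing**
from barcoded long-read amplicon sequencing, modelled on arthropod
*Dscam1*, plus efficiency-corrected qPCR relative-expression analysis.

Within the sequenced exon 3–10 region of *Dscam1*, every mature
transcript splices in exactly one variant from each of three tandem
exon clusters — 12 variants in cluster 4, 48 in cluster 6 (6.11 is a
never-expressed pseudo-exon) and 33 in cluster 9 — for a theoretical
space of 12 × 48 × 33 = 19,008 ectodomain isoforms. The package is
aimed at researchers asking whether an immune challenge (or any
two-condition contrast) biases that splicing, and provides the full
analysis stack:

* **Reference model** — a synthetic combinatorial exon library with
  guaranteed inter-variant divergence, serialized as FASTA + TSV
  (`build_reference()`, `isoform_space_size()`).
* **Simulator** — barcoded amplicon reads with per-base
  substitution/insertion/deletion errors and complete ground truth, and
  qPCR crossing-point (Cp) tables with per-gene amplification
  efficiencies (`simulate_experiment()`, `simulate_cp_table()`).
* **Isoform caller** — barcode demultiplexing, a k-mer-seeded banded
  local aligner with BLAT-style thresholds (tile 8, step 5, one-off
  seeds, min score 20, min identity 70), and per-cluster variant
  calling that retains a read only when clusters 4, 6 **and** 9 are all
  unambiguously resolved (`demultiplex()`, `classify_reads()`,
  `count_assignments()`).
* **Splice statistics** — median-of-ratios size factors, a negative
  binomial exact test per exon variant (blind-pooled dispersion with a
  parametric mean–dispersion fit; Poisson limit when the fitted
  dispersion is ≤ 0), Benjamini–Hochberg correction, per-cluster usage
  proportions and isoform-frequency correlations
  (`nb_exact_test()`, `exon_usage_test()`, `frequency_correlation()`).
* **qPCR analysis** — the Pfaffl ratio
  `E_target^dCp(target) / E_ref^dCp(ref)` and the pair-wise **fixed
  reallocation randomization test** (2000 reallocations, exhaustive
  when possible) for significance (`pfaffl_ratio()`,
  `fixed_reallocation_test()`).

The repository is organised as an analysis workflow: the numbered
scripts under `analysis/` (01 reference → 02 simulate → 03 call →
04 splice stats → 05 qPCR) narrate the study end to end and write
their tables under `results/`, while every computation lives in the
package under `R/` and `src/` where the tests can reach it.

## Worked example

```r
library(mxsplice)

lib <- build_reference(seed = 1)
lib
#> Mutually exclusive exon library
#>   constitutive exons: 5 (3, 5, 7, 8, 10)
#>   variable clusters:  4 (12), 6 (48), 9 (33)
#>   pseudo-exons: 6.11
#>   isoform space: 19,008

# two barcoded libraries, no true splicing change, CCS-like errors
cfg <- experiment_config(n_reads = 20000,
                         profile_control = study_profile(lib),
                         mode = "null",
                         barcodes = setNames(default_barcodes()[1:2],
                                             c("control", "e_coli")),
                         seed = 2024)
sim <- simulate_experiment(cfg, lib)

calls <- classify_reads(setNames(sim$reads$sequence,
                                 sim$reads$read_id), lib)
tb <- count_assignments(calls[grep("^control", calls$read_id), ],
                        sample = "control", lib = lib)
tb
#> Count table for sample: control
#>   reads: 20000  retained: 20000 (100.0%)
#>   dropped: missing = 0 , ambiguous = 0
#>   distinct isoforms: 2186
```

Retention is the fraction of reads whose cluster-4, -6 and -9 variants
were all called without ambiguity — only those reads contribute counts.
Running the per-exon test between the two conditions
(`analysis/04_splice_stats.R`) prints

```
per-exon tests: 93 variants, 0 with BH-adjusted p < 0.05
no exon variant changes usage significantly after exposure
```

i.e. under a null simulation the pipeline correctly reports no usage
shift for any variant, while per-exon frequencies between the two
libraries correlate with r² ≈ 0.999. The qPCR arm
(`analysis/05_qpcr_rest.R`) reports, for a simulated strong
*Diptericin* induction with unchanged *Dscam1* (fly arm, 2 biological
replicates per group):

```
Diptericin: ratio = 116.6 (reallocation mean 20.1, SE 19.3), p = 0.3333 [exhaustive, n = 6]
Dscam1:     ratio = 1.069 (reallocation mean 1.014, SE 0.0762), p = 1 [exhaustive, n = 6]
```

`ratio` is the efficiency-corrected fold change (treated over control,
normalized to *rpL13a*); with 2 vs 2 replicates the exhaustive
randomization test has 6 reallocations, so its smallest attainable
two-sided p is 1/3 — effect sizes, not p-values, are the readout at
that sample size.

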