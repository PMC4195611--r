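---
title: "Methods: quantifying mutually exclusive splice isoforms from long amplicon reads"
author: "mxsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mutually exclusive splice isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Arthropod *Dscam1* generates enormous receptor diversity by mutually
exclusive alternative splicing: within the sequenced exon 3–10 region,
each mature transcript contains exactly one variant from each of three
tandem exon clusters — 12 variants in cluster 4, 48 in cluster 6 (one of
which, 6.11, is a never-expressed pseudo-exon) and 33 in cluster 9 —
giving 12 × 48 × 33 = 19,008 possible ectodomain isoforms. (Two further
variants sit in the intracellular cluster 17, outside the amplicon; the
package carries them as metadata only, for a total of 95 variable
exons.) A long-standing hypothesis is that pathogen exposure biases
which variants are spliced in. Testing it requires quantifying, from
long amplicon reads that span all three clusters, (i) per-variant usage
in each condition, (ii) whole-isoform (triple) frequencies, and (iii)
whether any variant's usage differs between an exposed and a control
sample. A parallel qPCR arm asks whether overall expression of *Dscam1*
and of antimicrobial peptide genes changes after exposure.

`mxsplice` implements this entire workflow as a tested R package: a
synthetic data generator standing in for the (undeposited) sequencing
reads and crossing-point tables, the read classifier, the count
statistics and the qPCR analysis. The numbered scripts under
`analysis/` run the workflow end to end; every computation they perform
lives in the package and is exercised by the test suite.

## The synthetic exon library and read generator

`build_reference()` creates the alignment reference. Sequence content
is synthetic; the architecture (cluster sizes, one-variant-per-cluster
splicing, the silent 6.11) is what matters. Variants of a cluster are
generated by mutating a shared ancestor and rejection-sampled until all
pairwise divergences reach `min_intervariant_divergence` (default
0.25). The real variant exons are distinguishable by alignment, so the
synthetic ones must be too; 0.25 is a modeling choice, not a measured
value, and the builder fails loudly when a requested divergence cannot
be met. Variable exons default to 120 nt and constitutive exons to
150 nt, giving a ~1.1 kb amplicon comparable to the real exon 3–10
product. Amplicons carry a 7-bp sample barcode at the 5′ end of both
strands; the built-in barcode set has minimum pairwise Hamming
distance 3.

`simulate_experiment()` draws isoforms independently per cluster from a
usage profile, assembles barcoded amplicons, emits each read on a
random strand and applies an i.i.d. per-base error model (defaults
0.5% substitution, 0.5% insertion, 0.5% deletion — circular-consensus
scale). The model deliberately omits PCR chimeras, template switching
and quality-score structure: it is the simplest generator that
exercises ambiguity handling in the caller. Consequently, passing tests
demonstrate correctness of the algorithms under calibrated noise, not
robustness to every artefact of a real sequencing run.

Two profile presets matter. `uniform_profile()` spreads usage evenly
over all expressed variants and is used for calibration studies, so
that every variant is testable. `study_profile()` emulates the pattern
seen in vivo — one lowly expressed cluster-4 variant (4.9, ten-fold
down), silent 6.11, and an exon-9 cluster restricted to four expressed
variants; the identities of the restricted variants are a synthetic
choice. The sequencing arm of the original design pooled replicates
into one library per treatment, so the simulator's biological
between-replicate variance knob (`profile_jitter_sd`) defaults to 0;
it exists for sensitivity analyses but is not asserted anywhere.

## Read classification

The caller mirrors a BLAT-style search without shelling out to an
external binary, which keeps the pipeline self-contained and testable
against an exact oracle. Exons are tiled into 8-mers every 5 bp, with
all one-mismatch neighbours indexed (`-tileSize 8 -stepSize 5
-oneOff 1` analogues). For each read the better-seeded orientation is
chosen once — a read is a single molecule — and every exon whose seeds
cluster on nearby diagonals (≥ 2 seeds within a 10-diagonal window) is
extended by banded affine-gap local alignment (match +1, mismatch −1,
gap open 2, gap extend 1; band = seed window ± 6 diagonals). An
ungapped pre-screen (best diagonal score ≥ 8) skips hopeless
extensions. Hits are reported when score ≥ 20 and identity
(matches / aligned columns) ≥ 70%; coordinates are 0-based half-open on
the original read strand. The test suite checks the banded scores and
per-cluster winners against full (unbanded) Smith–Waterman via
`Biostrings::pairwiseAlignment` under the identical scoring scheme.

Calling is per cluster: a cluster is *assigned* when exactly one
variant's best score beats every other variant's best score by at least
`margin` (default 1 — a strict maximum on integer scores), *ambiguous*
when two variants tie within the margin, *missing* when no hit passes
the thresholds. A read is retained if and only if clusters 4, 6 and 9
are all assigned; constitutive-exon hits inform orientation and sanity
checks but never retention. The margin operationalizes "unambiguously
revealed"; no published definition of the original ambiguity criterion
exists, and a strict-maximum rule is the most conservative choice that
never invents a call. At the default library divergence the retained
misassignment rate is below 0.1% (simulation-tested), and on error-free
reads the pipeline reproduces the generating truth table exactly.

## Per-exon differential usage

Counts are depth-normalized with median-of-ratios size factors. Each
variant is then tested with a negative binomial exact test conditional
on its two-condition total: the null conditional probability of `k`
reads in condition A given the total is proportional to the product of
two NB densities with pooled mean, and the two-sided p-value sums all
outcomes at most as likely as the observed one. With one pooled library
per condition there are no replicates, so dispersion is estimated in
"blind-pooled" mode — the two conditions are treated as replicates,
the conservative no-replicate strategy — by method of moments,
stabilized through a parametric mean–dispersion fit
`alpha = a0 + a1/mean` (ordinary least squares). A parametric fit
replaces a local-regression smoother deliberately: it is deterministic,
has no spanning parameters, and at these depths the fitted values are
near zero anyway. Wherever the fitted dispersion is ≤ 0 the test drops
to its Poisson limit (a conditional binomial). Multiple testing is
corrected by Benjamini–Hochberg, by default within each cluster as its
own family (each cluster is a separate biological question); a pooled
family is available and the choice is recorded on the result object.

Calibration and power, under the study conditions, are part of the
acceptance suite: across 500 null simulations at 5,000 reads per
condition the raw p < 0.05 rate sits in [0.03, 0.07] (slightly
conservative, as expected for a discrete exact test) and the
probability of any BH rejection at 0.05 stays at or below 0.05; a
four-fold usage shift on one cluster-4 variant at 20,000 reads per
condition is detected with BH-adjusted p < 0.05 in well over 90% of
runs. The replicated arms simulate at the count level
(`sample_variant_counts()`, marginally identical to tabulating
sampled isoforms) so that 500 replicates finish in seconds; the
sequence-level pipeline is exercised by the caller-fidelity and
recovery checks at 10^4 and 10^5 reads.

## Frequency correlations

Figure-style concordance analyses correlate per-variant or per-isoform
*frequencies* (counts over retained totals — libraries differ in
depth; whether the original figures used counts or frequencies is not
stated, and frequencies are the depth-invariant choice) on the union of
ids observed in either sample, with absent ids counted as zero, and
report Pearson r² with a two-sided t-distribution p-value. One caveat
the simulation makes visible: isoform-level r² is governed by the
spread of true isoform frequencies relative to Poisson counting noise.
Under near-uniform generating profiles, thousands of isoforms have
almost identical true frequencies and r² is legitimately small even
between replicate runs of the same profile, whereas per-exon r²
approaches 1. High isoform-level correlations in real data reflect
strongly non-uniform isoform usage, which the default synthetic
profiles do not attempt to reproduce.

## qPCR relative expression

`pfaffl_ratio()` implements the efficiency-corrected ratio
E_target^ΔCp(target) / E_reference^ΔCp(reference), with
ΔCp = mean Cp(control) − mean Cp(treated) and per-gene amplification
efficiencies (panel defaults: *Diptericin* 1.979, *Drosomycin* 1.945,
*Dscam1* 2.0, reference *rpL13a* 1.98; efficiencies are validated to
lie in (1, 2]). Significance uses the pair-wise fixed reallocation
randomization test: the per-replicate (target, reference) Cp pairs are
pooled and reallocated to two groups of the original sizes — each
replicate's two values stay together, which is what "fixed" pairing
means here — recomputing the ratio every time. Two-sidedness is
|log ratio| exceedance, symmetric on the log scale. With ≤ 2000
distinct reallocations the test enumerates exhaustively and the
p-value is exact; otherwise 2000 random reallocations are drawn
(default, seeded). The reported mean and SE describe the reallocated
ratio distribution, alongside the observed point ratio; no claim of
bit-compatibility with any REST release is made.

Two granularity facts shape interpretation at small n. With 2 vs 2
replicates there are 6 reallocations and the smallest attainable
two-sided p is 1/3; with 3 vs 3 it is 0.1. Significance at
alpha = 0.05 is therefore mathematically impossible at those sizes
under paired exhaustive reallocation, and the package's power and
uniformity properties are demonstrated at 5 vs 5 (power ≥ 0.9 for a
one-cycle shift at noise SD 0.1) and 6 vs 6 (924 reallocations, where
null p-values are uniform by Kolmogorov–Smirnov). Cp noise is Gaussian
on the cycle scale, standard qPCR practice; Cp values are consumed as
given and the second-derivative-maximum computation from raw
fluorescence is out of scope.

## Numerical and design notes

* All generators, the caller and both test procedures are
  deterministic under fixed seeds; `scripts/acceptance.R` derives every
  stream from its `--seed` argument.
* Exact-test tail sums use log-density arithmetic normalized by the
  maximum, with the conventional `(1 + 1e-7)` tie tolerance when
  comparing outcome likelihoods.
* All-zero variants return p = 1 with an `all_zero` flag; calibration
  rates are computed over expressed variants only, since an unexpressed
  exon is not a testable hypothesis. Fold changes use no pseudocount; a
  zero denominator reports `Inf` with a flag.
* Degenerate inputs fail loudly and by name: zero-variance frequency
  vectors, missing genes or groups, reference-gene shifts, group sizes
  below 2, unsatisfiable divergence constraints.
* Problem sizes in the acceptance suite — 10^4 error-free reads for
  caller fidelity, 10^5 for proportion recovery (max per-variant error
  ~10^-3, bound 0.01), 500 replicates for calibration and uniformity,
  100 for power — were chosen so the whole suite completes in minutes
  on one core while keeping Monte-Carlo error well inside each
  asserted band.

## Known limitations

* The error model is i.i.d. per base; real long-read artefacts
  (homopolymer indels, chimeras, strand bias) are not represented.
* The aligner is seeded and banded: hits with fewer than two clustered
  seeds, or optimal paths wandering far off the seeded diagonals, can
  be missed. The acceptance checks bound the practical consequences at
  study-scale error rates.
* Dispersion estimation from two pooled libraries cannot separate
  biological from technical variance; as in any no-replicate design,
  the "blind-pooled" strategy is conservative against usage shifts
  that affect many variants at once.
* The isoform-level correlation analysis inherits the near-uniform
  synthetic profiles' low true variance (see above), so its r² values
  are not comparable to figures derived from real, strongly non-uniform
  isoform repertoires.
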