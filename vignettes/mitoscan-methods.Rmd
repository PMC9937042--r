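---
title: "Scanning for selection on mitonuclear-interacting genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for selection on mitonuclear-interacting genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscan)
```

## The question

Aerobic respiration depends on tight physical interactions between
mitochondrially encoded molecules and a few hundred autosomal genes:
OXPHOS subunits, mitochondrial aminoacyl-tRNA synthetases (ARS2),
mitoribosomal proteins (MRP) and mtDNA replication factors (REP). We
call these *N-interact* genes. In species where females stay in their
natal group and males migrate, mitochondrial lineages are anchored
geographically while autosomal variation is homogenised by male
dispersal, so N-interact alleles are continually tested against
mitochondrial backgrounds they did not co-evolve with. If that exposure
drives recurrent selection, N-interact loci should look different from
the rest of the genome: longer runs of homozygosity (ROHs) around them,
locally reduced diversity, elevated between-population differentiation,
a left-shifted site-frequency spectrum, and sometimes faster protein
evolution.

`mitoscan` implements that comparison as a reusable pipeline. Every
statistic is computed per genomic interval; intervals are classed
`N_INTERACT` (they contain the transcription start site of at least one
N-interact gene), `NON_N_INTERACT` (at least one gene TSS but no
N-interact gene), or `NONGENIC` (no TSS), and inference always contrasts
the first two classes. The TSS rule — not gene-body overlap — decides
membership, and windows or ROHs lacking any TSS are excluded from the
models.

## Statistics per interval

**Nucleotide diversity.** At one site with `n` called alleles of which
`n_alt` are alternate, pi is the proportion of differing pairs,
`2 n_ref n_alt / (n (n-1))`. Window pi is the *mean over sites
polymorphic within the group* — a per-polymorphic-site quantity, not
per-bp (a per-bp column is emitted alongside for completeness). Windows
with no polymorphic site are missing, not zero.

**F_ST.** Per-site Weir–Cockerham (1984) two-population variance
components by default, with a plain Hudson-style ratio
(`(p1-p2)^2 / (p1(1-p2)+p2(1-p1))`) selectable; the literature this
scan descends from is ambiguous about the exact estimator, so both are
exposed as configuration rather than a guess. Window F_ST is the
arithmetic mean of per-site values over sites whose *pooled* minor
allele frequency is at least 0.05 (the MAF is pooled across the pair
because the estimator is a two-population quantity). Negative per-site
estimates are retained.

**Tajima's D.** The standardised gap between mean pairwise differences
and the segregating-site estimator, evaluated directly from the 1989
constants. Missing genotypes make the per-site allele count vary; we
use the rounded median called-allele count over the window's
segregating sites as the sequence number `n`, a fixed rule that keeps
`D` well defined without imputing anything.

**ROHs.** A two-state HMM per sample: state AZ (autozygous) emits a
heterozygote with probability epsilon (default 1e-3), state HW emits it
at the Hardy–Weinberg rate `2p(1-p)` from cohort frequencies; the
transition probability across a gap of `d` bp is `1 - exp(-rate d)`
with defaults 6.7e-8 into AZ and 5e-9 out, the published defaults of
the widely used genotype-based caller this module reimplements. Both
states start at probability 1/2, Viterbi ties resolve to HW, missing
genotypes are skipped without breaking runs, and no minimum-length
filter is applied by default. Each maximal AZ run becomes one ROH,
reported 0-based half-open.

**dN/dS.** The Nei–Gojobori (1986) counting estimator with
Jukes–Cantor correction, averaged over all sequence pairs of each
gene's alignment. This is a deliberate, documented divergence from
maximum-likelihood codon models: the counting estimator is exactly
testable against hand-enumerated codon pathways, and the scan only uses
omega comparatively. Mutational pathways through stop codons are
excluded (all pathways are used if none is stop-free); a change to a
stop codon counts as nonsynonymous in the site totals so synonymous and
nonsynonymous sites sum to three per codon. Genes failing QC (no ATG
start, premature stop, length not a multiple of three) or with
omega > 5 are discarded, and when dN is zero but synonymous divergence
was observed omega is reported as 0 even if dS is too saturated to
correct. A neighbor-joining tree (via `ape`, with lexicographic taxon
ordering for deterministic ties) is emitted for reporting only; the
estimator itself is tree-free.

**Patterson's D.** Frequency-based ABBA/BABA sums on the tree
(((P1,P2),P3),O) — the groups here have multiple diploids, so
pseudohaploid sampling would waste information. The genome-wide Z comes
from a delete-one jackknife over (by default) 100 equal-site blocks;
windowed D re-uses the window grid, and the class contrast is an
upper-tail permutation test on window means.

## Inference

Each response (log ROH length in 100-kb units — logged because raw
lengths are strongly right-skewed; window F_ST and pi untransformed) is
modelled as

```
response ~ n_interact + gene_number + n_interact:gene_number
```

by OLS. The interaction term is there because gene-dense intervals
behave differently and we do not want to assume the N-interact effect
is constant across gene counts; the class gap at gene number `g` is
`beta1 + beta3 g`. Results are presented as marginal means on the
integer gene-number grid from the 1st to the 90th percentile of the
observed distribution — beyond that the data thin out and predictions
are extrapolation.

Neighbouring windows are autocorrelated, so OLS standard errors are too
small. For window models we therefore resample contiguous blocks of 30
windows with replacement (per chromosome), refit per replicate (1,000
by default), take the coefficient SD as the standard error, and convert
to p-values by the normal approximation. Confidence bands for marginal
means are the 2.5/97.5 percentiles of replicate predictions. The block
size follows the observed decay of window-level autocorrelation;
rank-deficient replicates are redrawn and counted.

Nonparametric backup for every contrast: one-sided permutation tests of
the class difference in means with the +1 convention,
`p = (#{null >= obs} + 1) / (B + 1)` (upper tail for ROH length, F_ST
and dN/dS; lower tail for pi and Tajima's D), B = 1,000 by default.

**Outlier excess.** Fitting `statistic ~ gene_number` over all
gene-bearing windows, windows with Cook's distance above `4/n` and a
residual of the expected sign (positive for F_ST, negative for pi) are
outliers; whether N-interact windows are over-represented among them is
a one-sided binomial test with success probability equal to the
N-interact share of gene-bearing windows. The cutoff and the linear
model are configuration, not claims about the one true outlier
definition — the recipe is recorded in the output.

**Combination.** Per metric and window size, the per-group or per-pair
permutation p-values combine by Fisher's method, `-2 sum(log p)` on
`2k` degrees of freedom (five clade-level Tajima's D tests give
df = 10; four data-set dN/dS tests give df = 8). Pairwise F_ST
p-values within a data set share samples and are not independent, so
their combination is anticonservative; the report carries that caveat.
The dN/dS comparison draws 3,000 background genes by default (all of
them, with a warning, when the pool is smaller).

## The synthetic-data generator

Everything above is exercised against generated data with planted
truth, because the original wildlife data sets are not redistributable
and a scan of this kind must be validated on inputs where the answer is
known.

Genotypes: each site gets an ancestral frequency from a log-uniform
prior on [0.01, 0.99] — the 1/p shape of the neutral site-frequency
spectrum, chosen so that null windows have Tajima's D near zero — and
each population draws its frequency from the Balding–Nichols Beta
distribution around it with dispersion F (`baseline_fst` 0.05 by
default, a typical intra-specific value for structured primate
populations); genotypes are binomial (Hardy–Weinberg). Balding–Nichols
was preferred to coalescent simulation because it is desk-scale and has
a closed-form F_ST expectation to test against.

Selection is planted in a chosen fraction of N-interact windows, two
ways. Elevated differentiation: those sites use `selected_fst` instead
of the baseline. Sweep signature: with probability
`sfs_skew/(1+sfs_skew)` a swept site's *population* frequencies are
drawn directly and independently from Beta(0.5, 5) — young, mostly
rare variants, which is what a sweep leaves behind. (Skewing only the
ancestral frequency does not work: drift plus conditioning on
polymorphism washes the skew out, which we verified during design.)
This one mechanism lowers per-polymorphic-site pi, pushes Tajima's D
negative by roughly 0.8 relative to the null, and adds
differentiation.

ROHs are planted by overwriting a sample's genotypes with the
population-major homozygote over a stated tract. CDS alignments evolve
star-tree taxa from an ATG-initiated stop-free ancestor; substitution
attempts arrive as a Poisson process and are accepted with probability
`min(1, omega)` if nonsynonymous and `min(1, 1/omega)` if synonymous,
so the realised rate ratio equals the target (omega = 0 is allowed and
means no amino-acid change ever fixes). The four-taxon scenario gives
the sister pair short terminal branches (F/5) and plants introgression
by copying P3's window frequencies into P2 — the strongest reading of
"copied or drifted", and the reason a 30% planted fraction is reliably
detectable.

What the generator does *not* emulate: linkage disequilibrium within
windows (sites are exchangeable given their window), recombination
maps, demography beyond a single drift parameter per branch, mutation
rate variation, or genotyping error. Passing tests therefore show that
the estimators and tests are correct and calibrated on
Hardy–Weinberg-exchangeable data with planted signals — not that the
pipeline's power on real, LD-structured genomes matches the simulated
power.

## Problem sizes and numerical choices

The default simulated genome is one 10-Mb autosome with 8,000 SNPs,
150 genes (25% N-interact, category labels drawn in the catalogue's
observed 101:77:17:4 OXPHOS:ARS2:MRP:REP proportions), two populations
of 10 diploids; sex chromosomes are never emitted. Power checks in the
test suite use the conditions fixed during design: differentiation
recovery at `selected_fst` 0.6 vs 0.05 on 10% of N-interact windows
with 250 genes and 12 diploids per population; sweep recovery at
`sfs_skew` 3 across all N-interact windows; introgression at f = 0.3
with `baseline_fst` 0.25 and 24,000 sites; calibration on 500
replicate 600-site null pipelines; bootstrap behaviour on n = 3,000
(iid) and n = 1,500 (AR(1) rho = 0.8) windows. These sizes were chosen
once, before the corresponding checks were frozen, as the smallest
configurations a desk-scale study of this design would trust.

Numerical conventions worth knowing: window tiling is anchored at
position 0 and trailing partial windows are kept (statistics are
per-site means) but flagged; a TSS on a window boundary belongs to the
right-hand window; duplicate gene ids collapse to the first record
while distinct genes sharing a TSS all count; permutation p-values can
never be zero, and a zero fed to Fisher's method is clamped to
`1/(B+1)` with a warning; bootstrap SEs that are zero to numerical
precision yield NA p-values; Viterbi ties resolve to the
non-autozygous state; Hudson F_ST is the uncorrected ratio (exactly
zero at equal sample frequencies), with Weir–Cockerham as the default
estimator.

## Known limitations

The ROH caller takes hard genotypes only (no likelihoods) and applies
no LD correction, so its absolute tract boundaries are optimistic on
real data. The counting dN/dS estimator saturates sooner than ML codon
models and assumes equal codon usage in its site counts. The raised-eps
monotonicity of the HMM (more tolerated heterozygotes never increasing
the autozygous call count) holds on heterozygote-free input but can
reverse around isolated heterozygotes, where a larger eps lets runs
bridge them. Fisher combinations over pairwise F_ST comparisons are
anticonservative, as noted in every report. The pipeline tests
class-level contrasts; it deliberately does not assign per-window
significance, so no multiple-testing correction across windows is
offered.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
bundle <- write_fixture_bundle(cfg, "sim_bundle")

gm <- read_vcf(bundle$vcf, bundle$groups)
ann <- read_annotations(bundle$gff3, bundle$gene_list)
cds <- read_cds_dir(bundle$cds_dir)

report <- run_scan(gm, ann, pipeline_config(seed = 1),
                   cds = cds)
print(report)
write_results(report, "scan_out")
```
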