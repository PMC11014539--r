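---
title: "Methods: characterizing APOBEC mutagenesis in smoking-associated lung cancer genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing APOBEC mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistics it implements: the
models, their assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical choices
made where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

APOBEC3 cytidine deaminases (chiefly APOBEC3A and APOBEC3B) deaminate
cytosines in single-stranded DNA, leaving C>T and C>G mutations concentrated
in the TpC dinucleotide — canonically the TCW trinucleotide (W = A or T). In
lung tumors from smokers this endogenous process operates alongside the
dominant exogenous tobacco process (C>A-rich, COSMIC SBS4) and the clock-like
CpG deamination process (SBS1). The package quantifies, per sample: how much
of the catalog is APOBEC-attributable; whether the APOBEC mutations are
clustered (kataegis) and strand-coordinated (a proxy for long-lived ssDNA);
whether the tetranucleotide fingerprint looks APOBEC3A-like (YTCA) or
APOBEC3B-like (RTCA); a two-evidence low/high APOBEC subtype call; how long
the tumor lineage took from its most recent common ancestor to diagnosis; and
which lung cell type's expression profile best explains the genome-wide
mutation density.

## Strand convention and motif spaces

All substitutions are reported in the pyrimidine frame: a mutation at a
reference G or A is reverse-complemented, so `pyr_ref` is always C or T and
the 5-base context is centred on the pyrimidine. Motif denominators count
both strands: `n_C` is the number of C plus G positions, and a motif such as
TCW counts once per plus-strand occurrence plus once per occurrence of its
reverse complement. Motifs containing N are never counted and the genome
length excludes N bases.

Two denominator scopes are exposed because the field's motif-enrichment tools
have used both and the appropriate one depends on the question:

* `scope = "windows"` (default, half-width 20, i.e. 41-base windows around
  each mutated cytosine, merged before counting): the local-background
  convention, robust to large-scale composition gradients.
* `scope = "genome"`: whole-genome denominators.

The windowed denominator carries a small conservatism: each mutated TCW site
contributes its own motif to the window inventory, so the background TCW
fraction is slightly inflated and the load estimate slightly reduced. This is
inherent to the windowed convention, and it is one reason the load statistic
is documented as a *minimum* estimate.

## TCW enrichment and the minimum APOBEC load

For a sample with `mut_c` pyrimidine-frame C>T/C>G mutations (C>A is
excluded: the estimand is benchmarked against SBS2+SBS13 chemistry) of which
`mut_tcw` lie at TCW, and context counts `ctx_tcw`, `ctx_c`:

$$E_{TCW} = \frac{mut_{TCW}/ctx_{TCW}}{mut_C/ctx_C}, \qquad
\text{load}_{\min} = mut_{TCW}\,\frac{E-1}{E} \;\; (E > 1,\ \text{else } 0).$$

The one-sided (greater) Fisher exact test on
`[[mut_tcw, mut_c - mut_tcw], [ctx_tcw, ctx_c - ctx_tcw]]` screens for
enrichment only — depletion is not biologically meaningful here. P-values are
Benjamini–Hochberg corrected across the cohort and flagged at Q < 0.05
(`alpha`, overridable). The load is reported raw and half-even rounded.

The load estimator's expectation is `A(1 - f)` when `A` true APOBEC TCW
mutations sit on a background whose C>T/C>G mutations are uniform over
cytosines, with `f = ctx_tcw/ctx_c` (about 0.17 at human-like GC): the
estimator deliberately discounts the TCW mutations that the background rate
alone would have produced, which is what makes it a lower bound. Background
processes restricted to non-TCW contexts (e.g. clock-like CpG mutations)
deepen the conservatism by inflating `mut_c` only.

## Clustered mutations, kataegis, and strand-coordinated ssDNA

Candidate clusters are maximal runs of same-chromosome mutations with
consecutive gaps at most `d_max` (default 1000 bp). `d_max` only bounds the
search: the binding criterion is the cluster P-value threshold `p_max = 1e-4`.
Members closer than 10 bp collapse to one event before the event count `k` is
taken (such complex events arise from a single lesion), keeping the first
coordinate as representative.

Under a constant-rate null with per-base mutation probability
`pi = n / genome_length`, the intervening non-mutated bases of a k-event
cluster sum to a negative binomial with `k - 1` successes, so
`P = Pr(NB(k-1, pi) <= gap_bp)`. The spec of this quantity is a valid CDF in
the gap and monotone in `k`. Regional rate variation is deliberately ignored;
with a genome-wide `pi` the null is conservative in cold regions and
anti-conservative in hot ones, a simplification documented here and standard
at this threshold.

Retained clusters with `k >= 4` are kataegis, `k` in 2–3 omikli. Clusters of
more than 3 events whose members all mutate reference-strand C (or all G)
proxy long persistent strand-coordinated ssDNA; the tract length is the
distance between the bordering mutations, and `scssdna_percent` is the summed
proxy span over the genome length. The 96-channel spectrum of kataegis
members and their TCW C>T/C>G fraction quantify how APOBEC-dominated the
clustered mutations are.

## Subtype rule and the YTCA/RTCA phenotype

Two independent detection routes feed the subtype call: signature
attribution (SBS2+SBS13 at least 5% of the sample's mutations **and** at
least 50 mutations) and motif enrichment (the BH-corrected Fisher flag).
Both positive is HAS; enrichment only is LAS; neither is no_APOBEC. The
remaining cell — signature-positive but enrichment-negative — is essentially
unobservable because the motif test confirms signature-positive samples; it
maps conservatively to LAS with a warning.

The A3A-like versus A3B-like phenotype compares observed YTCA versus RTCA
mutations (Y = C/T, R = A/G — standard IUPAC; note some prior literature
prints the codes inverted) among APOBEC-type TCA-context mutations against
the motif-space expectation, with a 1-df goodness-of-fit chi-square and no
continuity correction (counts are large when the test is reached). Samples
must first pass a TCA-enrichment gate (the TCW Fisher machinery with TCA in
place of TCW, BH-corrected); ungated or non-significant samples are `NA`.

The downstream association stage is ordinary maximum-likelihood logistic
regression of a binary genomic feature on subtype (LAS as reference) with
covariates encoded as indicators (sex, histology) or numerics (age, purity,
and log10 TMB — the transform is this package's choice), alongside the
unadjusted two-sided Fisher test. Complete separation is flagged, never
silently dropped.

## Clock-mutation timing: MRCA and latency

Clock-like mutations are pyrimidine-frame C>T at NpCpG. Clonality comes from
the cancer-cell fraction with threshold 0.8 (configurable; when CCF is absent
the stage refuses rather than guesses). The diploid-equivalent clonal burden
`n_clonal/(ploidy/2)` is Poisson with mean `r_i * age_i`; per-sample rates
are partially pooled around a cohort rate with log-normal spread, fit as a
Poisson GLMM with per-sample random intercept and `log(age * ploidy/2)`
offset (lme4). Purity enters upstream through the CCF threshold, not as a
divisor, avoiding double correction; samples with purity at or below 0.3 or
NRPCC at or below 10 are excluded before fitting. If the mixed model's inner
loop fails on a degenerate cohort (zero between-sample variance), the pooled
Poisson GLM — the exact limiting model — is used instead.

Latency converts the subclonal clock burden at an accelerated rate:

$$\text{latency} = \frac{n_{subclonal}/(\text{ploidy}/2)}{r_i \cdot A},
\qquad \text{MRCA age} = \text{age} - \text{latency},$$

with `A = 5` by default (the elevated mutational burden of the expanding
tumor), floored at zero with a flag. Latency is exactly homogeneous of degree
−1 in `A`. Only subclonal *clock* mutations are used (the alternative —
scaling all subclonal mutations by a clock fraction — is not implemented as a
default; clock-only is the cleaner estimand and what the burden model
justifies).

## Cell-of-origin inference

Somatic mutation density is depleted in regions highly expressed in the cell
of origin (transcription-coupled repair and open-chromatin accessibility of
repair machinery). Binned counts are regressed, one cell type at a time, as
`count ~ GammaPoisson(exp(b0 + b1 * centroid + gamma * covariates), phi)`
with variance `mu + phi mu^2` (MASS::glm.nb; `phi = 1/theta`), covariates
being replication timing, GC fraction, mean expression across centroids, and
log intronic/exonic fractions. The relative risk `exp(b1)` gets a Wald 95%
interval on the log scale. The origin call is the argmin of rr — the
depletion convention, invertible via a flag because the sign convention is
genuinely open; ties break toward the narrower interval. The default schema
is the seven benign lung cell types (basal, neuroendocrine, goblet, ciliated,
club, AT1, AT2) with Club/Basal/Ciliated/Goblet/Neuroendocrine mapped to the
proximal airway lineage and AT1/AT2 to the distal alveolar lineage; arbitrary
schemas are accepted. Fixed-width bins suffice to exercise the stage — no
gene-model dependency is required.

## The synthetic-cohort generator

The generator exists so every stage is verifiable against known truth without
any protected data. It emulates:

* an i.i.d. reference of configurable GC (default 0.41, human-like);
* a smoking-like process (C>A at cytosines), an APOBEC process (C>T/C>G 1:1
  at TCW, TCA-context sites split YTCA/RTCA at `ytca_bias`), a flat process
  (uniform position, uniform alternative), and a clock process (C>T at NpCpG,
  clonal count Poisson in `age * clock_rate * ploidy/2` with per-sample
  log-normal rate spread, sd 0.2, and subclonal count Poisson in
  `latency * clock_rate * A * ploidy/2`, A = 5) — so simulator truth is
  defined by the timing estimator's own generative skeleton;
* kataegis events (Poisson count, k = 6 + Poisson(2) members,
  strand-coordinated TCW sites, geometric gaps of mean 100 bp), labelled
  APOBEC and counted inside the APOBEC weight;
* a clonal/subclonal CCF structure (subclonal probability 0.15, subclonal
  CCF uniform on 0.2–0.5) — a threshold-logic stand-in, not a subclone
  deconvolution model;
* signature attributions taken from truth labels (SBS2+SBS13 := APOBEC,
  SBS4 := smoking, SBS1 := clock, SBS5 := flat), so subtype tests isolate the
  decision rule from extraction noise; an optional multiplicative noise knob
  stresses the 5%/50 thresholds;
* cell-of-origin bin counts drawn from the Gamma-Poisson model itself
  (defaults b1 = −0.5, phi = 0.3, 500 bins) against simulated centroids and
  covariates.

Everything is deterministic given the configuration and seed, to the byte in
the emitted files.

**Problem sizes.** The package's verification cohorts use 1 Mb genomes with
2000 SNVs per sample for motif and enrichment statistics — enough motif sites
(hundreds of thousands) for stable denominators — and 10 Mb genomes for the
clustered-mutation scenarios, where what matters is the per-base mutation
probability: 2000 SNVs on 10 Mb give pi = 2e-4, approaching the sparsity
regime of whole-genome data in which a P <= 1e-4 cluster filter has its
intended discriminating power. Timing cohorts use 60 samples at 300 kb (the
clock statistics depend on absolute clock counts, not genome size).

**What the generator does not emulate**, and hence what passing tests do not
establish about real data: regional mutation-rate covariates (replication
timing, chromatin) and their confounding of cluster detection; copy-number
structure and its effect on CCF estimation; signature-extraction noise
(attributions are truth-derived by design); sequencing artifacts; and
realistic k-mer composition beyond GC content (the i.i.d. reference has no
CpG depletion, so clock-site density is higher than in human genomes). The
desk-scale compression also over-represents absolute clock counts relative to
a 2000-SNV catalog compared with real tumors, which is why the load-soundness
scenario is run on the dispersed-process catalog the scenario statement
describes.

## Numerical and degenerate-input choices

* Empty catalogs warn, never error; enrichment propagates `E = 0`, P = 1.
* Zero motif denominators are an error (`undefined_statistic`), not NaN.
* BH adjustment preserves input order; a lone sample's Q equals its P.
* `cluster_pvalue` takes the intervening-failure-base count; at k = 2 and
  adjacent positions it equals `pi` exactly.
* Chi-square cells with zero expectation return `NA` with the zero-count
  flag rather than dividing by zero.
* Half-even rounding for the integer load companion.
* All file interfaces are 1-based inclusive (VCF/MAF) except BED output,
  which is 0-based half-open; internally R's native 1-based indexing is used
  throughout.
* Seeds: every stochastic routine takes an explicit seed; cohort runs derive
  per-sample seeds from the master seed below 2^31.

## Known limitations

The constant-rate cluster null ignores regional rate variation. The subtype
rule consumes external signature attributions as given. The timing model
reads "subclonal architecture" as a single subclonal clock burden; it does
not time copy-number gains or deconvolve subclones. The COO stage requires
user-supplied bins, covariates and centroids; it does not derive centroids
from single-cell atlases. None of the stages call somatic variants, estimate
purity/ploidy, or extract signatures — those are consumed as inputs.
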