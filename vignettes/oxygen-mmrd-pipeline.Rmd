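---
title: "Dissecting oxygen-dependent MMRd mutagenesis with isomutsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting oxygen-dependent MMRd mutagenesis with isomutsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomutsig)
```

## The scientific problem

Mismatch repair (MMR) corrects base-base mismatches left behind by the
replicative polymerases. Cells that have lost MMR (through *MSH6* or *MLH1*
defects, for example) accumulate single base substitutions (SBS) and short
indels at a high, measurable rate, which makes them a sensitive read-out for
the processes that *create* mismatches in the first place. One such process
is oxygen-dependent: isogenic MMR-deficient clones cultured at atmospheric
oxygen accumulate roughly twice as many mutations per population doubling as
clones kept at mild hypoxia, the excess being dominated by T>C transitions in
specific triplet contexts, enriched on the lagging strand and in
late-replicating regions, and showing no transcription-coupled repair
footprint — the hallmarks of a replicative error process rather than direct
oxidative base damage.

`isomutsig` re-implements the computational machinery needed to make and test
those observations, end to end, with synthetic data generators that plant a
known truth at every stage:

1. **Isogenic mutation calling** from per-sample, per-position allele-count
   tables (an IsoMut-style filter with Fisher-score calibration against
   ancestral clones).
2. **Spectrum construction** in the COSMIC SBS96 and ID83 channel systems,
   plus extended-context enrichment logos.
3. **Signature analysis**: non-negative least squares refitting, strict
   greedy signature removal, de novo NMF extraction, oxygen difference
   spectra and two-component decompositions of stratified mutation sets.
4. **Genome context**: replication timing (interpolated, decile-binned),
   replication fork directionality (RFD) from OK-seq-style counts,
   replication/transcription strand assignment and chi-square strand-bias
   tests.
5. **Clonality and rates**: two-centre VAF clustering into clonal/subclonal
   compartments, per-population-doubling mutation rates, and the paired and
   unpaired group comparisons.

## The caller and its parameters

The caller consumes a table of per-sample allele counts at shared positions
(a stand-in for pileups; the producer is responsible for base-quality
filtering) and emits mutations *unique to a single sample* within the
isogenic set. A candidate is emitted for sample $s$ at a position iff:

* the most frequent non-reference allele of $s$ has frequency $\geq$
  `min_alt_vaf` (default **0.2**),
* the coverage of $s$ is $\geq$ `min_cov` (default **5**), and
* every other sample's reference-allele frequency is $\geq$
  `min_other_ref_af` (default **0.93**); a sample with zero coverage fails
  this test, because absence of evidence must not support a unique call.

Candidates are scored with
$-\log_{10}$ of the one-tailed Fisher exact probability (hypergeometric upper
tail) on the $2\times2$ table of alt/ref counts in the mutated sample versus
the other sample with the lowest reference-allele frequency. Score
thresholds can be fixed per class (defaults 3.5 SBS / 2.1 insertion / 3.1
deletion) or, preferably, calibrated: the minimal observed score such that
every ancestral clone retains at most 1% of each descendant's SBS calls
(absolute cap of 5 events for indels). Calibration is the procedure we
recommend and test, because the fixed defaults are themselves the *outcome*
of such a calibration on a particular data set; at 30× Poisson coverage with
heterozygous (binomial, VAF 0.5) planted mutations, the fixed SBS threshold
of 3.5 sits close enough to the score distribution of true variants that the
expected recall is ~0.944, while the calibrated pipeline reaches recall
$\geq 0.99$ at precision $\geq 0.99$ on the same simulations.

Determinism choices: ties between equally frequent alternate alleles break
alphabetically (A<C<G<T, then insertion, then deletion); multi-allelic sites
emit only the top alternate; calibration scans only observed score values
plus zero, since any threshold between two observed scores is equivalent.

## Spectrum conventions

SBS96 channels use the pyrimidine-strand representation (purine references
are reverse-complemented with their flanks), blocks ordered C>A, C>G, C>T,
T>A, T>C, T>G, and alphabetical 5′/3′ flanks within a block. ID83 follows
the COSMIC v3 ordering so published indel signature matrices load directly:
1 bp events by homopolymer run length, longer events by tandem-repeat copy
number (counted rightward from the anchored position after left-alignment
against the reference), and deletions without a second tandem copy by
microhomology length. Left-alignment matters: a deletion that looks like a
microhomology event in one representation can be a tandem repeat after
left-alignment, and repeat counting is only well-defined on the left-aligned
form.

Context logos compare the base composition at each position around a
mutation class (pyrimidine-oriented) with a local background of 10 random
positions per mutation drawn within ±1 kb, using
$\log_2((f_{obs}+\varepsilon)/(f_{bg}+\varepsilon))$ scores that are
median-centred over the four bases per position. The pseudo-count is
$\varepsilon = 0.5$ per base (configurable), which keeps small mutation sets
finite without visibly biasing large ones. Background windows that would
leave the chromosome are excluded so observed and background contexts have
identical lengths; background positions are *not* filtered for
reference-base identity with the mutated base (a deliberate choice — the
logo then reports composition enrichment, not conditional preference).

## Signature fitting

`refit()` solves $\min_{e \ge 0}\lVert s - M e\rVert_2$ by Lawson–Hanson
NNLS; exposures are in mutation counts when the spectrum holds counts.
`refit_strict()` then iteratively removes the signature whose removal
decreases the reconstruction cosine the least, while that decrease is below
`max_delta` (default **0.004**), ties broken by column order and the last
signature never removed; with `max_delta = 0` it reduces exactly to
`refit()`. This greedy-removal contract makes sparse refitting deterministic
and auditable (the removed list is reported).

`nmf_extract()` is multiplicative-update NMF under Frobenius loss, best of
`n_starts` seeded restarts (default 200; the examples in this package use
10–20, which is ample at ranks 1–4 on 96-channel matrices), with a $10^{-6}$
relative-change stopping rule and bit-reproducible output for a fixed seed.
NMF runs on counts, so exposures have count units. Rank selection is the
user's: `nmf_scree()` reports reconstruction error over candidate ranks but
nothing is chosen automatically.

Oxygen difference spectra are computed on per-population-doubling normalised
counts — the natural scale here, since rates are reported per doubling —
then floored at zero and renormalised; the number of floored channels is
reported so the flooring is auditable. The two-component decomposition
refits stratified spectra (e.g. replication-timing deciles) against exactly
two normalised components, the low-oxygen spectrum and the high–low
difference, warning when the components are effectively collinear. The
difference fit has no free intercept: the model is that high-oxygen
mutagenesis is the low-oxygen process plus one additional component.

## Genome context conventions

* Coordinates are 1-based inclusive internally; BED/bedGraph inputs are
  converted at the boundary, and track points sit at interval midpoints.
* Replication timing keeps the source-track orientation (higher score =
  earlier); decile 1 is the earliest-replicating. Decile cuts are the
  empirical 0.1…0.9 quantiles *of the track points* (not of genomic
  territory), bins left-closed. When several timing data sets are supplied
  they are averaged after an inner join on identical intervals — the grids
  are assumed to be the same, and non-shared intervals are dropped loudly.
* $\mathrm{RFD} = (R - L)/(R + L)$ per window; the normalised form is used
  (rather than a raw difference) so the −0.5/0.5 stratification bounds are
  comparable across coverage. Windows without reads are gaps, not zeros.
* With the mutation on the pyrimidine strand: a pyrimidine on the plus
  strand under a rightward fork (RFD > 0) is on the **lagging** strand;
  flipping either the strand or the fork direction flips the call; RFD of
  exactly 0 is unassigned. Track lookups beyond the data return the nearest
  endpoint (clamped), interpolation only happens between points.
* Transcription labels follow the template-strand definition; positions
  under genes on both strands are ambiguous and excluded from bias tests,
  positions outside genes are intergenic. Strand-bias tests are
  one-degree-of-freedom chi-square against a 50:50 split. RFD stratification
  uses the open middle interval (−0.5, 0.5); boundary values fall outward.

The RFD-stratified transcription-bias analysis exists to expose a
confounder: replication and transcription are preferentially co-directional,
so a purely replicative strand bias masquerades as transcriptional bias. In
regions of weak fork preference the replicative signal dilutes away and only
a genuine transcription-coupled process would remain — the package's
synthetic drill plants exactly this confounding and confirms the middle
stratum goes quiet.

## Clonality and rates

`split_clonal_subclonal()` runs one-dimensional two-centre k-means (Lloyd)
on raw VAFs from a deterministic initialisation at the 25th/75th
percentiles; the border is the midpoint of the final centres, the upper
cluster is clonal, and samples with fewer than 300 mutations in either
compartment are flagged excluded. On the bimodal mixtures this package
generates, the Lloyd solution coincides with the global optimum found by
exhaustive split-point search (which the tests verify); raw VAFs rather than
histogram bins are clustered. Note the resolution limit: with binomially
read-sampled VAFs at depth 60, planted-fraction recovery within ±3% holds at
centre separations around 0.25, not at the 0.15 margin.

`rate_per_doubling()` divides mutation totals by population doublings
(`days * 24 / doubling_hours`); the per-megabase variant requires an
explicit genome size. Group comparisons use pooled-variance two-sided
t-tests by default (Welch behind a flag, recorded in the output), paired
t-tests for clonal-versus-subclonal signature contributions.

## What the synthetic data emulates — and what it does not

The generators encode the study design they emulate: 60 days of culture at a
20 h mean doubling time (72 doublings; the doubling time is our choice of a
realistic value for these colorectal lines), five clones per oxygen
condition, a baseline MMRd component at 76.8 SBS per doubling in both
conditions and an oxygen component at 87.0 SBS per doubling in the
high-oxygen condition only (totals 76.8 and 163.8), the oxygen component
being T>C-dominated and concentrated at the ATA/GTA/GTT/TTA triplets. The
shipped signature fixture (`synthetic_signatures()`; files labelled
`synthetic_`) was constructed once with those masses (T>C mass 0.44 in
`sim_hd`, 0.70 in `sim_ox`, pairwise cosine ≈ 0.5) so that the planted
high/low T>C fold is 2.80. Clone totals are Poisson around rate × doublings;
catalogs are multinomial draws from the exposure-weighted signature mixture
realised at genome positions with matching triplet context; isogenic count
tables use Poisson depth (mean 30), binomial heterozygous alt counts and a
0.001 per-base error rate; fork fields are smooth alternating waves
(`tanh(k sin)`) with binomial OK-seq read counts; timing tracks are cosine
waves with known analytic quantiles; VAF mixtures are binomial read-sampled
around two centres.

Deliberately not modelled: clone-level biological overdispersion (the
between-clone spread of real rates exceeds Poisson), mapping bias and
alignment artefacts, sequencing-error context dependence, copy-number
variation and aneuploidy, purity/cellularity in the VAF model, and any
correlation structure between replication timing, GC content and mutation
rate beyond what is planted. Passing tests therefore demonstrate that the
*methods* recover planted truth under the stated statistical model, not that
real WGS data are free of the artefacts the model omits.

For de novo extraction, note an identifiability caveat that the drills make
explicit: NMF can only recover a signature that some samples approach in
isolation. A cohort in which every high-oxygen clone has the same fixed
mixture pins down the mixture cone, not the components, so the NMF drill
uses clones with variable exposure to both components (baseline 20–110,
oxygen 60–120 per doubling); the difference-spectrum route, by contrast,
works on the fixed-rate study design directly.

## Problem sizes and numerics

The shipped tests and the acceptance script run on toy genomes of 20–200 kb,
cohorts of 10 clones at roughly 5,500–11,800 mutations per high/low clone,
NMF catalogs of 20 × 2,000 mutations, 10⁴-replicate null simulations for the
type-I checks, and the complete Fisher-score grid at coverage ≤ 20 — sizes
chosen so every stage's statistical target (recall/precision, recovery
cosines, exact-enumeration agreement) is comfortably identifiable. Numeric
edge cases are defined rather than accidental: zero coverage scores 0 with a
degenerate flag, zero spectra refuse to normalise or enter cosines, an
all-zero difference spectrum is an error, empty RFD windows are gaps,
degenerate (all-equal) score or VAF sets are errors, and every generator is
a pure function of its seed.

## A worked example

```{r example, eval = FALSE}
library(isomutsig)

g <- gen_genome(30000, seed = 3)
sim <- gen_isogenic_counts(g, n_descendants = 3, n_sbs = 50, seed = 7)
res <- call_mutations(sim$counts, ancestry = sim$ancestry)
nrow(res$records)            # ~150 unique calls, one per planted mutation

sigs <- synthetic_signatures()
catalog <- gen_catalog(sigs, c(sim_bg = 0, sim_hd = 1, sim_ox = 0),
                       5000, g, seed = 2)
sp <- build_spectrum(catalog, g, "SBS96")
refit_strict(sp, sigs)       # sim_hd carries the exposure; decoys removed
```

## Known limitations

* The caller sees only count tables: indel calls carry placeholder alleles,
  and sequence-resolved indel classification needs catalog/VCF input.
* Strict refitting is greedy; it inherits the usual greedy caveat that a
  jointly-redundant signature pair can shadow each other (ties and
  removal order are deterministic and reported, which bounds the damage).
* Lloyd k-means is not guaranteed globally optimal on pathological VAF
  distributions; the exhaustive 1-D oracle in the tests guards the regimes
  this package generates.
* Cancer-cohort applications (reference-set substitution, MMRd sample
  selection, clonal/subclonal exposure comparison) are implemented and
  unit-tested on synthetic fits, but no real cohort is bundled.
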