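---
title: "Methods: repertoire cleanup, CDR3 descriptors, usage statistics and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire cleanup, CDR3 descriptors, usage statistics and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific and numerical decisions behind
`bcrdev`: what each stage assumes, which parameters matter, what the
simulator does and does not emulate, and where the design was genuinely
open.

## Data model and cleanup

The unit of input is an annotated rearrangement: one sequencing read with
donor, cell subset (pre-B, immature, transitional, naive), chain (IGH,
IGK, IGL), V/(D)/J gene calls, and the junction. Germline alignment is
treated as an upstream black box — the package consumes its output (or
the simulator's ground truth) and never re-aligns. Gene families are
parsed from standard nomenclature (the digits between the segment letter
and the first separator: `IGHV3-23` is family 3), with allele suffixes
(`*01`) stripped deterministically.

By the IMGT convention the junction includes the conserved anchors (Cys
104 and Trp/Phe 118). Internally CDR3 excludes them; `junction_includes_anchors = TRUE`
(the default) trims the first and last codon on load. All length filters
and descriptors therefore apply to the CDR3 proper. Whether descriptors
should include the anchors is not settled usage; excluding them was
chosen because anchors are invariant and would only shift every mean-type
descriptor by a constant.

Cleanup is two-stage, because gene-usage analyses tolerate junction
errors that property analyses do not:

* `gene_stage`: structural validity only (parseable gene calls, non-empty
  CDR3). Used for usage tables.
* `cdr3_stage`: additionally requires CDR3 amino-acid length within 1–35
  (heavy) or 1–20 (light), both bounds inclusive, and productivity. Used
  for the physicochemical analyses.

Every removed record carries exactly one reason code and the
kept/removed pair partitions the input — counts are auditable.

## PCR-duplicate collapse

The target populations are antigen-naive, so true clonal expansion is
negligible and reads sharing a CDR3 are taken to be PCR duplicates of a
single gene rearrangement. Collapse proceeds within each
donor × subset × chain × V gene × J gene group by single-linkage
clustering under Levenshtein distance on the CDR3 nucleotide sequence;
each cluster is reduced to its modal sequence (most frequent read;
ties broken by the lexicographically smallest, so the result is
deterministic) with the cluster size recorded.

Open choices, and how they were fixed:

* **Threshold.** `threshold = 1` by default: it absorbs single
  sequencing errors (substitutions and, because edit distance bounds
  length difference, single-base indels), while `threshold = 0`
  reproduces exact same-CDR3 collapse. Both are exercised in the tests.
  Exact recovery of a noisy fixture is only guaranteed in the
  single-error-per-read regime; reads carrying two or more errors with
  no intermediate read split off, which is why the large-scale recovery
  check is stated as a ±2% band rather than equality.
* **Grouping key.** Clustering is keyed on the gene calls because the
  collapsed unit is a *gene rearrangement*; this also bounds the
  quadratic distance computation. Length binning is implicit: clusters
  cannot span CDR3 lengths differing by more than the threshold.
* **Single linkage** (transitive closure of the ≤-threshold relation) is
  used because relatedness, not centroid geometry, defines a duplicate
  cluster; it also makes the threshold-0 case provably identical to
  exact grouping.
* **Modal = most frequent member**, not per-position consensus: the
  representative is then always an observed sequence.

## CDR3 physicochemical descriptors

All descriptors are computed from scratch from residue-level scale
tables shipped as versioned CSV files (`inst/extdata/scales`, version
`scales-1.0`): Kyte–Doolittle hydropathy (GRAVY), the Boman
protein-binding scale (kcal/mol), average residue masses (Da, plus one
water per peptide), the ten Kidera factors (each column normalized to
mean 0, SD 1 over the 20 residues — asserted numerically in the tests),
a nine-class composition table (tiny, small, aliphatic, aromatic,
nonpolar, polar, charged, basic, acidic), and the EMBOSS pKa set.

Numerical choices:

* **Isoelectric point** is the zero crossing of the
  Henderson–Hasselbalch net charge over termini and ionizable side
  chains (C, D, E, H, K, R, Y), found by bisection on [0, 14] to
  |charge| < 1e-4. The charge is strictly decreasing in pH, so the root
  is unique; tests verify agreement with a 1e-4-step grid scan to within
  0.001 pH. The EMBOSS pKa values are the default because they are the
  de facto standard of the sequence-analysis tool ecosystem; the table
  is a data file and can be swapped.
* **Average (not monoisotopic) masses**, matching conventional Mr
  reporting.
* **Ambiguous residues** (X, B, Z) exclude a sequence from the property
  stage with a logged count — the cleanup stage is expected to have
  removed low-quality CDR3s already, so this is a guard, not a filter.
* Mean-type descriptors are linear in residue composition, so a
  homopolymer's value equals its table entry — this identity over all 20
  residues is the oracle for the whole battery.

## Usage tables and univariate statistics

Frequencies are percentages over *unique clonotypes* (never raw reads)
per donor × subset, at gene, family, or family-combination (VDJ / VJ)
granularity; absent keys are kept at 0 and denominators recorded, so
every donor × subset profile sums to 100. Donor × subset cells with no
clonotypes are dropped, not imputed.

`compare_usage()` treats per-donor frequencies as replicates (donor means
are the error unit, matching SEM-over-donors reporting). The default
route fits a two-way ANOVA (subset × key) and performs per-key subset
contrasts with the pooled residual error, adjusted across keys by
Holm–Šidák step-down — the convention of common graphing software;
Benjamini–Hochberg is available. The nonparametric route uses a paired
Wilcoxon signed-rank test when both subsets cover the same donors (the
bone-marrow pair and the blood pair are donor-matched) and Mann–Whitney
otherwise. Groups with fewer than two donors are flagged
`insufficient_replication` rather than tested.

CDR3 properties are compared with a Gaussian random-intercept model,
`property ~ subset + (1 | donor)` versus `property ~ 1 + (1 | donor)`,
fitted by **maximum likelihood** (not REML — the likelihood-ratio test on
a fixed effect requires ML), with the LRT statistic referred to a
chi-square on (subsets − 1) degrees of freedom. Convergence messages are
captured and surfaced in the result rather than silenced; a zero-variance
response short-circuits to a zero statistic. Tests verify the ML optimum
against an independent profile-likelihood grid search and check
calibration by simulation: type-I error within [0.02, 0.09] at α = 0.05
over 200 null data sets, and power above 0.9 for a one-residual-SD
subset effect with 8 donors × 200 clonotypes.

## Donor-mean PCA, permutation control, Minkowski clustering

Multivariate analyses operate on one row per donor × subset: the mean of
each feature (family frequencies, or Kidera factors, or the full
property set) over that donor's clonotypes. PCA is SVD-based (`prcomp`),
centred and unscaled by default (the standard `prcomp` behaviour;
both flags are exposed). Component signs are fixed by making the
largest-magnitude loading positive, so results are deterministic.

The separation of subsets in a score plot is quantified by an explicit
statistic — between-subset centroid dispersion divided by total
dispersion in the PC1–2 plane. This is an artifact construct (a score
plot itself has no p-value): it is invariant to feature reordering and
to orthogonal rotations of the score space, which is what makes the
permutation test well-posed. The control shuffles subset labels across
sequences *within each donor* (preserving subset sizes and donor
effects under the null; a global shuffle is available), re-runs
donor-means → PCA → statistic, and reports
`p = (1 + #{perm ≥ observed}) / (n_perm + 1)` — valid, never zero, and
exactly reproducible under a seed.

Hierarchical clustering uses Minkowski distances with power 4 (powers
below 1 are rejected — not a metric), which emphasizes the largest
coordinate differences relative to Euclidean distance, followed by
complete-linkage agglomeration (configurable) and Newick serialization
with merge heights as branch lengths.

## The simulator: study conditions and scope

`default_profiles()` defines the study conditions. The between-subset
*differences* are the recoverable signal; the absolute
baseline family frequencies are artifact constructs (real studies
report the shifts and show the absolute values only graphically), chosen
once to be realistic for human repertoires (IGHV3 the dominant V family
at 55% in bone marrow; IGHJ4 the dominant J at 40%). Planted shifts:

* IGHV3: 55% (pre-B = immature) → 48% (transitional) → 41% (naive), a
  14-point bone-marrow-to-naive decrease;
* IGHJ6: +9.5 points in transitional cells (compensated within IGHJ3/4/5)
  and reduced to 15% in naive cells;
* IGHD2: 16% → 9% in transitional and naive cells;
* IGHD3: +5.5 points in transitional cells only. The reported effect is
  5 points; the plant adds the simulation's own 0.5-point sampling
  tolerance at the default scale so that the signal, not the sampling
  noise, decides whether the reported magnitude is recovered — the same
  margin-above-the-bound pattern used for the other families;
* kappa families flat across subsets;
* IGLV2: 25% → 37% after the immature stage (within the reported
  10–15 range); IGLJ1: 8% → 11.5% at the expense of IGLJ3.

When a family is shifted, the complement is redistributed proportionally
over the remaining families ("small changes in all others to
compensate"); within families, gene weights are uniform — the reported
gene-level idiosyncrasies (e.g. which IGHV3 members move) are not
modelled. Light-chain profiles cover immature, transitional and naive
cells only: pre-B cells have not yet rearranged a light chain.

Junctions are assembled as trimmed V-head + N + trimmed D-core + N +
trimmed J-tail (no D for light chains), with geometric trims
(mean 2 nt) and the N region sized to hit a per-subset CDR3 length drawn
from a normal distribution (heavy means 16.0/15.7/15.4/15.0 aa for
pre-B/immature/transitional/naive, SD 3; light mean 9.7, SD 1.5). Length
selection weakening with age is modelled by `age_length_coupling`
(default 0.25 aa per decade past 50, applied in proportion to a subset's
decline from the pre-B mean, capped at the pre-B value) — a deliberately
simple phenomenological knob. Two-thirds of clonotypes are forced
in-frame and stop-free (in-frame stops are repaired deterministically);
the rest are frameshifted. Each clonotype is observed
`1 + Poisson(pcr_copies_mean − 1)` times with per-base substitution
(default 0.2%) and indel (default 0.05%) errors.

The error model is applied within the junction window, and productivity
and junction translation are re-derived per read from the observed
sequence, as an annotation pipeline would. Errors outside the junction
are not simulated because no downstream statistic in scope depends on
them (gene calls are consumed as ground truth). Likewise omitted:
454-style homopolymer indel bias (a uniform indel rate is used),
receptor editing as a mechanism (subset differences are injected
phenomenologically), and the absolute sequence counts of any particular
study, which depend on sequencing depth. Passing tests therefore show
that the pipeline recovers *planted family-level usage and length
structure under PCR duplication and low-rate sequencing error* — they do
not certify behaviour on real data with gene-call errors, biased
amplification, or clonally expanded populations.

The synthetic germline bundle (checked in under `extdata/germline`,
regenerable bit-identically from its seed) mirrors the locus structure —
26 IGHV, 17 IGHD, 6 IGHJ genes and kappa/lambda sets, each V ending in
an in-frame conserved Cys codon and each J carrying the conserved
Trp/Phe anchor — but its sequences are synthetic stand-ins, not human
germline alleles.

## Problem sizes

The test suite exercises the full recovery path at 5 donors × 4 subsets
× 5,000 clonotypes per subset per donor (heavy chain; 3 subsets for
lambda), the statistics calibration at 200 null simulations per test,
and the dendrogram topology checks at 20 seeded replicates of 5 donors ×
800 clonotypes; unit fixtures are a few hundred reads. These sizes were
chosen so each planted effect's sampling error (≈0.3–0.5 percentage
points at the recovery scale) is several times smaller than the smallest
planted delta.

## Known limitations

* Under the default effect sizes, the naive subset — carrying the single
  largest family shift (IGHV3, −14 points) — is the most distant subset
  in Minkowski power-4 space, so default dendrograms place naive, not
  transitional, as the root-split outgroup. Real early-B-cell data have
  shown transitional cells as the outlier group, driven by gene-level
  transitional idiosyncrasies that the family-level simulator
  deliberately does not plant. Reproducing that topology requires
  supplying profiles with additional transitional-specific structure.
* The two-way ANOVA post-hoc route ignores the compositional constraint
  (frequencies per donor sum to 100), as the field's standard practice
  does; the permutation control is the principled guard against its
  miscalibration.
* The simulator's productivity model (a forced in-frame fraction) is a
  selection *outcome*, not a mechanism; out-of-frame fractions carry no
  biological signal here.
* `compare_usage()` aims to reproduce decisions at α = 0.05, not the
  p-value arithmetic of any particular graphing package.
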