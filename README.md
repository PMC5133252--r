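# bcrdev

Immunoglobulin repertoire analysis across the earliest stages of human
B-cell development.

## The problem

As B cells mature from **pre-B** and **immature** cells in the bone marrow
to **transitional** and **naive** cells in peripheral blood, central and
peripheral tolerance checkpoints remove cells from the repertoire. Because
these populations are antigen-naive (no somatic hypermutation, no clonal
expansion), any change in V(D)J gene usage or in the physicochemical
character of the heavy-chain CDR3 between subsets is a read-out of
selection. `bcrdev` provides the complete computational pipeline for this
kind of study, for anyone working with AIRR-style annotated rearrangement
tables (heavy chain IGH, light chains IGK/IGL):

1. **Cleanup** — remove rearrangements whose CDR3 is likely inaccurate:
   amino-acid length outside 1–35 (heavy) or 1–20 (light), or
   unproductive (for the CDR3-character analyses).
2. **PCR-duplicate collapse** — in antigen-naive populations, reads with
   the same CDR3 are PCR duplicates of one gene rearrangement. Reads are
   clustered within donor × subset × chain × V × J by single-linkage
   Levenshtein distance on the CDR3 nucleotide sequence
   (`d ≤ 1` by default; `0` = exact collapse), and each cluster is
   represented by its modal sequence.
3. **CDR3 descriptors** — length, GRAVY (Kyte–Doolittle mean hydropathy),
   Boman index, molecular weight, isoelectric point (bisection on the
   Henderson–Hasselbalch net charge with EMBOSS pKa values), Ikai's
   aliphatic index `X_A + 2.9 X_V + 3.9 (X_I + X_L)`, nine amino-acid
   class counts, and the ten Kidera factors (orthogonal per-residue
   scales; a sequence scores the per-residue mean).
4. **Usage statistics** — per-donor percent frequencies of genes,
   families and V(D)J family combinations over *unique clonotypes*;
   two-way ANOVA with per-key post-hoc subset contrasts (Holm–Šidák
   adjusted), paired Wilcoxon / Mann–Whitney alternatives; and for CDR3
   properties a Gaussian mixed model `property ~ subset + (1 | donor)`
   fitted by ML with a likelihood-ratio test against
   `property ~ 1 + (1 | donor)`.
5. **Multivariate structure** — per-donor-mean PCA (prcomp) with a
   label-permutation control for subset separation, and agglomerative
   clustering on Minkowski power-4 distances with Newick dendrogram
   export.
6. **Simulation** — a seeded V(D)J recombination simulator (family-level
   usage profiles per subset, junctional trimming and N-insertion,
   CDR3-length selection, 2/3 productivity, PCR duplication, per-base
   sequencing error) that supplies ground truth for every stage. Its
   default profiles plant the subset effect sizes reported for early
   human B-cell development (e.g. IGHV3 falling 14 points from bone
   marrow to naive, IGHJ6 raised 9.5 points in transitional cells).

## Worked example

Simulate four donors, analyse heavy-chain family usage, and test the
planted bone-marrow-to-naive IGHV3 decrease:

```r
library(bcrdev)
library(dplyr)

sim <- simulate_repertoire(
  simulation_config(n_donors = 4, clonotypes_per_subset = 1500, seed = 42),
  chains = "IGH")

reads <- normalize_rearrangements(sim$reads)
clono <- apply_filters(reads, filter_policy(), "gene_stage")$kept |>
  cluster_duplicates(threshold = 1)

usage <- usage_frequencies(clono, "family", chain = "IGH", segment = "V")
compare_usage(usage) |>
  filter(key == "IGHV3", group2 == "naive")
#>   key   group1       group2 effect adjusted_p
#> 1 IGHV3 preB         naive  -13.7    0
#> 2 IGHV3 immature     naive  -12.6    0
#> 3 IGHV3 transitional naive   -6.50   4.51e-14
```

The `effect` column is the difference of mean per-donor percent
frequencies (group2 − group1): naive cells use IGHV3 family genes 13.7
percentage points less than pre-B cells, and the planted shift is
recovered as highly significant. The donor-mean PCA separates the
subsets, and a within-donor label permutation shows the separation is not
chance:

```r
pca <- run_pca(donor_means(usage))
pca
#> PCA of donor-mean matrix: 16 rows, 7 features
#> explained variance ratio: 0.939 0.027 0.020 0.008 ...
#> subset separation statistic (PC1-2): 0.913

props <- apply_filters(reads, filter_policy(), "cdr3_stage")$kept |>
  cluster_duplicates(threshold = 1) |>
  property_table()

randomization_control(props[, c("donor_id", "subset", paste0("kf", 1:10))],
                      n_perm = 199, seed = 42)
#> permutation control: observed separation 0.757, p = 0.0050 (199 permutations)

mixed_model_lrt(props, "length")
#>   property statistic df raw_p    method    effect converged
#> 1 length       92.7   3 5.82e-20 lrt_chisq  0.626 TRUE
```

The mixed-model likelihood-ratio test (chi-square, 3 df) confirms the
planted shrinkage of mean CDR3 length from pre-B to naive cells (0.63
amino acids across subsets in this run) while accounting for the donor
random effect. `autoplot(pca)`, `plot_usage()`, `plot_usage_bubbles()`
and `plot()` on a `minkowski_cluster()` result produce the standard
figures; `tidy()`/`glance()` methods return tidy summaries. The whole
chain can also be driven from one configuration with `run_pipeline()`,
which writes every stage table plus a checksummed run manifest.

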