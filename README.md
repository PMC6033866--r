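# epidiv

Single-molecule ("epiallele") DNA methylation analysis for targeted deep
bisulfite amplicon sequencing.

Deep amplicon bisulfite sequencing reads the methylation state of every CpG
site of a short genomic region on every sequenced molecule — one molecule,
one cell, one *epiallele*: the specific combination of methylated CpGs on
that allele. Averages can hide what epialleles reveal: two tissues with the
same mean methylation may distribute it across cells entirely differently.
`epidiv` is for researchers analysing such data (e.g. promoter methylation
across brain regions or diagnosis groups): it turns merged amplicon reads
into filtered per-molecule methylation profiles, builds rarefiable
sample-by-epiallele count tables, and quantifies epiallele composition with
the diversity and inference toolkit of community ecology.

## What it computes

Per molecule, each CpG is called 0 (unmethylated, read base T), 1
(methylated, C) or 2 (ambiguous: any other base or an alignment gap), after
a bisulfite-insensitive affine-gap alignment to the C→T-converted
reference. Reads are filtered on mean PHRED, expected length, bisulfite
efficiency (CpH conversion), ambiguous-call fraction and aligned fraction.
From the retained molecules:

- **Epiallele count table** (samples × binary patterns; a 10-CpG region has
  2^10 = 1024 possible species), rarefied without replacement to a common
  depth, serialised as BIOM JSON;
- **Class distributions**: frequency of molecules with k = 0..N methylated
  CpGs, position ignored;
- **Methylation summaries**: per-site percent (TSS-relative labels, no
  position 0), pooled regional average, and non-CpG (mCpH) methylation with
  spike-in correction — the residual-C fraction *f* of a fully unmethylated
  control is subtracted from the observed CpH fraction *p* (convention), and
  the unbiased calibration (p − f)/(1 − f) is reported alongside;
- **Alpha diversity** (observed epialleles, Shannon index in bits), **beta
  diversity** (Bray-Curtis), **PCoA**, **ANOSIM** (999 permutations), the
  **Cramér two-sample test** on class profiles
  (T = mn/(m+n)·[2/(mn)·ΣΣφ(‖x−y‖) − 1/m²·ΣΣφ(‖x−x‖) − 1/n²·ΣΣφ(‖y−y‖)],
  φ(z) = z/2, permutation p), and per-site t tests with Bonferroni plus
  ANOVA/Tukey for alpha metrics.

A fully seeded synthetic-data module generates study-shaped cohorts (three
brain areas × two groups, area-specific epiallele mixtures, conversion
failure, sequencing error, unmethylated spike-in) with exact per-read
truth, so every stage is verifiable against ground truth.

## Worked example

```r
library(epidiv)

ref <- make_synthetic_reference(325, 10, n_cph_min = 40, seed = 7,
                                locus_name = "locusA")
ref
#> amplicon_reference 'locusA': 325 bp, 10 CpG, 84 CpH
#>   CpG sites (TSS-relative): -157, -121, -108, -95, -58, -37, +65, +87, +130, +134

spike <- make_synthetic_reference(150, 0, n_cph_min = 40, seed = 8,
                                  locus_name = "spike")
spike$is_unmethylated_control <- TRUE

dir <- tempfile()
manifest <- simulate_cohort(dir, ref, spike, example_area_mixtures(),
                            n_per_group = 2L, reads_per_sample = 1000L,
                            spike_reads_per_sample = 300L, seed = 42)
cfg <- run_config(manifest, references = list(locusA = ref),
                  spike_reference = spike, output_dir = file.path(dir, "out"))
res <- run_pipeline(cfg)

res$locusA$rarefied
#> epiallele_count_table 'locusA': 12 samples x 80 patterns (N = 10 CpG), rarefied to 430 (seed 1)
head(res$locusA$alpha, 4)
#>      sample_id observed_epialleles  shannon
#> 1 HIPP_CTRL_01                  26 3.503979
#> 2 HIPP_CTRL_02                  27 3.595926
#> 3  HIPP_SCZ_01                  26 3.550275
#> 4  HIPP_SCZ_02                  25 3.506067
res$locusA$anosim$statistic; res$locusA$anosim$p_value
#> [1] 0.9267907
#> [1] 0.002
res$locusA$cramer$HIPP_vs_CB$p_value
#> [1] 0.033
```

Reading the output: the 12 simulated samples were rarefied to a common 430
molecules (the minimum retained depth; the QC filters reject reads whose
CpH conversion falls below 98%). Cortical samples carry ~26 distinct
epialleles at Shannon ≈ 3.5 bits, while the cerebellum-like mixture is much
less diverse; ANOSIM on Bray-Curtis dissimilarities separates the areas
almost perfectly (R = 0.93, p = 0.002), and the Cramér test detects the
class-profile difference between HIPP and CB (p = 0.033). All stage outputs
(count tables as TSV and BIOM JSON, class distributions, alpha/beta
diversity, PCoA coordinates, methylation and mCpH summaries, test JSONs,
and a run report with thresholds, seeds and input hashes) are written under
`output_dir`.

Lower-level entry points (`classify_cytosines()`, `bisulfite_convert()`,
`align_bisulfite()`, `call_profiles()`, `filter_profiles()`,
`estimate_conversion_efficiency()`, `build_count_table()`, `rarefy()`,
`class_distribution()`, `mch_summary()`, `alpha_diversity()`,
`bray_curtis()`, `pcoa()`, `anosim()`, `cramer_test()`,
`group_comparisons()`) expose each stage separately; see the vignette
`vignettes/epiallele-methods.Rmd` for the models and the reasoning behind
defaults.

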