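# trnaselect

Tumours consistently over-express many tRNAs, but each tRNA is encoded by a
redundant family of genes scattered across the genome. Which family members
carry that expression — and whether every tumour picks the same ones — can
be read out from H3K27ac ChIP-seq signal at the ~430 high-confidence human
tRNA loci. `trnaselect` implements that analysis as a tested R pipeline for
epigenomics researchers:

* **annotation** — parse gtRNAdb-style names
  (`tRNA-<Isotype>-<Anticodon>-<Fam>-<Copy>`) into the four-level
  gene < isodecoder < isoacceptor < isotype hierarchy; read BED / UCSC
  tables; filter to a configurable high-confidence set.
* **quantification** — count ChIP fragments in ±500 bp windows around gene
  centres, normalize to reads per million, and divide by matched input:
  `Q_gs = (chip RPM)_gs / ((input RPM)_gs + ε)`, with low-input cells
  flagged missing rather than reported.
* **family aggregation** — sum member Q-values at any hierarchy level,
  with explicit missing-data policies.
* **heterogeneity** — pairwise Spearman ρ between samples at each level
  (family buffering appears as ρ_gene < ρ_isoacceptor < ρ_isotype),
  per-sample totals and fold ranges, median-based activity calls, and
  Student t-tests between conditions with BH correction.
* **survival** — Kaplan-Meier quartile comparisons and per-unit Cox
  proportional-hazards screens (`HR = exp(β)` per SD of expression) with
  5-year administrative censoring.
* **synthetic data** — a seeded generator producing fragment-level ChIP
  cohorts in which family activity budgets are conserved across samples
  (log-normal budgets, between-sample sd σ) while member selection is
  heterogeneous (Dirichlet concentration α < 1), plus survival cohorts
  with a known log-hazard coefficient — ground truth for every recovery
  test in the suite.

## Worked example

```r
library(trnaselect)

# The initiator-methionine family: nine genes, eight identical in sequence
genes <- load_gene_table("imet.bed", format = "bed")
family_sizes(genes, "isoacceptor")
#> iMet-CAT
#>        9
family_sizes(genes, "isodecoder")
#> iMet-CAT-1 iMet-CAT-2
#>          8          1

# Simulate a 12-sample cohort, quantify, and measure family buffering
cfg <- synthetic_config(seed = 1)
co  <- simulate_chip_cohort(cfg)
m   <- build_signal_matrix(co, co$records,
                           chrom_lengths = attr(co$records, "chrom_lengths"))
ch  <- correlation_hierarchy(m)
round(tapply(ch$rho, ch$level, mean), 3)
#>        gene isoacceptor     isotype
#>       0.017       0.420       0.699

# Screen 20 expression units against simulated survival (effect on unit_11)
em  <- simulate_expression_matrix(cfg, n_units = 20)
sc  <- simulate_survival_cohort(cfg, em, "unit_11")
scr <- survival_screen(em, sc$surv, horizon_years = 5)
head(scr[, c("unit", "HR", "p", "q", "significant")], 3)
#>      unit   HR        p        q significant
#> 1 unit_11 2.01 1.66e-40 3.33e-39        TRUE
#> 2 unit_02 1.05 3.60e-01 9.60e-01       FALSE
#> 3 unit_17 1.05 3.94e-01 9.60e-01       FALSE
```

The correlation table is the core readout: individual gene signal is
nearly uncorrelated between samples (each sample activates its own family
members) while isoacceptor and isotype totals correlate strongly — the
family budget is buffered. The screen recovers the causal unit at the top
of the hazard-ratio ordering with its confidence interval excluding 1.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
on a default synthetic cohort and write their tables under `results/`
(fragment-level data go to `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + ground truth
Rscript analysis/02_quantify_signal.R    # Q-value matrix, totals, activity
Rscript analysis/03_family_buffering.R   # per-level correlations, shares, t-tests
Rscript analysis/04_survival_screen.R    # KM quartiles + Cox screen
```

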