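# ascbias

Simulation and imputation-based mitigation of SNP ascertainment bias.

Genotyping arrays carry only SNPs that were discovered — and common — in a
finite, non-random discovery panel. Statistics computed from such data are
systematically distorted: expected heterozygosity (H_E) is inflated, most
strongly for the discovery populations themselves, and allele-frequency
distances between differently biased population groups are stretched.
`ascbias` provides a self-contained, truth-known laboratory for this
phenomenon and for the correction strategy of imputing array genotypes to
sequence resolution against a small, fully observed reference panel. It is
aimed at population geneticists who want to quantify how much of an
estimate is array artefact, and at study designers choosing a reference
panel for imputation.

## What is inside

* **Synthetic multi-population data with known truth** — Balding–Nichols
  differentiation around shared ancestral frequencies
  (`Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `Var = F p(1-p)`), founder-mosaic
  haplotypes for LD, and a pooled-sequencing emulator with finite-pool and
  finite-depth noise.
* **In-silico array design** — discovery-population MAF filtering
  (`MAF > 0.05`, strict), masking that keeps sites addressable, and a
  sliding-window VIF LD-pruning arm (50 SNPs / step 5 / VIF 2).
* **Reference panels** — five sampling strategies (`allPop`, `randSamp`,
  `randPop`, `minPop`, `maxPop`) plus the reference-side `MAF > 0.01`
  filter.
* **Imputation** — a haploid Li–Stephens haplotype-copying HMM
  (switch probability `1 − exp(−0.04 · ne · d / K)`, default `ne = 1000`,
  windowed forward–backward, default 200 cM windows) producing posterior
  dosages, best-guess genotypes and per-site dosage r² (DR2).
* **Estimators** — H_E = mean of `2p(1−p)`; H_O; the Futschik–Schlötterer
  pool correction `n/(n−1)`; Nei's standard distance
  `D = −ln(J_xy / sqrt(J_x J_y))`; pairwise F_ST as the ratio of sums
  `Σ(HT_l − H̄S_l) / Σ HT_l`.
* **Evaluation** — discovery/reference/application group assignment,
  group-specific bias regression `y_ij = group_i + group_i·β_i x_ij + ε_ij`
  (a classed fit with `print`/`summary`/`coef`/`plot` methods), mean
  overestimation `mean((biased − true)/true)`, per-animal Pearson accuracy,
  leave-one-out validation.
* **Orchestration** — `run_scenario()` sweeps repetitions × discovery
  populations × panel strategies into tidy tables, fully reproducible from
  a master seed; VCF / PLINK-map / TSV / YAML I/O for running any stage
  standalone on files.

## Worked example

```r
library(ascbias)

model <- population_model(n_populations = 6, n_sites = 2000, seed = 7)
freqs <- simulate_population_frequencies(model)
haps  <- simulate_haplotypes(freqs, n_individuals_per_pop = 15, model = model)
geno  <- as_genotypes(haps)

# in-silico array discovered in P03, then a balanced 1-per-population panel
mask  <- design_array(geno, discovery_pop = "P03", threshold = 0.05)
panel <- filter_reference_sites(geno,
           sample_reference(geno, "allPop", size = 1, seed = 99), 0.01)

study_ids <- setdiff(haps$individuals, panel$individuals)
study <- subset_individuals(apply_mask(haps, mask), study_ids)
imp   <- impute_genotypes(study, subset_individuals(haps, panel$individuals),
                          panel)
imp
#> <imputation_result> 2000 sites x 84 individuals; 381 imputed sites,
#>   144 unimputable; median DR2 1.000

aggregate(r ~ pop, per_animal_accuracy(geno, imp), median)
#>   pop         r
#> 1 P01 0.7069294
#> 2 P02 0.6934956
#> 3 P03 0.8768300   <- discovery population imputes best
#> 4 P04 0.6764300
#> 5 P05 0.7208432
#> 6 P06 0.6981879

true_he <- sapply(model$populations, function(p)
  expected_heterozygosity(allele_frequencies(geno, pop = p)))
asc_he  <- sapply(model$populations, function(p)
  expected_heterozygosity(allele_frequencies(geno, pop = p, sites = mask$sites)))
group_regression(true_he, asc_he,
                 assign_groups(model$populations, "P03", panel))
#> Group-specific bias regression (biased ~ true):
#>        group n intercept slope     r mean_overestimation
#>  application 5         0 1.096 0.999               0.095
#>    discovery 1        NA    NA    NA               0.346
```

Reading the numbers: the array inflates H_E for every population (mean
overestimation +9.5% for populations not used in discovery), but 3.6× more
for the discovery population (+34.6%); the application-group slope above 1
is the across-population signature of ascertainment bias. The discovery
population is also imputed most accurately (median r 0.88 vs ≈ 0.70) —
array SNPs explain more of its variability. Imputing the masked sites back
(as `run_scenario()` does at scale) removes most of the overestimation.

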