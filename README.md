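# rotbreed

Simulation and analysis toolkit for long-term divergent artificial-selection
colonies maintained under **rotational breeding** — the design used for the
high/low-capacity-runner (HCR/LCR) rat lines, in which 13 families per line
are kept for dozens of generations, the extreme male and female of each
family become breeders, and mate pairings rotate between families to defer
close inbreeding.

The package is aimed at quantitative and population geneticists who want to
reason about such colonies: how fast inbreeding accumulates under rotation
versus random mating, what a genome-wide SNP panel should look like after
*g* generations of drift and selection, and whether standard estimators
(REML heritability, Castle–Wright) recover the truth at colony scale.

## What it implements

* **Pedigree machinery** — a `pedigree` data-frame class with CSV I/O and a
  column-mapping dialect, structural validation, the tabular additive
  relationship matrix *A*, inbreeding coefficients *F* (founders treated as
  unrelated: `F = A(i,i) − 1`), and Henderson's sparse `A⁻¹`.
* **Breeding schemes** — the rotational pairing rule
  `sire_family = ((dam_family − 1 + r) mod 13) + 1` with the same-family
  rotation skipped; the deterministic idealized 13-family pedigree; seeded
  random-mating pedigrees; within-family truncation selection; and
  two-line intercross (F0 → F1 → F2) designs with reciprocal balance and no
  sib mating.
* **Closed-form expectations** — the breeder-count recursions
  `F_{n+1} = F_n + (1 − F_n)(N_f + N_m)/(8 N_f N_m)` and
  `H_{n+1} = H_n (1 − (N_f + N_m)/(8 N_f N_m))`, plus rate and
  rotation-vs-random slowdown reporting.
* **Gene drop** — founder haplotypes as mosaics of 8 ancestral inbred
  strains on a 2.75-Gb map, Mendelian transmission with Haldane
  recombination and X-chromosome hemizygosity, PLINK-style text export.
* **Panel statistics** — marker QC (duplicates / missingness / exact HWE /
  LD prune / MAF), observed heterozygosity, runs of homozygosity (≥ 4
  markers, ≥ 1 SNP/500 kb), LD decay via two-locus EM `r²`, two-group
  AMOVA, IBS + classical MDS, method-of-moments IBD (Z0/Z1/Z2), and sex
  inference from X heterozygosity.
* **Quantitative genetics** — additive phenotype simulation, a full
  divergent-selection experiment driver, mid-parent regression, a sparse
  animal-model REML fitter (`animal_model()`, a formula interface with
  `print`/`summary`/`coef`/`logLik` methods), the Castle–Wright effective
  QTL number, the vertical-work equation, and cohort divergence summaries.
* **Published colony tables** — the per-generation breeder census and
  per-sex phenotype summaries of the HCR/LCR colony ship as TSVs
  (`colony_breeder_counts()`, `colony_cohort_summary()`), and
  `simulate_colony_records()` builds a synthetic full-pedigree stand-in
  that matches the census exactly.

## Worked example

How fast does rotation accumulate inbreeding, compared with random mating
at the same census?

```r
library(rotbreed)

ped <- build_idealized_rotational_pedigree(28)   # 13 families, perfect adherence
f   <- inbreeding_coefficients(ped)
ss  <- series_summary(ped, unname(f))
subset(ss, generation %in% c(4, 8, 9, 14, 20, 26, 28), c(generation, n, mean))
#>  generation  n   mean
#>           4 26 0.0156
#>           8 26 0.0943
#>           9 26 0.0593
#>          14 26 0.1634
#>          20 26 0.1973
#>          26 26 0.2587
#>          28 26 0.2281

rot  <- rate_per_generation(ss, span = c(1, 28), mode = "slope")
rand <- expectation_rate(expected_F_random_series(13, 0, 28), span = c(0, 27))
c(rotational = rot, random = rand,
  slowdown = rotational_vs_random_comparison(rot, rand))
#> rotational     random   slowdown
#>       0.92       1.51       39.1
```

Mean *F* jumps by ~6 percentage points at G8 — the first-cousin pairings
forced at the rotation's half cycle — and again at G14, G20 and G26, then
relaxes between spikes. Averaged out, rotation gains 0.92 %/generation
against 1.51 under random mating with the same 13 + 13 breeders: a ~39%
slowdown, which is the entire point of the design.

Heritability estimation at colony scale, on the synthetic stand-in colony
(published census + published stratum means, additive truth h² = 0.47 of
log running distance):

```r
col <- simulate_colony_records("HCR", seed = 1)   # 5,976 animals in G1-G28
fit <- animal_model(log(best_distance_m) ~ sex * factor(generation),
                    data = as.data.frame(col)[col$generation >= 1, ],
                    ped = col)
fit
#> Animal-model REML fit
#>   formula: log(best_distance_m) ~ sex * factor(generation)
#>   n = 5976 records, 6002 pedigree animals
#>   h2 = 0.514 +/- 0.036  (sigma_a2 = 0.02134, sigma_e2 = 0.02015)
```

The sparse mixed-model equations make this a ~2-second fit.

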