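---
title: "Rotational breeding, inbreeding theory, and simulated genomic evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational breeding, inbreeding theory, and simulated genomic evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotbreed)
```

`rotbreed` models the computational backbone of a long-term divergent
artificial-selection experiment: two rat lines (high- and low-capacity
runners, HCR/LCR) selected for treadmill endurance over 28 generations and
maintained by 13-family rotational breeding. This vignette is the package's
account of the models it implements, the conventions it adopts where the
design was genuinely open, and what its simulations can and cannot say
about real colonies.

## The rotational breeding scheme

Each line keeps 13 families. Every generation, the best (HCR) or worst
(LCR) male and female of each family become breeders, and the female of
family $i$ is paired at rotation $r$ with the male of family
$((i - 1 + r) \bmod 13) + 1$. Offsets that are multiples of 13 would mate
within a family and are skipped, so the offsets cycle through $1..12$. The
map is a fixed-point-free bijection for every rotation — no brother–sister
pair is ever formed — but the scheme cannot defer relatedness forever: at
the half cycle every pairing is between first cousins, which injects a
$1/16$ inbreeding pulse. On the idealized pedigree
(`build_idealized_rotational_pedigree()`, deterministic, one male and one
female per family per generation, offspring assigned to the dam's family)
this produces the characteristic spikes of mean $F$ at G8, G14, G20 and
G26.

Two conventions here were inferred rather than stated by any source:
offspring inherit the *dam's* family index (the convention that reproduces
the worked pairing examples, e.g. a family-1 male descending from a
family-1 dam × family-7 sire mating), and rotation $r$ is used by the
generation-$r$ breeders (so the first-cousin rotation 7 produces the G8
spike). Both are locked by tests.

## Inbreeding and relationship machinery

`additive_relationship()` implements the tabular method; founders are
treated as unrelated and non-inbred, so every $F$ is an *increase* relative
to the founder generation — the pre-colony history of the heterogeneous
stock is deliberately not modelled. `inbreeding_coefficients()` runs the
tabular pass only over the ancestor-closed set of animals that ever appear
as parents (for colony pedigrees a few hundred of several thousand
records) and derives terminal animals' $F$ as half the parental
relationship. `ainverse()` builds the sparse $A^{-1}$ directly by
Henderson's rules with the inbreeding adjustment; its log-determinant comes
free from the $A = TDT'$ factorization. Correctness is pinned by three
independent routes in the tests: a memoized recursive-kinship oracle, a
Monte-Carlo allele-drop kinship oracle, and the identity
$A^{-1} A = I$.

## Expected trajectories from breeder counts

With $N_m$ male and $N_f$ female breeders the classical recursions are

$$F_{n+1} = F_n + (1 - F_n)\,c_n, \qquad
  H_{n+1} = H_n (1 - c_n), \qquad
  c_n = \frac{N_f + N_m}{8 N_f N_m}.$$

Both are iterated exactly (`expected_F_random_series()`,
`expected_H_random_series()`); $1 - F_n = H_n / H_0$ holds to machine
precision when both start from $F_0 = 0$. With the constant 13/13
configuration the mean increase over 27 steps is 1.51 percentage points
per generation — the random-mating reference against which rotation is
judged.

Three reporting conventions exist in `rate_per_generation()` and
`expectation_rate()`:

* `absolute_points` — endpoint difference per step, in percentage points
  (default for $F$ series);
* `relative` — percent of the starting value lost per step (default for
  $H$ series);
* `slope` — OLS slope of the per-generation mean on generation. For
  rotational $F$ series the 6-generation cousin cycle makes endpoint-based
  rates depend on where the endpoints fall in the cycle (G28 is a
  post-spike trough and biases the endpoint rate low); the regression
  slope is phase-robust and is the convention used for colony $F$-rate
  reporting.

For the expected-$H$ rate computed from the published per-generation
breeder census, the span convention is not pinned down by the source. The
package reports the average per-step relative decrease over the full span
with known counts (G0–G26), under which both lines land on ~1.5%/gen
(HCR 1.48, LCR 1.59); the G5–G26 alternative (the genotyped span) gives
1.40/1.52 and is logged alongside.

### The one-generation inbreeding lag

A realized random-mating pedigree (`build_random_mating_pedigree()`) uses
monogamous male–female pairs re-drawn each generation, with each offspring
assigned to a uniformly random pair. Multinomial family sizes match the
variance assumptions behind $c_n$; balanced (equal) family sizes would
double the effective size and halve the realized rate. With separate
sexes, inbreeding cannot arise in the first offspring generation of
unrelated founders: the pedigree's mean $F$ at generation $g$ corresponds
to the recursion's $F_{g-1}$. Tests therefore compare lag-aligned
trajectories, within three Monte-Carlo standard errors over 60–100 seeds
at up to ten generations; beyond that a small second-order damping term of
monogamous mating (relative size $\approx c$ per step) accumulates beyond
Monte-Carlo resolution, which is why the tests do not stretch to 28
generations.

## The gene-drop engine

`make_genetic_map()` emulates a 2.75-Gb genome (20 autosomes + X by
default, 1 cM per 2 Mb); marker spacing is uniform or uniform-random, the
real panel's spacing distribution being unknown.
`simulate_founders()` builds each founder haplotype as a mosaic of K = 8
ancestral inbred strains, with ancestry switch points Poisson along the
genetic map. The switch rate (default 0.3/cM, i.e. mean block ~3.3 cM) is
an emulation knob standing in for a few dozen generations of stock mixing,
not a measured value; smaller values (e.g. 0.1/cM) give larger blocks and
stronger short-range LD and are used where the analysis needs the
strong-LD regime. Strain haplotypes are i.i.d. Bernoulli(½) per marker
unless supplied, so the expected founder heterozygosity is
$\mathrm{mean}_m\, 2p_m(1-p_m)$ with $p_m$ the strain-pool frequency.

`drop_genotypes()` transmits recombinant gametes through any pedigree with
crossover counts Poisson in map distance (Haldane, no interference — the
simplest model consistent with the available information). X-chromosome
males are hemizygous: they carry the maternal X in both haplotype slots
(coded homozygous) and pass their single X to daughters only. Everything
is deterministic given the seed.

What the generator does *not* emulate: mutation, genotyping error beyond
uniform missingness, crossover interference, marker ascertainment, and the
real panel's allele-frequency spectrum. The last point matters for LD:
with 8 independent strain haplotypes the expected $r^2$ between perfectly
co-inherited markers is only $\approx 1/(K-1)$ in the founder pool, so
absolute $r^2$ levels are lower than on the real ascertained panel and
only the *shape* (monotone decay with distance, drift-driven rise over
generations) transfers.

## Population-genetic statistics

* **Marker QC** (`qc_marker_panel()`): duplicates → missingness > 10% →
  HWE exact test $p < 10^{-3}$ (yielding a "panel 1") → windowed LD prune
  (10-SNP windows, step 2, remove the later marker of a pair with
  $r^2 > 0.05$) → MAF < 5% (yielding "panel 2"). The HWE test is the exact
  conditional test without mid-p. All thresholds are arguments.
* **ROH** (`detect_roh()`): maximal runs of consecutive homozygous,
  non-missing calls, kept if ≥ 4 markers and ≥ 1 marker per 500 kb over
  the span; segment length is end − start in 1-based bp. The strictest
  reading — no heterozygous or missing call inside a run — is the default.
* **LD** (`ld_decay()`): pairwise $r^2$ within 5 Mb, binned at 500 kb.
  Unphased genotypes go through two-locus EM haplotype frequencies; the
  double-heterozygote is the only latent cell. Phased counting is
  available and agrees with EM whenever phase is unambiguous. The
  threshold-crossing distance interpolates linearly between bin centers.
* **AMOVA** (`amova_two_groups()`): per-locus one-way variance partition
  on allele indicators (each diploid contributes two observations),
  components summed across loci and expressed as the among-group
  proportion — the "weighted average over loci" convention, clipped to
  $[0, 1]$.
* **IBS/MDS** (`ibs_mds()`): $\mathrm{IBS} = (2 - |g_i - g_j|)/2$
  averaged over shared calls; classical Torgerson scaling of
  $1 - \mathrm{IBS}$.
* **IBD** (`ibd_z_proportions()`): method-of-moments $Z_0, Z_1, Z_2$ from
  IBS-state counts given allele frequencies, projected to the simplex. No
  small-sample frequency correction is applied, so estimates are noisier
  than tool-grade output at small panels; pedigree expectations
  (parent–offspring $Z_1 \approx 1$, full sibs $(0.25, 0.5, 0.25)$, half
  sibs $(0.5, 0.5, 0)$) are recovered on simulated data.
* **Sex inference** (`infer_sex_chrx()`): deterministic two-means split of
  per-animal X heterozygosity, threshold at the cluster-mean midpoint,
  configurable ambiguity band. Simulated males sit at exactly zero.

## Quantitative genetics

Phenotypes are additive: $y = \sum_q x_q a_q + e$, $e \sim N(0,
\sigma^2_E)$, with $\sigma_E$ optionally calibrated against the realized
founder genetic variance to hit a target $h^2$
(`trait_architecture()`, `simulate_phenotypes()`).
`simulate_breeding_values()` draws pedigree-consistent breeding values by
the Mendelian-sampling recursion, with variance
$\sigma_a^2(0.5 - 0.25(F_s + F_d))$ for the within-family deviation.

`animal_model()` is the REML fitter: $y = X\beta + u + e$,
$\operatorname{var}(u) = \sigma^2_A A$. The likelihood is profiled over
$h^2$ with the residual scale maximized analytically; each profile point
solves the sparse mixed-model equations built from Henderson's $A^{-1}$,
so a ~6,000-animal colony fits in seconds. The profile deviance is
verified against a dense-matrix REML implementation to $10^{-6}$, the
optimum against a 21-point grid, and the standard error comes from the
numerical curvature of the profile deviance (a profile-likelihood SE;
adequate away from the $[0,1]$ boundary, anti-conservative at it).
`heritability_midparent()` is the cheap cross-check: offspring-mean on
mid-parent regression after covariate residualization.

Under *within-family* truncation selection the expected response to the
within-family selection differential is the within-family heritability
$(\sigma_a^2/2)/(\sigma_a^2/2 + \sigma_e^2)$ — at $h^2 = 0.5$ exactly
$1/3$ — which is what the selection-driver test asserts; cohort-level
response to cohort-level differential would conflate between-family
variance that this design never selects on.

`castle_wright()` uses the standard unlinked-equal-effect form
$n_E = (\mu_{P1} - \mu_{P2})^2 / (8(\sigma^2_{F2} - \sigma^2_{F1}))$ (the
source of the estimator does not print the formula; this is the canonical
one, and its assumptions — unlinked, additive, equal effects, fully
diverged parents — are the documented caveats). On simulated 8-QTL
intercrosses the estimator's median sits in the published 4–10 band, with
a heavy upper tail whenever $\sigma^2_{F2} - \sigma^2_{F1}$ is small — the
known instability of the denominator; incomplete fixation of QTL in the
parental lines biases it low. Parental means are taken as the
final-generation line cohort means.

`vertical_work()` is the treadmill work equation
$d \cdot w \cdot \sin(15^\circ) \cdot 9.8 / 1000$ J for distance in m and
weight in g. `divergence_statistics()` reproduces the published G28
contrasts from per-sex summary rows: fold change of sex-averaged means,
and mean difference in units of the average combined-sex within-line SD,
where the combined-sex moments come from the two-component mixture
formula — the only convention that reproduces the published "9 SD units"
from the printed per-sex tables.

## The synthetic colony stand-in

The real colony's full pedigree/phenotype export is not redistributable,
so `simulate_colony_records()` builds a clearly-labelled synthetic
stand-in from what *is* published: the idealized rotational core supplies
the breeding structure; per-generation, per-sex cohort sizes match the
published census exactly (5,976 HCR and 5,446 LCR animals over G1–G28);
within-stratum log-normal running distances center on the published
stratum means with SD 0.2 on the log scale (matching the published
coefficients of variation); an additive genetic component with
$h^2 = 0.47$ of log distance runs through the pedigree; and body weights
match the published stratum moments with per-sex rank correlations at the
published Spearman values (via $r = 2\sin(\pi\rho/6)$ against the
stratum-standardized distance deviation — standardized empirically,
because within-generation relatedness shrinks the raw within-stratum
variance and would otherwise attenuate the correlation).

Features of the real data deliberately not emulated: substitute and
out-of-schedule matings, cross-generation matings, refused-to-run missing
phenotypes, operator effects, and litter-size variation. Consequently the
stand-in's $F$ trajectory is exactly the idealized scheme's (slope
0.92%/gen vs the real pedigree's 0.94 — the real colony's substitute
matings add a little extra inbreeding), and REML on it tests estimator
recovery under the published conditions, not the real data's robustness
problems. The heritability fit uses sex × generation fixed effects as the
generation-blocked surrogate for the unpublished operator covariate.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately desk-scale configurations: maps
of 100–500 markers over 1–10 chromosomes, founder pools of 26–186, 8–28
generations, 25–100 seeds for Monte-Carlo properties, three-SEM bands for
stochastic assertions. These are the package's choices for fast,
convergent checks; all generators scale to panel sizes of the real study
(a 10K-marker, 28-generation colony drop runs in minutes).

Other numerical conventions: ties in within-family selection break to the
smallest id; EM for two-locus haplotypes starts at linkage equilibrium and
iterates to $10^{-10}$; the REML profile searches $h^2 \in [10^{-4},
1 - 10^{-4}]$; AMOVA skips monomorphic loci and errors only when no locus
is informative; degenerate LD pairs (monomorphic) are skipped; mean $F$
per generation is *not* monotone under rotation (it dips after each
cousin-mating spike), so monotonicity is asserted only for the closed-form
recursions.

## Known limitations

* The recursion comparison inherits the one-generation lag and a small
  monogamy damping term; neither matters at the reported precision but
  both preclude bit-exact recursion-vs-pedigree equality.
* Absolute LD and AMOVA levels depend strongly on founder-pool size and
  marker ascertainment; only qualitative patterns (monotone LD decay,
  rising between-line differentiation, line separation in MDS) are
  claimed for real data.
* The animal model fits a single trait with independent residuals; no
  maternal effects, litter effects, or genetic correlations.
* Castle–Wright is reported with its classical biases; it is an order-of-
  magnitude tool, not an estimator with useful confidence intervals.
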