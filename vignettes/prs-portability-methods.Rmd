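---
title: "Methods: decomposing the cross-population portability of polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing the cross-population portability of polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsport)
```

## The problem

A polygenic score (PRS) built from GWAS effect sizes estimated in one
population loses predictive accuracy when applied in a genetically distant
population. Three mechanisms act even when the causal variants and their
per-allele effects are identical everywhere: (i) the score's SNPs tag the
causal variants through linkage disequilibrium (LD), and LD patterns differ
between populations; (ii) the per-variant variance contribution
$2p(1-p)\beta^2$ depends on the allele frequency $p$, which differs between
populations; and (iii) SNP heritabilities of the trait may differ. A fourth
mechanism — genuinely different causal effect sizes (cross-population effect
correlation $\rho_b < 1$) — is not identifiable from summary data and enters
only as an assumption.

`prsport` implements the full analysis pipeline around this decomposition:
clumping + thresholding PRS construction over a tuning grid, incremental-$R^2$
evaluation (liability scale for binary traits), a continuous genetic-distance
metric, the relative-accuracy (RA) decomposition with loss-of-accuracy (LOA)
statistics, and recombination-rate-stratified accuracy — all exercised on a
synthetic genotype/phenotype generator, because the cohort and biobank data
such analyses are run on are controlled-access.

## The relative-accuracy model

Let population 1 be the discovery GWAS population and population 2 the
target. For PRS SNP $k$ with marginal effect estimate $\hat\beta_k$,
frequencies $p_{k,1}, p_{k,2}$, and candidate causal neighbors $j$ (every
variant within 100 kb with $r^2 > 0.45$ to SNP $k$ in the discovery panel,
always including SNP $k$ itself), write
$\overline{r^2_{k,1}}$ for the mean squared discovery-panel correlation over
candidates and $\overline{r_{k,1} r_{k,2}}$ for the mean product of signed
correlations in the two panels. The predicted relative accuracy is

$$
RA \;=\; \frac{R^2_{2}}{R^2_{1}} \;\approx\;
\frac{\rho_b^2\, h^2_{2}}{h^2_{1}} \times
\left(
\frac{\sum_k \overline{r_{k,1} r_{k,2}}\,
      \sqrt{\tfrac{p_{k,2}(1-p_{k,2})}{p_{k,1}(1-p_{k,1})}}}
     {\sum_k \overline{r^2_{k,1}}}
\right)^{\!2}
\times
\frac{\sum_k p_{k,1}(1-p_{k,1})\hat\beta_k^2}
     {\sum_k p_{k,2}(1-p_{k,2})\hat\beta_k^2}.
$$

Constrained variants isolate each factor: `ra_ld_maf()` sets
$h^2_1 = h^2_2$, $\rho_b = 1$; `ra_ld()` keeps only the tagging ratio;
`ra_maf()` assumes every PRS SNP is itself causal, reducing the tagging term
to $\bigl(\sum_k \sqrt{p_{k,2}(1-p_{k,2})/p_{k,1}(1-p_{k,1})}/M\bigr)^2$.
Each prediction is summarized against the observed ratio
$RA_{\mathrm{OBS}} = R^2_2 / R^2_1$ as the percentage of the observed loss it
accounts for, $LOA = (1 - RA_{\mathrm{pred}})/(1 - RA_{\mathrm{OBS}}) \times 100\%$.

Two reading-of-the-formula decisions are worth recording. First, the
square-root frequency ratio is indexed by the PRS SNP $k$, not by the
candidate $j$, so the candidate-level average applies only to the signed
$r$ products. Second, the candidate screen's LD threshold ($r^2 > 0.45$,
exceeded strictly) is evaluated in the discovery population's reference
panel: candidates are proxies for what the discovery GWAS could tag. Both
choices are configurable arguments.

Standard errors for every RA and LOA term come from resampling the $M$ PRS
SNPs with replacement (default 1000 replicates) with normal-approximation
95% intervals ($\pm 1.96\,SE$). A SNP-level bootstrap is self-contained and
assumption-light; it treats the PRS SNP set as the sampling unit, which is
the level at which the model's sums are defined.

### What the model cannot do

Because every PRS SNP is always its own candidate (with $r = 1$ in both
panels), the candidate-mean tagging ratio is pulled toward 1 whenever true
tagging is lost. In generative simulations where LD divergence is the loss
mechanism, `ra_ld_maf()` therefore lies *between* `ra_maf()` and the observed
RA rather than on top of the observed RA — it captures part, not all, of the
LD-driven loss. This mirrors what such decompositions report on real
biobank data, where predicted accuracies exceed observed ones for every
ancestry, and is why LOA is a useful summary at all. The package's
acceptance checks assert exactly this directional behavior, not exact
recovery.

## Accuracy evaluation

`incremental_r2()` reports $R^2(\text{covariates} + \text{PRS}) -
R^2(\text{covariates})$, by OLS for quantitative traits. The default
covariate design (`standard_covariates()`) is age, age², sex, age×sex and
the first ten genetic PCs. For binary traits the models are logistic and the
observed-scale $R^2$ is the squared Pearson correlation between outcome and
fitted probabilities — continuous with the linear-model definition; whether
a pseudo-$R^2$ (e.g. Nagelkerke) would be preferable is genuinely open, and
the choice is documented rather than hidden. `liability_r2()` converts the
observed-scale value with the Lee et al. (2012) transformation
$R^2_l = C\,R^2_o/(1 + C\,\theta\,R^2_o)$, where
$C = \frac{K(1-K)}{z^2}\frac{K(1-K)}{P(1-P)}$, $K$ is the population
prevalence, $P$ the sample case proportion, $z$ the normal density at the
liability threshold, and $\theta$ the ascertainment correction (zero for
population samples, where the factor reduces to $K(1-K)/z^2$). $K$ defaults
to the sample case proportion because the cohorts emulated here are
population-based; it is configurable.

Confidence intervals are percentile bootstrap over individuals, 1000
replicates by default. Negative incremental $R^2$ (pure sampling noise) is
reported as computed, never truncated, so bootstrap percentiles remain
valid. Replicates on which a statistic is undefined (e.g. a case-free
resample) are redrawn with a logged count.

## PRS construction

`clump()` is greedy $p$-value-ordered clumping: take the most significant
remaining variant passing the threshold as an index SNP, remove all
remaining variants within the physical window whose dosage $r^2$ with it
exceeds the LD threshold, repeat. LD is the squared Pearson correlation of
dosages in a genotype reference panel (composite LD; no phasing), windows
are closed intervals in bp on the same chromosome, and $p$-value ties break
toward smaller (chromosome, position) for determinism. The default tuning
grid is $p \in \{5\times10^{-5}, 0.01, 0.5\}$, $r^2 \in \{0.1, 0.5\}$,
window $\in \{100, 250\}$ kb — 12 scores per discovery population and
phenotype — and `select_best_score()` picks the within-population argmax,
ties toward the stricter thresholds. Scoring is
$PRS_i = \sum_j \hat\beta_j G_{ij}$ on effect-allele dosages, with missing
dosages mean-imputed at $2p$ from the scoring panel.

Allele harmonization (`harmonize()`) aligns summary statistics to a panel's
effect-allele orientation before any signed computation: swapped alleles
negate $\hat\beta$ and complement the frequency; strand-ambiguous (A/T,
C/G) variants are dropped outright rather than frequency-inferred, because
that behavior is deterministic and testable. The operation is idempotent.

## The ancestry space and genetic distance

Ancestry is treated as a continuum. The joint coordinate system is built in
three steps (`build_ancestry_space()`):

1. **Reference PCA with adjusted projection.** Reference PCs come from the
   SVD of the standardized reference genotypes. Study individuals are
   projected with an online augment–decompose–align adjustment
   (`project_pcs(method = "oadp")`): each study sample is appended to the
   reference, the augmented spectral decomposition is obtained from a small
   $(K{+}1)\times(K{+}1)$ eigenproblem, and a Procrustes transform mapping
   the reference's augmented coordinates back onto its original scores is
   applied to the study sample. This counteracts the shrinkage toward zero
   that naive projection suffers when variants far outnumber reference
   samples (`method = "naive"` is retained as the fallback and for
   comparison). The adjustment is accurate on structured dimensions (clear
   eigengaps); on noise dimensions any augmented decomposition mixes
   near-degenerate eigenvectors, so a duplicated reference sample reprojects
   to within a few percent of — not exactly onto — its reference
   coordinates. Tests assert that contract rather than exact recovery.
2. **Allele-frequency MDS.** Classical (Torgerson) MDS of the pairwise
   Euclidean distances between population allele-frequency vectors, for the
   reference populations together with the discovery-GWAS populations, on
   the variants present in all sources. Classical MDS is the deterministic
   flavor with an exact spectral oracle. Component signs are fixed
   (largest-magnitude loading positive).
3. **Procrustes alignment.** The closed-form orthogonal Procrustes solution
   (scale, rotation, translation) maps the reference populations' MDS rows
   onto their PC centroids; the fitted transform is then applied to *all*
   MDS rows, placing the discovery-GWAS populations into PC space.
   Reflections are allowed (orthogonal, not special-orthogonal): a
   reflection can only reduce the alignment error, and the choice is
   switchable (`allow_reflection = FALSE`).

Genetic distance is the Euclidean distance between an individual's PC
coordinates and a mapped GWAS point. The real analyses use five dimensions;
the synthetic two-population designs here span two, so the package default
is dimension-agnostic (`k` argument) and the bundled study uses `k = 2`.
`binned_accuracy_profile()` assigns individuals to equal-sized distance bins
(20 by default, deciles for within-ancestry profiles; sizes differ by at
most one), evaluates the incremental $R^2$ within each, plots bins at their
mean distance, and reports the Pearson correlation between bin mean distance
and accuracy with the bin-level regression p-value. Inference is at the bin
level — that is the unit the profile plots — and per-individual alternatives
are out of scope. How many variants enter the PC/MDS step, and whether they
are LD-pruned first, is an exposed choice, not an assertion.

## Recombination-rate stratification

If LD divergence drives non-portability, SNPs in low-recombination regions
(where LD is conserved across populations) should transfer better.
`interpolate_rate()` computes the mean rate in a 20 kb window around each
PRS SNP exactly, as the difference of the linearly interpolated cumulative
map divided by the window width in Mb — an integral, not an average of
sampled rate points, which removes the discretization ambiguity of
"linear interpolation". Windows truncated at the map ends renormalize by the
retained width. `quartile_profile()` splits the PRS SNPs into four
equal-sized rate bins (ties broken by position; sizes within ±1), scores
each subset separately — the sub-scores sum exactly to the full score — and
evaluates each with percentile-bootstrap CIs.

## The synthetic-data generator

The generator produces the statistical structure the analysis consumes and
nothing more:

* **Genotypes** (`simulate_genotypes()`): a Gaussian copula on latent
  haplotypes. Each haplotype allele indicates that a latent standard normal
  falls below the frequency quantile; latent variables follow a per-block
  AR(1) correlation, and a genotype is the sum of two independent
  haplotypes. This gives independent, analytically checkable control of the
  two levers the RA model isolates: marginal frequency and LD. The realized
  genotype correlation is the thresholded-bivariate-normal value, which the
  tests verify against numerical integration. There is no coalescent
  realism, selection or phasing — only moments.
* **Effects and phenotypes** (`simulate_effects_and_phenotypes()`): causal
  effects drawn jointly across populations with correlation $\rho_b$ on the
  standardized-genotype scale, then converted to per-allele units; each
  population's genetic value is rescaled so the realized genetic variance
  fraction equals its target $h^2$ exactly. Standardized sharing is the
  default because it is the regime in which the MAF-only RA prediction is
  unbiased for the observed RA (effect sizes independent of frequency);
  per-allele sharing is available (`effect_scale_mode = "per_allele"`).
  Binary traits threshold the unit-variance liability at the
  $(1-K)$ normal quantile — the regime in which the Lee transformation is
  exact.
* **Summary statistics** (`simulate_sumstats()`): actual per-variant
  marginal regressions on a simulated discovery cohort, not analytic noise
  injection, so LD-induced tagging is present in $\hat\beta$ — the RA
  model's $\bar r$ terms require it.
* **Admixture gradient** (`simulate_admixture_gradient()`): per-individual
  admixture fraction $\alpha \sim U(0,1)$ with per-variant frequency
  $\alpha p_A + (1-\alpha) p_B$, providing the continuum for the
  genetic-distance analyses.
* **Recombination maps** (`simulate_recomb_map()`,
  `recombination_map()`): piecewise-linear cumulative maps in the HapMap
  convention (the rate column applies from each position to the next).

## Study conditions and problem sizes

The bundled study (`run_config()` defaults) uses two populations, 600
variants in 3-SNP LD blocks, 150 causal variants, discovery cohort 6000 and
4000-sample evaluation cohorts, $h^2 = 0.30/0.25$, $\rho_b = 0.8$,
AR(1) LD 0.8 vs 0.35, symmetric frequency perturbation up to ±0.2 with a
directional heterozygosity deficit at causal variants in the target
population (the discovery-bias mechanism), prevalence 0.3 for the binary
trait, the 3×2×2 tuning grid, 1000 bootstrap replicates, 20 distance bins
and a 3000-sample admixed cohort. The generative recovery experiments use
20 replicate simulations of 50,000 samples per cohort and 500 variants; the
liability recovery uses 30,000 samples; bootstrap calibration uses 200 outer
repetitions of 1000-replicate CIs. These sizes make every Monte-Carlo
tolerance in the tests a property of the design rather than of luck, while
keeping a full run in minutes on one CPU.

What passing tests on this generator shows: the estimators and the
decomposition behave as derived under the model's own assumptions
(controlled MAF/LD divergence, liability-threshold binary traits,
homogeneous effect scaling). What it does not show: robustness to real-data
features the generator deliberately omits — long-range LD, allele-frequency
spectra shaped by demography, genotyping error, phenotype measurement
heterogeneity, or fine-scale structure within reference populations.

## Numerical choices and degenerate inputs

* Clumping p-ties and rate-bin ties break by (chromosome, position);
  interpolated rates are rounded at 1e-9 before ordering so floating-point
  jitter cannot reorder exact ties.
* Monomorphic variants: excluded from summary statistics, from RA sums
  (the frequency-ratio terms are undefined at $p(1-p) = 0$) and from the
  PCA standardization, always with logged counts.
* A constant PRS yields incremental $R^2 = 0$ with a warning; exactly
  collinear covariate columns are dropped with a warning.
* `relative_accuracy_observed()` refuses a non-positive discovery $R^2$;
  `loa()` refuses $RA_{\mathrm{OBS}} \ge 1$ (no loss to explain).
* Bin assignments (`balanced_bins`) are exact partitions with sizes within
  ±1, smallest values first.
* Stage seeds derive from the run seed by a fixed affine fold into
  $[0, 2^{31})$, so every stage is independently reproducible.

## Relatedness pruning

Sample QC in such studies removes one member of each pair with kinship
above 0.1. Kinship estimation itself is out of scope here;
`prune_related()` implements the generic pruning contract over an
externally supplied pairwise kinship table, removing one member of each
over-threshold pair at random (seeded) until no retained pair exceeds the
threshold.

## A worked miniature

```{r demo, eval = FALSE}
cfg <- run_config(seed = 42, out_dir = "results/full_study")
bundle <- run_all(cfg)
bundle$best          # selected grid cell
bundle$ra_obs        # observed relative accuracy
bundle$ra_report     # RA_MAF / RA_LD / RA_LD+MAF / RA_full with LOA
bundle$gd_profile    # accuracy by genetic-distance bin
bundle$recomb_profile
```

The `analysis/` directory contains the numbered drivers that reproduce the
full set of tables under `results/`, and `scripts/acceptance.R` recomputes
the headline quantities from scratch for a given seed.
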