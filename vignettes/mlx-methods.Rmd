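---
title: "Models and methods behind mlxtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mlxtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlxtools)
```

# The experimental design

Male-limited X (MLX) evolution uses compound-X (DX) females — two X
chromosomes fused at the centromere, plus a Y — to force father→son
transmission of the X. In the DX cross, the father's X-bearing sperm is
only viable with the mother's Y-bearing egg (a wildtype son carrying an
exact copy of the paternal X), and his Y-bearing sperm only with her
compound-X egg (a new DX daughter); triple-X and YY zygotes die. Three
male genotype classes are compared: Control (`C`), Control-X males
produced by one passage through a DX mother (`CDX`), and males whose X
evolved for many generations under male-limited transmission (`MLX`).
The expression design is 3 treatments × 3 replicate populations × 2
replicate arrays = 18 arrays; the fitness assays use 20 vials per
population, 3 populations per treatment.

Everything in this package runs on synthetic data whose generating
process matches the assumptions of the analysis models, so every test
has ground truth. What that does and does not establish is discussed at
the end.

# Fitness and sex-ratio ANOVAs

Vials are the sampling unit of the paternity assay (target males within
a vial are not independent), but vials within a replicate population
share that population's evolutionary history, so treatments are
compared at the *population-mean* level: each (treatment, population)
cell contributes one mean, giving the one-way ANOVA df = (2, 6) at
canonical replication. `oneway_anova()` delegates to `lm()`/`anova()`;
a degenerate decomposition (all means identical at floating-point
noise) is reported as F = 0, p = 1 rather than NaN.

Sex ratios (proportion male among adult offspring) are
arcsine-square-root transformed. The transform is applied **per vial**
before averaging, consistent with the vial being the sample; since a
mean of transformed vials is not the transform of the mean,
`analyze_assay(..., transform_at = "population")` provides the
alternative order for comparison. The choice matters little at 20
vials per cell but is explicit rather than silent.

Zero-offspring vials carry no information about a proportion and are
dropped (with a count), not imputed.

# Per-transcript nested ANOVA

The model is Treatment fixed and Population a random factor nested
within Treatment. For transcript values $y_{ijk}$ (treatment $i$,
population $j$, replicate $k$), the correct test of the treatment
effect uses the population-within-treatment mean square as its error
term:

$$F = \frac{MS_{\mathrm{Treatment}}}{MS_{\mathrm{Pop(Treatment)}}},
\qquad df = (t - 1,\; t(b - 1)) = (2, 6),$$

independent of the number of replicate arrays per population — the
arrays only sharpen the population means. The implementation is a
vectorised sums-of-squares decomposition over the whole matrix (a 5000
× 18 matrix takes well under a second); tests verify it against an
independent `lm(y ~ treatment/population)` route to ~1e-15 relative
error. Only balanced designs are accepted: with unbalanced data the
nesting decomposition is no longer orthogonal and several inequivalent
approximations exist, so the package refuses rather than silently
choosing one.

Multiplicity across transcripts is controlled with Benjamini–Hochberg
at $q^* = 0.05$. The original analysis states only "a false discovery
rate of 0.05" without naming a procedure; BH step-up under independence
is the standard reading and `stats::p.adjust(method = "BH")` is used
(rejection at $q \le q^*$ is equivalent to the step-up rule).

## Pairwise contrasts and the six categories

For transcripts passing the FDR gate, the three pairwise treatment
contrasts are tested with the pooled population-within-treatment mean
square as the error term, $t = \Delta / \sqrt{2\,MS_{P}/(br)}$ on
$t(b-1) = 6$ df. Pairwise p-values are taken at unadjusted
$\alpha = 0.05$ by default — the gate has already controlled the
transcript-level FDR and no pairwise adjustment is described in the
source analysis — with BH across all gated pairwise tests available via
`pairwise_adjust = "BH"`.

Categories follow the significance pattern plus the ordering of the
three treatment means:

| category | pattern | reading |
|---|---|---|
| 1 | C–CDX and C–MLX significant, same direction; CDX–MLX not | maternal effect of DX females |
| 2 | C–CDX and CDX–MLX significant; C–MLX not | imprinting signature (CDX unique) |
| 3 | C–MLX and CDX–MLX significant; C–CDX not | response to MLX evolution |
| 4 | all three; C mean in the middle (CDX–C–MLX) | fitness-related |
| 5 | all three; MLX in the middle (CDX–MLX–C) | maternal effect reduced by adaptation |
| 6 | all three; CDX in the middle (C–CDX–MLX) | maternal effect enhanced by adaptation |

Anything else — no pair, a single pair, or CDX and MLX deviating from C
in opposite directions — is category 0 with the reason recorded. The
strict rule (ordered categories require all three contrasts) is the
default; the documented ambiguity between a just-underpowered ordered
pattern and categories 2/3 motivates the `lenient` mode, which promotes
CDX–MLX plus one other significant pair to an ordered category. Lenient
necessarily cannibalises categories 2 and 3, which is why strict is the
default and lenient is reported only for comparison.

# Enrichment batteries

*GO*: flat upper-tail hypergeometric per term,
$p = P(X \ge \text{observed})$, universe = all informative transcripts
on the array. No graph propagation or conditional testing — annotations
are taken as given — and term p-values are reported raw by default
(`adjust = "BH"` optional), matching how term lists are usually
reported for this design.

*Chromosomes*: goodness-of-fit $\chi^2 = \sum (O-E)^2/E$ of the set's
chromosome counts against universe proportions, df = #chromosomes − 1.
Excluding a chromosome (the gene-poor chromosome 4 is the motivating
case) renormalises the proportions over the remainder and reduces df.
Cells with zero expectation are dropped with a warning.

*Tissues*: per tissue, a one-tailed Fisher exact test on the 2×2 table
(in set vs not) × (tissue-specific vs not), Bonferroni-corrected by the
panel size (17 in the atlas emulation). The one-tailed Fisher p equals
the hypergeometric upper tail of the same table; the tests verify this
identity numerically.

*MR-GSE*: the mean rank of the set in a genome-wide association
ranking, with the sampling-without-replacement null moments
$E = (N+1)/2$ and $\mathrm{Var} = (N-n)(N+1)/(12n)$, two-tailed normal
p. An exact mode evaluates the permutation distribution through the
exact Wilcoxon rank-sum distribution (`pwilcox`; the rank sum is $n
\cdot \bar r$, valid without ties). `method = "auto"` uses exact when
$n(N-n) \le 10^4$ — beyond that the exact DP becomes expensive while
the normal approximation is already accurate to ~0.01, which the test
suite checks directly for $n \ge 20$, $N \ge 200$. Ties are mid-ranked;
with continuous scores they do not arise.

# Feminization direction test

Every informative X-linked transcript is cross-classified by its
sex-bias direction (sign of female − male expression, an **external**
annotation — the 18 arrays are all male, so sex bias cannot come from
this experiment) against the sign of its CDX − C mean difference, with
no individual significance filter. Transcripts with an exact zero on
either axis are excluded and counted.

The omnibus null is **uniform over the four cells** (expected =
total/4), matching the constant expected value of the published worked
table — not an independence (margin-product) null. The two differ
whenever the margins are unbalanced, so this choice is deliberate and
prominent: the uniform null asks whether transcripts spread evenly over
the direction combinations, and feminization specifically predicts mass
in the two concordant cells, which is why the concordant fraction is
reported alongside χ². With observed counts (116, 69, 187, 71) the test
gives expected 110.75 per cell and χ² = 82.7517 on df = 3 — and the
concordant fraction 0.42 shows the signal is *not* feminization but a
general up-shift of X-linked expression in CDX males.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions and were chosen once:

* Design 3 × 3 × 2 (18 arrays). Expression = baseline (N(7, 2²) log2
  units) + fixed treatment offset + population effect drawn once per
  (transcript, population) and shared by both replicate arrays —
  exactly the random-effect structure the nested ANOVA assumes — +
  independent residual. `population_sd = 0.1`, `residual_sd = 0.3`
  log2 units, typical of between-replicate variability on normalized
  arrays.
* Planted effect size 1.5 log2 units = 5× the residual sd, the regime
  in which category recovery is assessed; category 4 up-variant offsets
  are (δ_CDX, δ_C, δ_MLX) = (−e, 0, +e), categories 5/6 use equal
  spacing e with C fixed at 0 as the reference. The per-category effect
  magnitudes in real data are unknown; these are free parameters of the
  artifact, not estimates.
* Annotations: fly-like chromosome weights (X 0.16, 2 0.40, 3 0.42,
  4 0.02 — chromosome 4 deliberately gene-poor), 17-tissue panel with
  disjoint-per-tissue specific sets, GO-like terms as random subsets,
  standard-normal fitness-association scores. Signal is planted on
  request (score boosts for MR-GSE recovery; `couple_sign`/`coupling`
  ties sex bias to the CDX shift for feminization power tests). By
  default sex bias is independent of expression effects, so the
  feminization test is null-calibrated.
* Fitness assay: beta-binomial vials (`overdispersion` = intra-vial
  correlation 0.02, population effects sd 0.03 on the proportion
  scale) — the vial-level overdispersion that motivates population-mean
  ANOVA. Treatment siring proportions 0.5 / 0.4 / 0.6 for C / CDX /
  MLX, i.e. ±20% around Control, the magnitude of fitness divergence
  the design is meant to detect; 20 vials × 3 populations × 3
  treatments = 180 vials, 80 offspring per vial.

# The transmission simulator

Discrete non-overlapping generations; the 48-h mating ecology is
abstracted into fitness-proportional paternity (and maternity for
wildtype females), since paternity share is exactly how fitness is
measured. Haplotypes are 0/1 vectors over `L` SA loci; fitness is
multiplicative, $(1+s_m)$ per allele in hemizygous males and
$(1-s_f)^{c/2}$ for allele count $c$ in females (semidominance — a free
modelling choice). MLX mode: main population of males + DX females
(sons copy the father's X exactly), exchanging `migrants_per_gen` males
with a wildtype recombination box each generation; selection inside the
RB acts on both sexes by default and can be disabled, since its
strength is not specified by the protocol. Control mode: one wildtype
population, standard XY segregation, per-adjacent-locus recombination
in female meiosis. X–Y recombination in DX females is not modelled (it
is unknown whether it occurs). Locus count and per-locus effects are
user parameters; nothing constrains them empirically.

Structural laws are tested rather than assumed: no triple-X/YY
individual can be constructed, sons' X equals the father's X under the
DX cross, MLX without migration only resamples existing haplotypes,
neutral trajectories are a martingale, and paired MLX-vs-Control runs
show the male-benefit allele frequency rising faster under MLX.

# Numerical choices and degenerate inputs

* Nested ANOVA with zero population mean square: F is 0 when the
  treatment SS is also zero, +Inf (p = 0) otherwise.
* Contrast t with zero SE and zero difference is 0 (p = 1).
* BH on an empty vector returns empty; q ≥ p always holds.
* χ² cells with zero expectation are dropped with df reduction and a
  warning, never divided by.
* All generators are seeded (`withr::with_seed`) and leave the caller's
  RNG state untouched; identical arguments + seed give bit-identical
  output.

# Problem sizes used in the checks

Null calibration uses 5000 all-null transcripts for the
Kolmogorov–Smirnov uniformity check and 20 seeds × 2000 transcripts for
the realized-FDR check; oracle comparisons use 100 random instances
each; category recovery uses 2000 transcripts with 100 planted per
category 1–4; the simulator checks use populations of 100–120 over
10–20 generations with 50–200 replicate runs. These sizes give the
binomial/KS margins quoted in the tests while keeping a full run of the
suite in a few minutes.

# What passing these tests shows — and what it does not

The generator draws from the exact model families the analyses assume:
Gaussian noise with true population random effects, beta-binomial
vials, independent transcripts. Passing therefore demonstrates
correctness of the implementations and calibration *under the assumed
model*, not robustness to what real arrays do: correlated transcripts,
heavy-tailed residuals, normalization artefacts, probe effects, or
confounding between population and batch. The original raw data are
not available, so the real-data summary statistics cannot be
recomputed here; the package instead reproduces every closed-form
worked example exactly and validates the stochastic machinery by
property.
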