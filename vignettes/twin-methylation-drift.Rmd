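---
title: "Methods: longitudinal twin methylation analysis with twindrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal twin methylation analysis with twindrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindrift)
```

## The scientific problem

Longitudinal twin designs separate the forces acting on the early-life
methylome. Comparing the same child's buccal methylome at birth and at 18
months measures developmental (age-associated) change; comparing co-twins
measures the residue of non-shared environment and stochastic events on top
of a shared genome (MZ) or half-shared genome (DZ); and following the
*within-pair* difference over time asks whether pairs drift apart
epigenetically, converge, or stay put. `twindrift` implements this entire
analysis chain — quality control, paired empirical-Bayes testing,
bump-hunting region detection, annotation enrichment, and the discordance /
drift-convergence classification — together with a synthetic cohort
generator that provides ground truth for every stage.

## The generative model

All effects are additive on the log2-odds (M-value) scale and transformed
back with the inverse logit, which keeps β in [0, 1] and makes M-value
testing natural. For probe $g$, individual $i$ in pair $p$, timepoint $t \in
\{\text{birth}, \text{18m}\}$:

$$\mathrm{logit}_2(\beta_{git}) = \mu_g + a_g \, 1[t = 18\text{m}] + G_{gi} +
C_{gp} + \lambda_p^{1[t = 18\text{m}]} E_{git},$$

- $\mu_g$: probe baseline, drawn from a bimodal mixture (40% low-methylated
  Beta(2,8), 40% high Beta(8,2), 20% uniform mid-range) as on real arrays;
- $a_g$: planted age effect. The configured effect size is a **β shift**
  (default 0.25) converted per probe into the log2-odds offset that produces
  exactly that shift at the probe's baseline;
- $G$: genetic component (sd `sigma_genetic`), identical for MZ co-twins and
  correlated `dz_genetic_correlation` (default 0.5) for DZ co-twins;
- $C$: shared-environment component per pair (sd `sigma_shared_env`);
- $E$: non-shared stochastic component per individual and timepoint (sd
  `sigma_nonshared`), scaled at 18 months by the pair's dynamics factor
  $\lambda_p$. This is the only place dynamics enter: drift and convergence
  are by construction a property of the non-shared/stochastic term.

Technical replicates add noise of sd `sigma_technical` on the same scale.
Detection p-values are near zero except for a configurable fraction of
probes given failures (> 0.05) in at least one array; these probes are the
QC ground truth. Infinium II probes are compressed toward β = 0.5 by a
configurable factor to exercise the design-bias adjustment.

### Default study conditions

The defaults encode the emulated design: 15 pairs (10 MZ, 5 DZ; MC
chorionicity only within MZ), two timepoints, 20,000 probes, stringent
planted aDMPs of Δβ = 0.25 with an 87% gain bias, region-enrichment odds
(intergenic 6, enhancer 2.5, open sea 1.7, island 0.25) so age effects
concentrate outside CpG-dense promoters, ten planted DMRs of 5–8 consecutive
probes, and λ cycling over 1.6 / 1.0 / 0.6 so drift, stable and converging
pairs appear in equal numbers.

Variance components are free parameters — the source study does not quantify
the non-shared variance share in buccal tissue — and were fixed once by a
variance budget: `sigma_genetic = 0.4`, `sigma_shared_env = 0.3`,
`sigma_nonshared = 0.28`, `sigma_technical = 0.05` (log2-odds units). The
resulting within-pair β differences give MZ pairs Euclidean-distance ratios
of essentially λ between ages, while for DZ pairs the constant genetic
difference dilutes the ratio to ≈ 1.33 (λ = 1.6) and ≈ 0.83 (λ = 0.6) —
still cleanly outside the ±10% stable band. Technical noise an order of
magnitude below `sigma_nonshared` reproduces the observation that co-twin
(biological) variation dwarfs replicate (technical) variation.

Two further generator idealizations matter for the bump hunter. First,
probes are placed in small local groups (3–5 probes within < 1 kb; 55% of
groups anchored at CpG islands and their flanks, 30% in gene footprints, 15%
uniform). Real 450K manifests also cluster probes around islands and
promoters but contain genuinely isolated probes; we exclude them because an
isolated probe passes through the running-mean smoother unchanged, so a
strong isolated aDMP is indistinguishable from a one-probe "region" and the
upper-quantile threshold loses its meaning. Second, affected-probe baselines
are drawn from a mid-methylation band (gains U(0.25, 0.55), losses U(0.45,
0.75)) so that both endpoints of a 0.25 shift stay inside the assay's
dynamic range and the implied log2-odds effects span less than a factor of
two. Passing tests therefore demonstrate correct recovery under these
conditions; on real arrays with isolated probes and a continuum of effect
sizes, region detection at the 0.995 quantile keeps only the strongest
coordinated signals, and probe-level recall at a fixed Δβ has no single
number.

## Processing conventions

Stages run in a fixed order: probe detection filter → sample detection
filter → manual exclusions → sex-chromosome removal → design-bias adjustment
(β scale) → β→M → between-array quantile normalization (M scale).

- **Probe filter.** A probe is removed if its detection p exceeds 0.001 in
  *one or more* arrays; the boundary is strictly greater, so p = 0.001
  survives. Samples are removed when their mean detection p exceeds 0.05.
- **β↔M.** $M = \log_2(\beta/(1-\beta))$ with β clipped to
  $[10^{-6}, 1-10^{-6}]$; raw intensities are out of scope, so M is defined
  from β directly.
- **Design-bias adjustment.** Within each array, Infinium II β values are
  mapped onto the empirical quantiles of the Infinium I probes in the same
  island-relation stratum. The full matched stratum serves as the reference
  (a deterministic special case of subsetting it); the map is monotone, so
  type II ranks are preserved and type I values never change.
- **Quantile normalization.** Every column is forced to the mean of the
  per-column sorted vectors; tied values receive the mean of the reference
  values across the tied ranks.

## The moderated paired test

The paired design is equivalent to a one-sample test on within-individual
differences $d_{gi} = M_{gi,18\text{m}} - M_{gi,\text{birth}}$ (replicates
averaged first; individuals missing a timepoint dropped). Per probe,

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + df_g s_g^2}{d_0 + df_g}, \qquad
\tilde{t}_g = \frac{\bar{d}_g}{\tilde{s}_g/\sqrt{n_g}},$$

with two-sided p-values on $d_0 + df_g$ degrees of freedom. The prior
$(d_0, s_0^2)$ comes from the moment estimator on log variances: solve
$\mathrm{trigamma}(d_0/2) = \mathrm{var}(\log s^2) - \mathrm{trigamma}(df/2)$
by Newton inversion of the trigamma function, then back out $s_0^2$ from the
mean of $\log s^2$; when the spread of log variances does not exceed its
sampling expectation, $d_0 = \infty$ and every probe is tested against the
common variance. At $d_0 = 0$ the statistic reduces exactly to the classic
paired t-test, which the test suite checks to $10^{-9}$, alongside agreement
with an independent implementation of the same estimator and a
marginal-likelihood grid search. Probes with fewer than 3 differences are
flagged and excluded from prior estimation. Benjamini–Hochberg FDR is
applied to the p-values; stringent aDMPs additionally require |Δβ| > 0.2,
where Δβ is the mean within-individual difference of normalized β.

Both the total β change and its per-year rate are reported by the pipeline
summary, since a two-timepoint design cannot distinguish the two
conventions.

## Bump hunting

Probes are chained into clusters wherever the inter-probe gap is ≤ 1 kb
(configurable). The per-probe moderated t is smoothed within clusters by a
centered running mean (window 3; clusters shorter than the window pass
through unchanged — a running mean is used instead of loess because it is
deterministic, parameter-light and adequate at array probe densities). The
detection threshold is the 0.995 **quantile** of the |smoothed statistic|
over all probes — a literal t cutoff of 0.995 would be meaninglessly
permissive — and maximal same-sign runs above it with ≥ 4 probes become
regions, ranked by area. Coordinates are 0-based half-open spanning the
first to last probe plus one CpG-site width; a region is TSS-proximal when
any member probe lies within 5 kb (closed interval) of a transcription
start site.

## Enrichment

For a hit set $H$ in category $K$ within universe $U$ (all QC-passing
autosomal probes, matching the "final data set" convention):
$\text{expected} = |H||K|/|U|$, ratio = observed/expected, and the
hypergeometric upper tail $P[X \ge \text{observed}]$ is the reported
p-value; the lower tail is reported alongside for depleted categories, and
significance tiers (0.05, $10^{-20}$, $10^{-50}$) use the
direction-appropriate tail. Tests are one-sided per direction; no
multiple-testing correction is applied across categories (the raw tiers are
flagged as such in the output).

## Discordance and dynamics

Within-pair discordance at an age is the probe-wise $|\beta_1 - \beta_2|$
(replicates averaged). The package also exposes the residual formulation —
M-values minus the pair-group mean, $\pm(M_1 - M_2)/2$ for complete pairs —
but β-scale discordance is the default for all dynamics summaries.
Delta discordance is the 18-month minus birth discordance per probe;
per-pair Euclidean distances are computed over the full analysis probe set
(whether the original figures used all probes or only the > 0.2 subset is
not stated; all-probe is the default and configurable). A pair drifts when
its distance grows by more than 10% relative to birth, converges when it
shrinks by more than 10%, and is stable otherwise; the boundary is a package
decision — no numeric criterion is published — chosen scale-free and
conservative for the observed distance range, and exposed as
`rel_threshold`. A zero birth distance classifies as stable with a warning.
Ranked gene lists order probes by a discordance metric (descending, ties by
probe id), map them to genes via the manifest, drop intergenic probes and
keep each gene at its best rank.

Birth-weight discordance is $100 \times (\text{heavier} -
\text{lighter})/\text{heavier}$; the bundled pair table reproduces the
published cohort's median of 13.3% at birth, and its removed-array ledger
yields the published 53 of 60 retained arrays.

## Sample-relationship checks

Hierarchical clustering uses Euclidean distance and complete linkage over
arrays (probe-median imputation for missing values), serialized as Newick.
"Co-twins cluster together" is operationalized as **mutual nearest
neighbours** within a timepoint — deterministic and linkage-independent,
with distance ties broken by lexicographic sample id; the dendrogram-sibling
variant is available as an option. SNP-probe subsets (`any_snp`,
`snp_at_cpg`, `none`) re-run the same analyses on genotype-sensitive or
genotype-free probe sets.

## Numerical and implementation choices

- Single RNG stream per cohort seeded from `config$seed`; the same seed
  reproduces every matrix bit for bit.
- Trigamma inversion by Newton iteration to relative $10^{-10}$; $d_0 =
  \infty$ handled analytically throughout the shrinkage formulas.
- Degenerate inputs: all-zero differences give t = 0, p = 1; contrasts with
  fewer than 10 positive variances (e.g. bit-identical replicates) fall back
  to the unmoderated test; empty SNP classes, absent design classes and
  single-sample normalization return identity with a warning rather than
  failing.
- Problem sizes in the test and acceptance suites: 20,000-probe cohorts for
  recovery and null checks (10 and 20 seeds), 4,000-probe cohorts for the
  replicate contrast (20 seeds), chosen so the full suite completes in a few
  minutes while keeping binomial error on recovered fractions around a
  percentage point.

## Known limitations

- The generator draws annotation axes (island relation, gene features,
  regulatory flags) independently except for island placement at promoters;
  real manifests correlate these strongly.
- No covariate adjustment (sex, gestational age), no cell-composition
  correction, no IDAT-level processing: matrices are the entry point, and
  the design-bias adjustment is a simplified within-array quantile map, not
  the published subset-quantile (SWAN) algorithm.
- Pair dynamics scale only the non-shared component; if real drift had a
  shared-environment component, the MZ/DZ contrast implied here would
  change.
- Ontology analysis itself is out of scope; the package exports ranked
  lists and gene sets in the dialect the external tools expect.
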