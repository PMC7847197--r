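---
title: "Assessing metal-contamination impacts in streams: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing metal-contamination impacts in streams: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamimpact)
```

## The assessment problem

Rivers downstream of active or legacy mines carry mixtures of dissolved
trace metals. Whether that contamination harms the resident biota is a
field question: laboratory toxicity tests on surrogate species miss dietary
exposure, sensitive life stages, and species interactions, so bioassessment
compares biological metrics measured at contaminated sites with the same
metrics at reference sites of similar character. `streamimpact` implements
one complete, reproducible version of that workflow for a paired design:
each contaminated site is matched to a reference site at a similar
elevation in a nearby uncontaminated channel, with replicate sampling
within every site (stones for benthic macroinvertebrates, sampling areas
for fish, water replicates for chemistry).

## Exposure: hardness-adjusted criteria and the CCU

Toxicity of Cu, Zn, Cd, and Pb to freshwater life decreases with water
hardness. The U.S. EPA chronic criteria are therefore hardness equations,

$$c_i(H) = \exp\{m_A \ln H + b_A\} \cdot \mathrm{CF},$$

with the conversion factor CF from total to dissolved metal constant for Cu
and Zn and itself a linear function of $\ln H$ for Cd and Pb. The package
embeds the 2006 national-recommended-criteria constants
(`wqc_constants()`); users can substitute updated tables. Contamination by
the metal mixture is summarized by the cumulative criterion unit,

$$\mathrm{CCU} = \sum_i m_i / c_i,$$

the sum over metals of the measured dissolved concentration divided by its
chronic criterion. CCU > 1 flags potential risk from the measured metals
alone.

Numerical choices:

* **Criterion precision.** `criterion_set(rounded = TRUE)` (the default)
  rounds each criterion to its conventional reporting precision (1 decimal
  for Cu and Zn, 2 for Cd and Pb) before the ratios are formed. This is how
  published CCU tables are computed and is required to reproduce them from
  printed concentrations; `rounded = FALSE` keeps full precision (the
  difference is at most a few percent of the CCU). Recomputing the bundled
  survey table from its printed, rounded concentrations reproduces the
  printed CCUs at six of nine sites; at the remaining three (the published
  values evidently used unrounded measurements) the recomputation differs
  by 0.1 in the first decimal, which we document rather than force.
* **Censoring.** Concentrations below the limit of quantification are
  substituted before ratios are formed. The default policy is zero
  substitution — the most conservative downward choice, and the one that
  reproduces the published reference-site CCUs; `half_loq` and `loq` are
  selectable and give identical rounded results for the bundled table.
* **Replicates.** Replicate water samples (3 per site in the reference
  design) are substituted, then averaged per metal before the CCU, matching
  the one-value-per-site convention of published tables.
* **Soft water.** The criteria equations were calibrated with toxicity data
  at hardness ≥ 20 mg/L. The studied river sits near 10 mg/L, so
  `criterion_set()` computes anyway but warns; the warning is recorded in
  pipeline logs rather than silenced.

## Biological metrics

**Macroinvertebrates.** From stone-level counts the package computes eight
community metrics — total abundance and richness plus the abundance and
richness of Ephemeroptera, Trichoptera, and Diptera — and the per-stone
abundance of *dominant families*: families exceeding 5% of a stone's total
abundance on at least one stone and collected on strictly more than
`ceiling(0.30 * n_stones)` stones pooled across sites (at 45 stones, more
than 14). Two readings of the share clause are possible; we adopt "on at
least one stone" (`share_rule = "any_stone"`) because the literal
every-stone reading would contradict the separate occupancy clause, and we
expose the alternative as a switch. Mayfly metrics and heptageniid mayflies
in particular are the classic metal-sensitive indicators; chironomids are
comparatively tolerant.

Abundances are log10(x + 1)-transformed *per replicate* before any
averaging; richness stays on the raw count scale. Site means carry standard
errors `sd/sqrt(n)` over the (default five) stones.

**Fishes.** Capture records give per-area counts (standardized to a nominal
50 m² sampling area) treated like stone counts, and a Fulton-type condition
factor per individual fish,

$$\mathrm{CF} = 1000 \cdot W / L^3$$

(weight in g, fork length in cm), which is pooled within sites rather than
averaged per area — individual fish are the replicate for condition.
Species with trivially few captures (≤ 5 across the whole survey by
default) are excluded. Where hatchery fish are stocked, otolith-mark
subsamples (20–27 fish per site) estimate the hatchery proportion;
`wild_adjusted_counts()` scales every area count by one minus the site's
proportion — fish outside the subsample are apportioned at the subsample
rate, the simplest estimator consistent with the data — so the abundance
analysis can be re-run for wild fish only.

## The two-gate classification

For each metric, `assess_impacts()` asks two questions of every
contaminated site:

1. **Range gate.** Is the site mean outside the *reference range*, the 90%
   prediction interval for a new reference-site mean from an intercept-only
   model fitted to the reference-site means:
   $\bar{x} \pm t_{1-\alpha/2,\,n-1}\, s \sqrt{1 + 1/n}$ with
   $\alpha = 0.10$?
2. **Test gate.** Is the site significantly different from its paired
   reference site? A one-way fixed-effects ANOVA over all sites pools the
   within-site variance; each pairing contrast gets a t statistic, and
   familywise error over the five contrasts is controlled single-step: the
   adjusted p of contrast $i$ is $1 - P(\max_j |T_j| \le |t_i|)$ under the
   joint central multivariate t with the contrast correlation matrix and
   the residual degrees of freedom. Significance uses $\alpha = 0.05$,
   two-sided throughout.

Both gates firing is an **adverse effect**; exactly one is **some effect of
concern**; neither is **no effect of concern**. The conjunction makes
"adverse" strictly rarer than either gate alone, which is the point: a
single noisy gate should not drive a strong conclusion.

Design choices behind the engine:

* **One pooled ANOVA, not five two-sample tests.** The single-step
  adjustment is defined on the joint distribution of all contrasts, which
  presumes a common error variance; we fit all nine sites in one model.
  A per-pair Welch comparison can be obtained by calling
  `paired_contrasts()` on site pairs for sensitivity analysis.
* **Integration.** The multivariate-t probability is evaluated by
  Genz–Bretz quasi-random integration (`mvtnorm::pmvt`) under a fixed
  internal seed (20180626) at absolute tolerance 1e-4, so adjusted p-values
  are reproducible to that tolerance; the adjusted p is floored at the raw
  p. A 10^6-draw Monte-Carlo oracle agrees to within 2×10⁻³ in the test
  suite.
* **Degenerate inputs.** Zero pooled variance flags the contrasts
  degenerate (p `NA`, gate not triggered). A reference range needs at least
  two reference-site means; for abundance metrics the species must also be
  *present* (positive mean) at ≥ 2 reference sites — a species caught at a
  single reference site gets no range, the range gate is skipped and
  flagged, and the label can then never be "adverse".
* **Percent differences** for abundances are reported on back-transformed
  means ($10^{\bar{y}} - 1$) relative to the paired reference site; the raw
  analysis-scale alternative is a switch (`percent_scale`), since either
  convention appears in the literature.

## What the synthetic generator emulates

`scenario_config()` fixes the study conditions: 9 sites (5 contaminated,
4 reference, paired by elevation, with the two most upstream contaminated
sites sharing one reference), 5 stones, 5 fish areas, and 3 water
replicates per site. Its defaults were chosen once, as follows:

* **Contamination profile.** Per-site CCUs follow the observed survey
  (8.4, 9.4, 6.8, 3.8, 0.9 downstream along the contaminated channel;
  2.1, 0.1, 0.3, 0.3 at the references — the elevated first reference value
  reflects a real, unexplained Zn anomaly at that site). Water means mirror
  the measured table, with censored cells placed at LOQ/2 and replicate
  noise lognormal with cv 5% (the observed replicate RSD was ~2%).
* **Benthos.** Counts are negative binomial (dispersion `size = 5`,
  overdispersion typical of stone samples) over a 14-taxon pool spanning
  the three insect orders plus non-target taxa, baseline ≈ 160
  individuals/stone. Expected counts decline with contamination as
  $\mu = \mathrm{baseline} \cdot e^{-s \beta \cdot \mathrm{CCU}}$, with
  per-taxon sensitivity $s$ highest for heptageniid mayflies and lowest for
  chironomids. The default $\beta = \ln(10)/9$ makes a fully sensitive
  taxon decline 90% at CCU 9 — the contamination level of the two most
  upstream sites, where reductions of that order were observed; $\beta = 0$
  is the exact null (counts provably independent of the profile). The
  exponential-decline model is deliberately simple and monotone; it is a
  simulation device, not a claim about real dose–response shape.
* **Fish.** Poisson catches (masu salmon the dominant species), lognormal
  fork lengths, allometric weights $W = aL^3 e^\varepsilon$ so condition
  factor concentrates at $1000a$; fish sensitivities default to 0 because
  no fish effects were observed in the motivating survey. Hatchery
  proportions default to the observed per-site values.

The generator does **not** emulate spatial autocorrelation among stones,
temporal dynamics, taxon co-occurrence structure, species' distributional
quirks (e.g. lamprey absence from particular reaches), or
community assembly. Passing operating-characteristic tests therefore shows
the *procedure* behaves correctly under its own assumptions — correct null
error rates and high power against strong effects — not that real
communities satisfy those assumptions.

## Operating characteristics and problem sizes

The test suite verifies, at sizes chosen to balance Monte-Carlo error
against runtime:

* adjusted p against a 10^6-draw max-|t| oracle (absolute 2×10⁻³) and the
  `multcomp` single-step implementation (2×10⁻³), with the single-contrast
  case equal to the pooled t-test p to 10⁻⁶;
* 90% prediction-interval coverage on 10^5 simulated reference draws
  (±1%);
* null scenario ($\beta = 0$), 1000 simulated surveys: per-metric
  "adverse" rate ≤ 0.05 across the eight community metrics, and strictly
  below each single gate's rate;
* effect scenario (default $\beta$), 200 simulated surveys: heptageniid
  abundance flagged (adverse or some concern) at the two most contaminated
  sites in ≥ 90% of cases.

## Limitations

* The classification is operational, not causal: a flagged metric says the
  site differs from reference expectations, not why. Confounders (habitat
  differences, biotic interactions such as net-spinning caddisfly
  colonization at individual reference sites) require separate lines of
  evidence.
* Reference ranges from four reference sites are wide and their coverage
  is exact only under normality of site means; with so few reference sites
  the range gate is the blunter of the two.
* CCU treats metal toxicities as additive and ignores water-chemistry
  modifiers other than hardness (pH, DOC); at hardness near 10 mg/L the
  criteria are extrapolated below their calibration range and carry a
  standing caution.
* Single-occasion grab samples stand in for time-integrated exposure;
  interpreting CCU as an annual mean needs corroborating measurements.

## Re-analysing a real survey

All inputs are plain CSV in documented dialects (`read_water_samples()`,
`read_counts()`, `read_taxonomy()`, `read_fish_captures()`,
`read_otolith()`, `read_site_design()`); `run_pipeline()` accepts file
paths directly, so a field dataset exported in these shapes — for instance
a published survey's supplementary data table — can be classified without
touching package code:

```{r, eval = FALSE}
res <- run_pipeline(out_dir = "results",
                    water = "water.csv", counts = "counts.csv",
                    taxonomy = "taxonomy.csv", captures = "fish.csv",
                    otolith = "otolith.csv", design = "design.csv")
summary(res$assessment)
```
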