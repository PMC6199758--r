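---
title: "Relating the MSC secretome to post-irradiation survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating the MSC secretome to post-irradiation survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretopls)
```

## The problem

Mesenchymal stromal cells (MSCs) support hematopoietic recovery after
irradiation largely through the proteins they secrete. Different MSC
preparations — different passages, biophysically sorted subpopulations,
cells mechanoprimed on substrata of different stiffness — secrete
different concentrations of dozens of cytokines and growth factors, and
cohorts of irradiated animals treated with those preparations survive at
different rates. `secretopls` implements the computational path from a
multiplex secretome panel (preparations x analytes, pg/mL) and the paired
survival curves (preparations x timepoints) to:

1. a per-timepoint **Pearson correlation screen** flagging analytes whose
   expression tracks survival;
2. a two-component multivariate-response **partial least squares
   regression (PLSR)** whose loading geometry identifies
   survival-correlated analytes and whose coefficient matrix predicts
   survival curves for new preparations;
3. a **Spearman rank screen** of expression against culture-substratum
   stiffness under Bonferroni correction (the mechanopriming axis); and
4. the **validation statistics** used on subject-level animal data:
   Kaplan-Meier curves, median survival, the Mantel-Cox log-rank test,
   Mantel-Haenszel hazard ratios, one-tailed Welch t tests and
   family-wise p adjustment.

Because panels of this kind are rarely deposited, the package ships a
seeded synthetic-data generator that emulates the assumed data structure,
so that every stage is testable end to end.

## Preprocessing conventions

Multiplex immunoassays are read in technical replicate;
`collapse_technical_replicates()` uses the arithmetic mean as the
representative concentration per (preparation, analyte).
`normalize_by_cell_count()` multiplies each preparation's row by a
positive cell-number factor, since conditioned-media concentrations scale
with the number of secreting cells. `apply_lod_policy()` handles readouts
below an assay's limit of detection (LOD): the default drops an analyte
only when *every* sample is below its LOD — the situation in which a
panel analyte is simply undetectable in the system — rather than imputing
values; an explicit `substitute_half_lod` policy (below-LOD cells set to
LOD/2) is available where partial censoring must be retained. Every step
is logged in table attributes.

CSV input/output uses a single dialect (UTF-8, comma, `.` decimal,
header row). Writers emit the shortest decimal representation that
round-trips a double exactly and readers parse with correctly rounded
conversion, so `write(read(f))` is a byte-level fixed point — a cheap,
strong guarantee for provenance auditing. Survival rows must be
non-increasing within `1e-9`: product-limit proportions are exactly
non-increasing, so any real violation signals corrupt input.

## The Pearson timepoint screen

For analyte $j$ and timepoint $t$, the screen computes the sample Pearson
coefficient $\rho_{jt}$ across preparations between concentration and
survival proportion, with the two-sided p-value from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. A cell
*hits* when $|\rho_{jt}| > \rho^\* $ and $p < \alpha$ (defaults
$\rho^\* = 0.875$, $\alpha = 0.05$). Timepoints at which survival does
not vary across preparations (typically the early days when every cohort
is still at 1.0) are **non-evaluable**: Pearson correlation is undefined
there, and assigning $\rho = 0$ instead would dilute the aggregate.
Analytes with zero variance are likewise non-evaluable.

An analyte is an **aggregate hit** when the joint criterion holds at a
chosen fraction of evaluable timepoints. "Over the whole experiment" is
genuinely ambiguous between *all*, *any* and intermediate rules; the
default is the **majority** (at least 50%) of evaluable timepoints, since
*all* is fragile to a single noisy timepoint and *any* inflates hits.
Both alternatives and arbitrary fractions are exposed.

Two design facts matter for interpreting this screen at small $n$:

* With five preparations, the two-sided critical $|\rho|$ at
  $\alpha = 0.05$ is $\approx 0.878$ (3 df), so the joint criterion
  behaves as a single constraint; both thresholds are still applied
  literally.
* For a potency-independent analyte, the per-timepoint joint criterion is
  by construction a $\approx 5\%$ event, and because one noise draw of
  the analyte's five concentrations drives *all* timepoints
  simultaneously (survival columns are highly correlated), aggregation
  cannot push the per-analyte false-hit rate below that floor. With
  ~27 null analytes the probability of a screen with zero false hits is
  only about $0.95^{27} \approx 0.25$, whatever the assay noise
  magnitude. Exact recovery of a planted analyte set is therefore only a
  sharp test in the noise-free limit, where potency-independent analytes
  are constant and hence non-evaluable; the test suite exercises exactly
  that regime, and users should read positive-noise screens as candidate
  lists containing roughly one chance analyte per run, not as exact sets.

## The PLSR model

Both blocks are column-standardized to mean 0 and sample standard
deviation 1 (`n-1` denominator), which stops high-abundance analytes from
dominating purely by scale; zero-variance columns map to zeros and are
flagged. On the standardized blocks $X_s$ ($n \times p$) and $Y_s$
($n \times q$), `fit_plsr()` runs **SIMPLS** — the deterministic
algorithm used by the standard commercial statistics toolbox for PLSR —
extracting, per component, the weight vector maximizing covariance with
the response block from the deflated cross-covariance matrix
$S = X_s^\top Y_s$, with orthonormal scores. Two components are the
default: in data of this shape they typically capture well over 90% of
both blocks' variance (`variance_explained()` reports per-component and
cumulative fractions; scores are orthonormal, so contributions are
additive and cumulative fractions are bounded by 1).

The fitted object exposes an intercept-augmented coefficient matrix of
shape $(p+1) \times q$, intercept row first. On the standardized scale
the intercept row is exactly zero (both blocks are centred);
`coef(fit, scale = "original")` folds the standardizers in, giving
coefficients that map raw pg/mL concentrations to survival proportions.
`predict()` standardizes new expression with the *training*
standardizer, applies the coefficients and inverts the response
standardizer. Predictions are clipped to $[0,1]$ by default (they are
proportions); an optional monotone post-processing replaces each curve
with its best non-increasing least-squares approximation
(pool-adjacent-violators). Timepoints constant in training (day 0 at 1.0)
are predicted as that constant. Post-processing is recorded in an
attribute.

Component signs are fixed by making the largest-magnitude entry of each
X-weight vector positive, so loading maps and rankings are reproducible
across runs. If the cross-covariance is exhausted before the requested
number of components (low-rank data — e.g. the noise-free synthetic
cohort, whose informative block has rank 1), the remaining components are
returned as all-zero with a warning rather than amplifying numerical
noise.

### Biomarker identification

`loading_map()` returns the first two loading coordinates of every
analyte and every timepoint; variables that load in the same direction
are correlated. `rank_biomarkers()` scores each analyte by the **maximum
cosine similarity** between its 2-D loading vector and any timepoint
loading vector. Cosine (angle) rather than Euclidean distance is the
default because loading magnitude conflates a variable's variance with
its direction; a Euclidean option exists for sensitivity analysis. Ties
are broken by analyte name; degenerate (zero-loading) analytes are
excluded with a warning. Analytes whose similarity to every timepoint is
negative are flagged as anti-correlated and reported separately.

`consensus_biomarkers()` intersects the Pearson aggregate hits with the
top-$k$ proximity ranking; since no published proximity cutoff exists,
$k$ defaults to the Pearson hit-list size, making the consensus a
two-route confirmation of the same candidate pool.

## The stiffness screen

`screen_stiffness_correlation()` pools all wells per analyte and computes
the Spearman rank correlation between concentration and substratum
stiffness, with significance from the t approximation on $n-2$ df and a
Bonferroni-corrected threshold $\alpha/m$ across the $m$ analytes tested
(for a 45-plex panel, $0.05/45 \approx 0.0011$). Because stiffness enters
as ranks, any monotone coding of the levels (kPa, log-kPa, level index)
gives identical results.

A documented limitation: the t approximation is asymptotic, and with few
wells and heavily tied stiffness ranks its extreme tail is optimistic —
at 3 wells per level the family-wise error of the corrected screen is
roughly 0.11 rather than 0.05, and only at around 10 wells per level does
it fall to the nominal rate. The type-I calibration in the test suite
therefore runs at 10 wells per level (45 analytes, 200 screens); results
from very small tied designs should be treated as exploratory.

## Survival statistics

Kaplan-Meier estimation, the log-rank test and Welch t tests are
delegated to the standard `survival` and `stats` machinery behind tidy
wrappers that fix the conventions: tied deaths pooled into one stratum
with hypergeometric variance; censorings at a death time leave the risk
set after deaths are counted; the median is the *first* time the estimate
reaches 0.5 or below, "undefined" (`NA`) when never reached within
follow-up. The Mantel-Haenszel hazard ratio is
$\exp\{(O_A - E_A)/V\}$ with CI $\exp\{(O_A-E_A)/V \pm z/\sqrt{V}\}$; the
reference group is the second argument. An $O/E$-ratio variant is
selectable.

The $(O-E)/V$ form is a first-order approximation to the log hazard
ratio, accurate near 1 and progressively biased away from the null for
large ratios under heavy event pressure: in simulations at a true ratio
of 4.4 it averages ~5.2 when ~90% of subjects die, but ~4.7 when roughly
two-thirds die. The estimator-recovery test fixes the latter design
(rates 0.044 and 0.01 per day, 500 subjects per group, administrative
censoring at day 50) — a regime where most subjects die, events are
plentiful, and the approximation is within its documented accuracy.
Multiplicity for blood-count/weight panels defaults to Holm (uniformly
more powerful than Bonferroni at the same family-wise error), with
Bonferroni available.

## The synthetic generator

`simulate_cohort()` draws a latent potency score $\theta_g$ per
preparation, equally spaced on $[0,1]$ by default so that even a
five-preparation design spans the potency range (a flag randomizes it).
Informative analytes follow $a_j + b_j\theta_g + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$ truncated at zero; intercepts are drawn
on 50–500 pg/mL and informative slopes on 100–400 pg/mL per unit potency,
with a default assay noise of $\sigma = 10$ pg/mL — a few percent of the
dynamic range, typical of multiplex panels. Non-informative analytes are
potency-independent noise around their intercepts. Survival follows
proportional hazards, $S_g(t) = \exp\{-e^{-\beta\theta_g}\Lambda(t)\}$,
with $\beta = 3$ and a piecewise-linear baseline cumulative hazard that
is flat for the first 8 days (the lag phase of radiation injury) and
rises at 0.0381/day thereafter, putting the weakest preparation near 20%
and the strongest near 92% survival at day 50 — the spread observed
between untreated and best-treated cohorts in this injury model. By
construction, curves are valid (in $[0,1]$, non-increasing, $S(0)=1$) and
group ordering by potency equals ordering by survival at every timepoint
with accrued hazard.

`simulate_rank2_cohort()` is a diagnostic variant driven by exactly two
latent factors, with both blocks affine in them and survival rows built
from non-increasing basis curves: the centred blocks have rank two, so a
two-component fit must reproduce the response exactly and the
observed-vs-fitted parity slope must be 1 — a sharp correctness check for
the regression code. `simulate_events()` draws exponential death times
per group with administrative censoring (default day 50, cohorts of ~9+
as in small-animal studies); `simulate_stiffness()` generates per-well
concentrations with a linear trend in $-\log_{10}(\text{stiffness})$, so
positive slopes mean expression rises as the substratum softens. All
generators are deterministic given their integer seed.

What the generators do *not* emulate: between-animal heterogeneity within
a cohort's survival curve (curves are the model law, not Kaplan-Meier
realizations), correlated analytes, heteroscedastic assay noise,
plate/batch effects, and partially-below-LOD censoring. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the *computations*, not the biological validity of any particular panel.

## Problem sizes used by the test suite

The suite verifies the regression against independent oracles on 50
randomized univariate-response problems (where SIMPLS coincides exactly
with the NIPALS implementation in `mixOmics`) plus multivariate problems
at full rank (where any PLSR equals the least-squares fit); planted-set
recovery over 50 noise-free cohorts; log-rank size over 1000 null
simulations at 50 subjects per group; hazard-ratio recovery over 20
simulations at 500 per group; and stiffness-screen family-wise error over
200 all-null screens. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping the default run fast.

## Known limitations

* With five preparations the Pearson screen cannot certify exact analyte
  sets at any positive noise (the 5% per-analyte floor above); it ranks
  candidates.
* The loading-proximity ranking uses the 2-D component space only; if
  meaningful structure lives in later components the ranking will not see
  it.
* The Mantel-Haenszel $(O-E)/V$ hazard ratio is an approximation; for
  large true ratios under near-complete mortality it overestimates, and a
  partial-likelihood (Cox) estimate should be preferred when subject-level
  modelling is acceptable.
* The Spearman t approximation is optimistic in the far tail for tiny,
  heavily tied designs; exact permutation nulls are the alternative when
  well counts are very small.
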