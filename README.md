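# secretopls

Mesenchymal stromal cells (MSCs) aid recovery from radiation-induced
hematopoietic failure mainly through the cytokines and growth factors
they secrete. Which secreted proteins track that therapeutic potency, and
can a preparation's secretome predict how well treated animals will
survive? `secretopls` implements the statistical pipeline for this
question, for researchers running MSC potency or mechanopriming studies:

* **Preprocessing** of multiplex immunoassay panels: technical-replicate
  averaging, cell-number normalization, below-detection-limit policies,
  and validated CSV I/O for expression tables, survival-curve tables,
  subject-level event tables and stiffness–expression tables.
* **Correlation screens** — a per-timepoint Pearson screen of analyte
  concentration against survival proportion with a joint criterion
  (|ρ| > 0.875 and p < 0.05, aggregated across evaluable timepoints),
  and a Bonferroni-corrected Spearman rank screen of expression against
  culture-substratum stiffness.
* **Two-component multivariate-response PLSR (SIMPLS)**, written from
  scratch: both blocks z-scored column-wise, an intercept-augmented
  (p+1) × q coefficient matrix, per-component variance accounting, 2-D
  loading maps, loading-proximity biomarker ranking, and survival-curve
  prediction for new expression data (clipped to [0, 1], optional
  monotone projection).
* **Survival statistics** for in vivo validation: Kaplan–Meier curves,
  median survival, Mantel–Cox log-rank, Mantel–Haenszel hazard ratio
  exp((O−E)/V) with CI, one-tailed Welch t tests, Holm/Bonferroni
  adjustment.
* A **seeded synthetic-data generator**: a latent potency score θ links
  analyte concentrations (a + bθ + ε) to proportional-hazards survival
  curves S(t) = exp(−e^{−βθ} Λ(t)), plus exponential event tables and
  stiffness panels, so the whole pipeline is testable without access to
  proprietary assay data.

The model at the core: given standardized expression X (n preparations ×
p analytes) and survival Y (n × q timepoints), SIMPLS extracts latent
components t_a = X r_a maximizing covariance with Y, yielding B = R Qᵀ
such that Ŷ = [1 | X_std] B_aug, de-standardized back to survival
proportions. Analytes whose loading vectors point with the timepoint
loadings (maximum cosine similarity) are the survival-correlated
biomarkers; intersecting them with the Pearson hits gives the consensus
set.

## Worked example

```r
library(secretopls)

sim <- simulate_cohort(seed = 1)      # 5 preparations x 35 analytes, 8 potency-linked
scr <- screen_survival_correlation(sim$expression, sim$survival)
scr
#> Survival correlation screen: |rho| > 0.875 and p < 0.05, aggregation 'majority'
#> 9/35 analytes hit: A01, A04, A11, A14, A18, A19, A23, A27, A32

fit <- fit_plsr(sim$expression, sim$survival, ncomp = 2)
fit
#> SIMPLS fit: 5 groups, 35 analytes -> 21 timepoints, 2 component(s)
#> variance captured: 60.3% of expression, 99.7% of survival

pred <- predict(fit, sim$expression)
parity_slope(sim$survival, pred)
#> [1] 0.9991849

hits <- screen_hits(scr)
rb <- rank_biomarkers(fit, top_k = length(hits))
consensus_biomarkers(hits, rb$analyte)
#> [1] "A01" "A11" "A14" "A19" "A23"
```

The screen recovers nine candidates (eight planted potency-linked
analytes plus one chance correlate — with five preparations the joint
criterion admits ~5% of null analytes per run); the two-component fit
captures 99.7% of the survival block's variance, the fitted curves sit on
the parity line (slope ≈ 1), and the consensus of the two routes is a
high-confidence subset. Validation statistics work on subject-level
event tables:

```r
ev <- simulate_events(c(strong = 0.01, weak = 0.044), n_per_group = 12, seed = 2)
logrank_test(ev, "weak", "strong")
#> statistic 8.14, p.value 0.00433, observed_a 11, expected_a 5.78, variance 3.34
hazard_ratio(ev, "weak", "strong")
#> hr 4.76, conf.low 1.63, conf.high 13.9, method mantel-haenszel
median_survival(ev)
#> strong: NA (undefined, never reaches 0.5); weak: 18.1 days
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages and
writes every intermediate table plus a JSON report;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

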