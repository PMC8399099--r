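# survscreen

Genome-wide discovery of prognostic expression biomarkers by
optimal-cutpoint survival screening, with multiple-testing correction,
Cox effect-size gating against clinical confounders, and two-cohort
consensus validation — plus a synthetic-cohort generator with known truth
so the whole procedure can be characterized without external data.

**Who it is for**: biostatisticians and computational biologists screening
a bulk expression matrix (genes × patients, log2 scale) against
overall-survival follow-up for genes whose dichotomized expression
separates survival, while controlling the substantial selection optimism
that minimum-p cutpoint selection introduces.

## The method

For each gene, patients are ranked by expression and a serial cut is slid
across the 30th–70th percentile band (ranks ⌊0.3N⌋+1 … ⌈0.7N⌉; for
N = 414, ranks 125–290, 166 cuts). At each admissible cut k the cohort
splits into low (ranks 1..k) and high groups and a two-group log-rank
statistic is evaluated; the minimum-p cut is the gene's **optimal
cutpoint** (median-rank fallback when no cut reaches p < 0.05). Cuts
splitting tied values, or leaving a group with no events, are skipped and
fully degenerate genes are excluded with an error category rather than
halting the screen.

Per-gene minimum p values are adjusted across genes by Benjamini–Hochberg
FDR and by Bonferroni. Effect sizes come from Cox proportional-hazards
models

    h(t) = h0(t) · exp(β1·X1 + … + βn·Xn)

fitted univariately (gene indicator alone) and multivariately (gene plus
eight dichotomized clinical confounders: gender, age > 65, T3–T4, N+, M1,
stage III–IV, positive surgical margin, high tobacco exposure), with Efron
tie handling and Wald 95% CIs. A **candidate** needs adjusted p < 0.05 and
HR ≥ 1.8 (or ≤ 0.6) in *both* models, same side. A **consensus candidate**
additionally passes an independent validation cohort screened at fixed
median cutpoints with FDR correction, with the same effect direction.

Because the minimum over ~166 correlated log-rank tests is optimistically
biased, the raw per-gene p values are inflated several-fold under the
null; the pipeline treats Bonferroni gating, effect-size gating and
cross-cohort consensus as the guards against this, and ships experiments
quantifying it (see the methods vignette).

## Worked example

The `analysis/` scripts run the full workflow on paired synthetic
cohorts (400 patients each; 300 null genes plus three planted threshold
effects: HR 0.4 at the 35th expression percentile, HR 2.5 at the 50th and
65th):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_discovery_screen.R
Rscript analysis/03_validation_consensus.R
Rscript analysis/04_cutpoint_inflation.R
```

Step 2 screens the discovery cohort and prints:

```
Discovery run (bonferroni gating): 303 genes scanned, 4 candidates
     gene        raw_p        fdr_p bonferroni_p    uni_hr  multi_hr  direction
    SIG02 1.914863e-10 5.802034e-08 5.802034e-08 2.5468192 2.7243976    harmful
    SIG03 8.368445e-07 1.124216e-04 2.535639e-04 1.9812980 1.9943016    harmful
    SIG01 1.113085e-06 1.124216e-04 3.372648e-04 0.5025422 0.4842036 protective
 NULL0225 9.357447e-05 7.088266e-03 2.835306e-02 0.5729856 0.5794795 protective

Scanned 303 genes (0 failures). Raw p < 0.05 at the optimal cut: 81 genes.
```

(the fourth candidate, a null gene, slipped through this cohort's
Bonferroni + HR gates). Step 3 validates at median cutpoints in the second cohort and
intersects:

```
     gene  direction validation_status validation_uni_hr validation_multi_hr
    SIG02    harmful         validated         1.9636375           1.9267387
    SIG03    harmful         validated         1.9045523           1.8748414
    SIG01 protective         validated         0.4255437           0.4044409
 NULL0225 protective   not-significant         1.2359675           1.2305076

Consensus: SIG02, SIG03, SIG01
HR concordance across cohorts (Pearson r, 4 genes): 0.87
```

The consensus list is exactly the planted truth: the spurious discovery
candidate fails validation, and all three planted genes replicate with the
correct direction. Step 4 characterizes the procedure (this seed):
optimal-cut screening calls 26.4% of null genes significant at raw
p < 0.05 versus 4.2% for median cuts; the selected cut sits a median of
1 percentile point from a planted threshold; the covariate-adjusted Cox CI
at the true split covers the planted HR in 94.5% of replicates. Note that
off-median planted effects frequently fail the 1.8/0.6 hazard-ratio gate
under *median-cut* validation (their median-split HR is structurally
attenuated), so recovering all three planted genes simultaneously is the
exception, not the rule — the methods vignette quantifies this.

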