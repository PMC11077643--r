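# gradientsig

Tools for deriving a **ferroptosis-versus-apoptosis gradient gene
signature** from dose-gradient transcriptomics and applying it to classify
perturbation datasets and stratify patient cohorts.

## The scientific problem

Ferroptosis and apoptosis are distinct regulated cell-death programs, but
their transcriptomic responses overlap heavily in a generic drug-stress
component, which makes naive "ferroptosis signatures" poor classifiers.
When a drug combination is dosed along a gradient that programs cells from
a ferroptotic state (`JB2`) through an intermediate (`JB3`) into an
apoptotic one (`JB6`), the informative genes are those that respond
*differentially* between the gradient's extremes. `gradientsig` is for
computational biologists who want to:

* derive the **Gradient Gene Set (GGS)** — four disjoint subsets defined by
  exclusive FDR significance in one extreme treatment (`q < α` in JB2 vs
  control, `q ≥ α` in JB6 vs control, or vice versa) plus a significant
  JB2-vs-JB6 difference with concordant sign;
* optimize **compact biomarker panels**: the *gradient-derived* genes
  (JB2-vs-JB6 effect significantly negative at 6 h, significantly positive
  at 24 h) and the *datasets-derived* genes (bootstrapped-aggregation
  Welch-t ranking of ferroptosis-inducer vs apoptosis-inducer fold-change
  profiles);
* score profiles by **ssGSEA** (weighted running sum over a ranked
  profile: `score = Σ_i [P_in(i) − P_out(i)] / N` with rank weights
  `r^0.25`), classify FIN vs AIN by leave-one-out kNN and ROC-AUC;
* stratify cohorts: per-patient ssGSEA, two-group k-means (k-means++
  seeding), Kaplan–Meier, log-rank, Cox proportional hazards
  (`HR = exp(β)`), and Pearson correlation with ordinal therapy response
  (CR < PR < SD < PD).

Differential expression uses an empirical-Bayes **moderated t**
(`t = lfc / (s̃ √(1/n₁+1/n₂))`, gene variances shrunk toward a
method-of-moments prior) with Benjamini–Hochberg q-values. A
**synthetic-data generator** plants shared, ferroptosis-specific,
apoptosis-specific and time-reversing ("flip") gene modules in
negative-binomial counts, labelled FIN/AIN fold-change collections, and
survival cohorts driven by a latent signature activity — so every stage is
testable against ground truth.

## Worked example

```r
library(gradientsig)

cfg  <- sim_config(seed = 7)                       # default study conditions
sim  <- simulate_dose_experiment(cfg)
de24 <- dose_contrasts(sim$counts, sim$samples, 24)
ggs  <- build_ggs(de24[["JB2-vs-DMSO"]], de24[["JB6-vs-DMSO"]],
                  de24[["JB2-vs-JB6"]])
ggs
#> Gradient Gene Set: 325 genes
#>   jb2_up : 171
#>   jb2_down : 4
#>   jb6_up : 148
#>   jb6_down : 2

coll <- simulate_perturbation_collection(cfg, sim$truth, seed = 7)
evaluate_signature(coll, ggs$jb2_up)
#> FIN-vs-AIN classification: 45 profiles, 171 signature genes
#>   ROC-AUC: 1  two-sample t p: 5.83e-44
#>   mean scores: FIN 0.496 / AIN -0.0781

coh   <- simulate_cohort(cfg, sim$truth, n_patients = 299, seed = 7)
strat <- stratify_cohort(coh$data, list(jb2_up = ggs$jb2_up), seed = 7)
strat$logrank
#> # A tibble: 1 × 3
#>   chisq    df        p
#>   <dbl> <dbl>    <dbl>
#> 1  72.3     1 1.86e-17
```

Reading the output: the GGS recovers the planted death-mode-specific
modules (171 of its `jb2_up` genes are dominated by the 150-gene ferro
module plus borderline shared genes); its `jb2_up` subset separates the 19
simulated ferroptosis inducers from the 26 apoptosis inducers perfectly
(AUC = 1 under the strong planted effects); and k-means clusters of the
per-patient `jb2_up` ssGSEA scores split the simulated cohort into groups
with very different survival (log-rank χ² = 72.3), as expected when the
latent activity drives a hazard ratio of 2.

Plot helpers (`plot_landscape()`, `autoplot()` on classification reports,
`plot_km()`, `plot_selection_frequency()`) return ggplot objects; fitted
objects support broom-style `tidy()` / `glance()`.

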