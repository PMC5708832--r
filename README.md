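# condsmolt

Size-conditional smolting and life-cycle models for anadromous steelhead
(*Oncorhynchus mykiss*).

Steelhead juveniles rear in fresh water, smolt, and enter the ocean, where
early survival depends strongly on body size at entry. `condsmolt` is a
retrospective analysis pipeline for long-term river monitoring programs
that asks whether adult returns are driven by juvenile *abundance* (a
fixed-rate life cycle) or by juvenile *growth* (a size-conditional life
cycle), and what density regulation and rescue translocations did to the
juvenile stage. It is aimed at fisheries biologists and quantitative
ecologists working with electrofishing survey series, dam counts and
rescue-program records.

## What it implements

* **Age structure** — October length-frequency samples decomposed into
  age classes by normal mixtures, `L ~ sum_k alpha_k N(mu_k, sigma_k)`,
  with the number of classes K selected by BIC (parameter count 3K − 1,
  variance floor 1 mm, parsimony tie-break). Smallest-mean component =
  young-of-the-year (YOY).
* **Abundance** — Zippin 3-pass and Seber–LeCren 2-pass removal
  estimators with total-catch fallback, and river-wide expansion
  `J_t = mean site YOY density × channel length`.
* **Growth** — a daily individual-based model with size-asymmetric
  competition `C(L|lambda) = exp(beta (lambda − L))`, a unimodal
  temperature response peaking at 15 °C, and a fitted food-availability
  scalar `eta_H` per site-year; fitted to October YOY mean/sd and
  projected to the 1 April smolt window (compiled core).
* **Life cycle** — fixed-rate model
  `A_t = q1 (0.53 J_{t−1} + 0.47 J_{t−2}) + q2 (0.53 C_{t−1} + 0.47 C_{t−2})`
  versus the size-conditional model with smolt-equivalent predictors
  `J*, C*` (abundance weighted by smolting probability — logistic,
  threshold 120 mm, dispersion 10 mm — times marine survival
  `min{0.35, 0.84/(1 + exp(8.657 − 0.0369 L))}`), both fitted by
  no-intercept least squares with sign-unconstrained apparent transition
  rates, compared by AICc, and decomposed into wild vs captive origin.
* **Recruitment** — the six density-regulation models (fixed production,
  proportional, logistic capacity, each ± a translocation term) ranked by
  AICc, plus sampling-bias corrections and YOY-length covariate
  regressions.
* **Model selection** — AICc from RSS, deltas, Akaike weights, evidence
  ratios, summed-weight odds.
* **Synthetic data** — a generator with full recorded ground truth
  (mixture length structure, binomial depletion passes, sinusoidal
  temperatures, adults forward-simulated from either life-cycle truth)
  for end-to-end validation; bit-identical under a fixed seed.

## Worked example

Simulate a three-site monitoring program whose adults truly follow the
size-conditional model, then run the full pipeline on the simulated
tables:

```r
library(condsmolt)

cfg <- scenario_config(sites = c("lower", "mid", "upper"), seed = 7)
scenario <- simulate_scenario(cfg)
report <- run_report(scenario,
                     report_control(em_restarts = 5,
                                    growth = growth_control(n_fish = 100,
                                                            n_starts = 3,
                                                            reltol = 1e-4)))
print(report)
```

```
Steelhead pipeline report
  54 site-year age fits, 18 years of abundance

Adult-model comparison (AICc):
              name k  n  aicc delta    weight evidence_ratio
1 size_conditional 3 16 119.8  0.00 1.000e+00      1.000e+00
2       fixed_rate 3 16 199.3 79.48 5.518e-18      1.812e+17
```

The size-conditional model is selected with an AICc gap of ~79 — the
size signal in the simulated April length distributions carries almost
all of the information about adult returns. Its fitted apparent
transition rates recover the generating truth (q3 = 1.178, q4 = 0.594):

```r
report$lifecycle$fits$size_conditional
#> size-conditional adult model (16 years, AICc = 119.80)
#>   q3 = 1.172 (SE 0.01145)
#>   q4 = 0.5825 (SE 0.01986)
```

`q3` and `q4` are *apparent* rates: products of true vital rates with the
fixed sampling biases of the monitoring series. `bias_correct()` exposes
the spatial-evenness arithmetic that converts fitted recruitment
parameters to bias-corrected ones, e.g.

```r
bias_correct(c(r = 272.5, K = 282676, s = 1.9))$corrected
#>            r            K            s
#>     193.2624  734223.3766       0.7315
```

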