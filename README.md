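# tmsdkinetics

Sequence-dependent kinetics of toehold-mediated DNA strand displacement
(TMSD), for DNA-nanotechnology researchers who want to understand — and
predict — why two invader strands with the same 6-nt toehold length can
displace at rates differing by orders of magnitude.

In TMSD, an invader strand **I** nucleates on the single-stranded toehold of
a substrate strand **F** and displaces the incumbent **Q** by branch
migration. The package closes the loop from fluorescence traces to sequence
design:

* **Kinetics.** A standard curve converts intensity to product
  concentration; the equal-concentration second-order law
  `c(t) = c0·(k·c0·t)/(1 + k·c0·t)` is fitted for the rate constant *k*
  (M⁻¹s⁻¹); the time to 95% completion,
  `t_eq = f*/((1−f*)·k·c0)`, assigns one of three rate classes
  (< 1000 s, 1000–3600 s, > 3600 s); `ln k` vs `1/T` over 15–30 °C gives the
  Arrhenius apparent activation energy.
* **Structure.** A built-in partition function over nested Watson–Crick
  structures (per-pair penalty + SantaLucia nearest-neighbor stacking)
  yields base-pairing probabilities and MFE structures, validated against an
  exhaustive enumeration oracle; a two-state model of the toehold duplex
  gives the intermediate's bound fraction
  `θ = ((1+2Kc0) − √(1+4Kc0))/(2Kc0)`. Externally computed pair
  probabilities (ppairs files) can be imported in place of the built-in
  engine.
* **Features and prediction.** Sixteen variables X1–X16 describe free
  bases, hydrogen-bond budgets (A/T = 2, G/C = 3 bonds), ensemble energies,
  MFE structure and the intermediate; a random forest ranks their
  importance; logistic regression, an RBF SVM and a decision tree predict
  the rate class, evaluated by stratified splits, cross-validation and
  one-vs-rest ROC with micro/macro AUC. The key `z(X2) + z(X5) − z(X11)`
  orders near-identical designs fastest-first.

A first-class synthetic-data module generates whole studies (random
toeholds on a fixed branch region, planted sequence-dependent rates,
calibrated noisy traces, temperature series) so every stage is testable
without laboratory data.

## Worked example

```r
library(tmsdkinetics)
set.seed(1)

sys <- displacement_system("GCGATCTCATTCAATACCCTAC", id = "demo")
sys
#> <displacement_system demo: toehold 6 nt + branch 16 nt>
#>   invader   (I) 5'-GCGATCTCATTCAATACCCTAC-3'
#>   substrate (F) 5'-GTAGGGTATTGAATGAGATCGC-3'
#>   incumbent (Q) 5'-GTAGGGTATTGAATGA-3'

fv <- featurize_system(sys)
round(fv[c("X2", "X5", "X11", "X14")], 3)
#>     X2     X5    X11    X14
#> 12.668 44.474  4.763  0.171
```

X2 ≈ 12.7 of the toehold's 16 hydrogen-bonding sites are free at
equilibrium, X11 ≈ 4.8 bonds are consumed by intramolecular folding of the
invader, and X14 ≈ 0.17 bonds are engaged in the toehold intermediate at
50 nM. Simulate a noise-free displacement trace at this design's planted
rate and recover *k*:

```r
cfg <- synthetic_config(trace_noise_sd = 0)
k_true <- planted_log_rate(fv, synthetic_config(noise_sd_log10k = 0))
k_true
#> [1] 735400

tr <- simulate_trace(k_true, cfg, sample_id = "demo")
cal <- fit_standard_curve(c(10, 25, 50, 75, 100),
                          12 * c(10, 25, 50, 75, 100) + 50)
fit_rate_constant(trace_to_concentration(tr, cal, background = 100),
                  tr$times, cfg$c0)
#> <rate_fit: k = 7.354e+05 M^-1 s^-1, t_eq = 516.7 s, class 0>
```

The fitted rate matches the planted one and the design lands in the fast
class (t_eq < 1000 s). The design-rule report confirms why:

```r
design_rule_report(sys, fv)
#> <design_rule_report demo: all rules pass>
#>   [ok] toehold_length: toehold length 6 vs configured maximum 6
#>   [ok] gc_proportion: toehold G/C proportion 0.67 (threshold 0.50)
#>   [ok] toehold_occlusion: 0 toehold base(s) paired in the MFE structure (max 2)
```

`run_pipeline(pipeline_config(...))` chains all stages (simulate or load →
fit kinetics → featurize → train/evaluate → rank) and writes CSV/JSON
artifacts plus a reproducibility manifest;
`inst/scripts/tmsd_pipeline.R` is a command-line wrapper.

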