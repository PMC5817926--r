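# foldclamp

Simulation and analysis of single-molecule force-clamp refolding
experiments on polyproteins in the presence of Hsp40/Hsp70 chaperones
(DnaJ, DnaK), for biophysicists who quantify chaperone–substrate binding
from mechanical folding assays.

## The model

A substrate domain under piecewise-constant force occupies one of five
states — folded (F), extended free/bound (E, EB), collapsed free/bound
(C, CB) — with regime-switched kinetics:

* force pulse: F →(k_u)→ E, C →(k_uc)→ E (and CB → EB),
  E ⇌ EB with k_on·c / k_off;
* quench (~0 pN): E →(k_c)→ C, C →(k_f0)→ F, chaperone exchange on both
  free non-native states.

Bound domains cannot fold, so refolding yield — the ratio of test-pulse to
initial-pulse unfolding steps — reads out binding. The linear master
equation is solved exactly per segment (matrix exponentials); an exact
Gillespie twin generates noisy staircase traces and refolding-count
datasets. On top of that the package provides:

* change-point step detection (penalized L2 binary segmentation with
  multi-step merging) and P(u) unfolding-kinetics fitting;
* pooled refolding yields with the five-step and equal-extension quality
  filters and 500-replicate bootstrap SEMs;
* χ² fitting of k_on/k_off (hence K_d = k_off/k_on) per
  chaperone–conformation pair across quench-time, extended-hold and force
  sweeps, in log space with multi-start;
* a dihedral-remodeling free-energy estimator ΔG(F) = −Σ ln p(φ*, ψ*) in
  k_BT over the five constrained (φ, ψ) couples of the recognition
  fragment, from von Mises mixture samples;
* scanners for the Hsp40/DnaJ consensus G X [LMQ] {P} X {P} {CIMPVW} and
  DnaK-style hydrophobic patches.

## Worked example

```r
library(foldclamp)
sch <- dnaj_scheme()   # ubiquitin scheme + 5 uM extended-state binder
sch
#> Five-state kinetic scheme
#>   k_u = 0.93 /s, k_c = 8 /s, k_f0 = 0.52 /s, k_uc = 50 /s
#>   extended:  k_on = 48000 /(M s), k_off = 0.045 /s
#>   collapsed: k_on = 0 /(M s), k_off = 0 /s
#>   [chaperone] = 5e-06 M, fold competence = 0.75

# synthetic experiment: unfold 5 s at 120 pN, quench 5 s, test 8 s
pr  <- force_quench_protocol(t_unfold = 5, t_q = 5, t_test = 8)
cfg <- sim_config(n_recordings = 40, noise_sd = 1, seed = 42)
sim <- simulate_experiment(sch, pr, cfg)

# step detection on the first recording's unfolding pulse
detect_steps(trace_pulse(sim$traces[[1]], "unfold"), expected_step = 20)
#>    time     size multiplicity
#> 1 0.365 19.97676            1
#> 2 0.590 20.01430            1
#> 3 1.090 20.06286            1
#> 4 2.092 20.00518            1

# pooled yield with QC and bootstrap SEM
ry <- refolding_yield(sim$dataset, yield_qc(step_size = 20), B = 500, seed = 1)
sprintf("pooled yield %.3f +/- %.3f (%d recordings, %d domains)",
        ry$yield, ry$sem, ry$n_recordings, ry$n_domains)
#> "pooled yield 0.344 +/- 0.029 (31 recordings, 218 domains)"

# the deterministic model agrees: ~0.30 predicted for this protocol
predict_yield(sch, force_quench_protocol(t_unfold = 0, t_ext = 5,
                                         t_q = 5, t_test = 0))
#> [1] 0.3025942
```

The detected 20-nm steps are the unfolding staircase; the pooled yield
(~0.34 at 5 uM chaperone versus ~0.70 without) is the quantity whose
dependence on t_q, t_ext and force the χ² fit converts into binding
constants. A YAML-driven `run_pipeline()` chains
simulate → analyze → fit and writes trace TSVs, dataset CSVs and results
JSON, all stamped with the config hash and seed.

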