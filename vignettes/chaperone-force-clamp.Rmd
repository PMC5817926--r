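---
title: "Modelling chaperone-modulated mechanical folding under force clamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chaperone-modulated mechanical folding under force clamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldclamp)
```

## The experiment being modelled

In force-clamp spectroscopy a polyprotein of identical domains (a ubiquitin
nonamer, or I27/Z1 octamers) is tethered between a surface and an AFM
cantilever and held at constant force. An initial high-force pulse
(~120 pN) unfolds the domains one by one, each unfolding appearing as a
fixed-size extension step (20 nm for ubiquitin, 25 nm for Z1). Dropping the
force to ~0 for a quench time $t_q$ lets domains collapse and refold; a
test pulse then restretches the molecule and counts how many domains
regained mechanical stability. The per-recording refolding yield is the
ratio of test-pulse to initial-pulse step counts.

Holdase chaperones change this picture: Hsp40 (DnaJ) binds the mechanically
*extended* chain and Hsp70 (DnaK, in its ADP state) binds the *collapsed*
molten-globule-like intermediate, and a bound domain cannot fold. Varying
the time $t_{ext}$ the chain is held extended before the quench, the quench
duration $t_q$, the holding force, and the chaperone concentration turns
the refolding yield into a read-out of binding kinetics.

## The five-state kinetic model

A domain occupies one of five states: folded (F), extended free/bound
(E, EB), collapsed free/bound (C, CB). The active transitions switch with
the force regime (threshold 10 pN — the experiments only use ~0 versus
$\ge$ 30 pN, so any value between the regimes is equivalent):

* **Force pulse** (> 10 pN): F $\to$ E at $k_u$; C $\to$ E and CB $\to$ EB at
  $k_{uc}$ (binding status preserved); E $\leftrightarrow$ EB at
  $k_{on}^{ext}\,c$ and $k_{off}^{ext}$.
* **Quench** ($\le$ 10 pN): E $\to$ C at $k_c$; C $\to$ F at $k_{f0}$;
  E $\leftrightarrow$ EB and C $\leftrightarrow$ CB by mass action.

Two structural assumptions are built in: bound states never fold, and a
bound extended chain does not collapse until the chaperone leaves (the
observed slow-down of collapse with increasing $t_{ext}$ motivates this;
allowing EB $\to$ CB is not supported by anything we can fit, so the
transition is omitted and flagged here as an assumption). Collapsed states
re-extend fast under force ($k_{uc}$ = 50 1/s) so only folded domains
produce test-pulse steps.

The master equation $\dot x = Q(F)\,x$ is linear with piecewise-constant
$Q$, so `propagate()` solves it *exactly* by per-segment matrix
exponentials (`Matrix::expm`); a constant within-segment step reuses one
propagator. There is no ODE-solver tolerance anywhere: probability is
conserved to ~1e-12, and the test suite checks conservation at 1e-9.

`predict_yield()` reports the folded fraction at the end of the quench,
scaled by the fold competence (below). For protocols that include the
initial unfolding pulse, `fit_dataset(t_unfold = ...)` additionally
conditions on having unfolded before the quench: domains unfold at random
times during the pulse, so their chaperone exposure varies, and the
never-unfolded mass $e^{-k_u (t_u + t_{ext})}$ stays folded through the
quench and must be removed from both numerator and denominator. Ignoring
this biases fitted association rates by roughly 20%.

### Parameters, units, defaults

All times are seconds, forces piconewtons, concentrations molar, rates
1/s or 1/(M s). The reference parameterisation (`ubiquitin_scheme()`):

* $k_u$ = 0.93 1/s — unfolding at the 120 pN reference force. Rates are
  stored per reference force; no Bell-type force law is applied because
  each substrate is only ever pulled at one force.
* $k_{f0}$ = 0.52 1/s, $k_c$ = 8 1/s — chosen so the no-chaperone quench
  kinetics show the observed apparent folding rate $k_f \approx$ 0.52 1/s
  (with collapse much faster than folding, the two-step chain's slow
  eigenvalue is $\approx k_{f0}$). These two conformational rates are the
  ones held fixed in all fits.
* `fold_competence` = 0.75 — the fraction of domains able to reach the
  folded state, matching the observed long-quench yield plateau (~75%).
  It is a *partition of domains* (an incompetent domain has $k_{f0} = 0$),
  not a sixth state: the deterministic reference for an ensemble is the
  mixture $fc \cdot x_{full} + (1-fc) \cdot x_{k_{f0}=0}$, and
  `predict_yield()` folds the partition into a single scale factor.
* `dnaj_scheme()`: $k_{on}^{ext}$ = 4.8e4 1/(M s), $k_{off}^{ext}$ =
  0.045 1/s. The printed constraints are $K_d$ = 9.4e-7 M and an apparent
  yield decay of ~0.27 1/s versus $t_{ext}$ at 5 uM; the pseudo-first-order
  identity $k = k_{on} c + k_{off}$ fixes the split.
* `dnak_scheme()`: $k_{on}^{coll}$ = 2e5 1/(M s), $k_{off}^{coll}$ =
  0.028 1/s. Only $K_d$ = 1.4e-7 M is printed; the split is set so a 5 uM
  quench-time sweep plateaus near the observed ~30% yield. Note that
  $k_{off}^{coll} t_q \le 0.4$ on the experimental grid, which is why the
  dissociation rate of a collapsed-state binder is only weakly identified
  (see *Limitations*).

An optional force-dependence of $k_{on}^{ext}$ couples the binding rate to
the dihedral free-energy profile below as a Boltzmann factor
$e^{-\Delta\Delta G(F)/k_BT}$ (`kon_multiplier_from_energy()`): binding is
fastest at the force where remodeling the backbone to its bound geometry is
cheapest, which places the predicted yield minimum at the profile minimum.

## The synthetic force-clamp generator

`simulate_experiment()` is the stochastic twin of the deterministic model:
per-domain Gillespie (direct method) with the generator refreshed at every
segment boundary, which is exact for piecewise-constant rates — the
exponential clock is memoryless, so truncating a waiting time at a boundary
and redrawing is the correct dynamics. Domains are independent, as in the
per-domain counting of the experiments. Each recording tethers a uniform
random number of domains in `[pickup_min, n_domains_max]` (default 4–9,
mean ~7), deliberately letting some recordings fall below the five-step
quality filter so the filter is exercised. Each recording has its own RNG
stream derived from the master seed, so any single recording can be
regenerated alone.

Traces are rendered as a per-(state, regime) extension lookup — folded 0,
extended 1 step, collapsed 0.5 steps under force, everything 0 at quench —
plus white Gaussian noise (default 1 nm at 1 kHz). What this reproduces is
staircase geometry, which is all the step detector consumes. What it does
*not* reproduce: worm-like-chain curvature of the baseline, instrument
drift and 1/f noise, the ~3 ms force-settling transient, surface-adhesion
artifacts. Passing detector tests therefore demonstrate correctness of the
segmentation logic on idealised staircases at realistic SNR, not robustness
to drifting baselines. A further renderer idealisation: collapsed domains
re-extend in the test pulse as synchronised half-steps; when many
folding-incompetent domains accumulate, two coincident half-steps can
imitate one full step. Real collapse remnants produce heterogeneous
non-staircase elongation. The count-based yields (`steps_test`,
`steps_initial`) are unaffected; only trace-level analysis of test pulses
in low-competence regimes inherits this artifact.

`steps_test` counts re-unfolding of domains that unfolded during the
initial pulse, keeping `steps_test <= steps_initial` structurally; the rare
domain unfolding for the first time in the test pulse stays visible in the
trace and in the final-extension pair, so the equal-extension filter
rejects those recordings exactly as the experimental procedure does.

## Trace analysis

**Step detection** is penalized binary segmentation with an L2
(piecewise-constant mean) cost: the split maximising the residual
sum-of-squares reduction is accepted while the gain exceeds
$\beta = 40\,\hat\sigma^2 \log n$, with $\hat\sigma$ the robust noise
estimate $\mathrm{MAD}(\Delta x)/\sqrt2$, under a minimum segment length
(default 5 ms). At 20 nm steps in 1 nm noise the SNR is ~20, so detection
is insensitive to the penalty constant over more than an order of
magnitude. A level change close to $m$ times the expected step (within
±35% of one step) is reported as $m$ coincident events; adjacent rejected
changes within twice the minimum dwell are merged before applying the size
rule, which recovers the occasional coincident pair that segmentation
splits at a slightly wrong sample. Measured performance at nominal noise:
recall 0.995, precision 1.000 over 500 traces.

**Unfolding kinetics**: traces with at least six events are kept, each
trace's cumulative step count is rescaled to [0, 1] *per trace* and then
averaged (the alternative — pooled normalisation — weights traces by their
event count; per-trace normalisation matches the "summed, averaged, and
normalized" reading in which every trajectory contributes equally), and the
average is fitted to $1 - e^{-k_u t}$. Degenerate inputs (all events at
$t = 0$) return a typed failure, never a number.

**Refolding yield**: recordings need five or more initial steps and equal
extension at the ends of the initial and test pulses within 10% of the
fully unfolded length (the equal-extension criterion is standard practice
to ensure the same molecule is held in both pulses; the 10% tolerance is
this package's choice, as no standard value exists). The pooled yield is the ratio of summed counts —
domains, not recordings, are the independent observations — with the mean
of per-recording ratios also exposed for comparison. Errors are
nonparametric bootstrap over recordings, B = 500, seeded. The different
event-count thresholds for the unfolding (6) and refolding (5) analyses are
both config-exposed with the printed defaults.

**Yield-curve fits** use weighted (1/SEM²) nonlinear least squares
(`minpack.lm::nlsLM`) with a log-linearised starting point, for the
saturating form $A(1-e^{-kt})$ ($t_q$ sweeps) and the decaying form
$Y_\infty + (Y_0-Y_\infty)e^{-kt}$ ($t_{ext}$ sweeps). Flat data return a
failure flag; zero/missing SEMs are replaced by the median positive SEM.

## Fitting binding constants

`chi_square()` is $\sum_i ((y_i - \hat y_i)/\mathrm{SEM}_i)^2$ over all
points of all supplied datasets, with $\hat y$ from the deterministic
model. `fit_model()` optimises $\log_{10}$ of the free rates (positivity
for free) under box bounds — $k_{on} \in [10^2, 10^8]$ 1/(M s),
$k_{off} \in [10^{-4}, 10^2]$ 1/s, conformational rates
$[10^{-4}, 10^3]$ 1/s — with L-BFGS-B from 16 Latin-hypercube starts plus
the template scheme's own values. Only the rates flagged free move; the two
conformational reference rates stay at their no-chaperone values. A single
protocol family triggers an identifiability warning, and
`identifiability_sweep()` profiles any free rate, flagging flat profiles.
Force-sweep data can be fitted either with per-force yields or through the
energy-profile coupling; the per-force route is the default since the
coupling has no closed form.

## Dihedral remodeling free energy

For each constrained residue of the recognition fragment (the five
(φ, ψ) couples LYS48–ASP52; flanking residues excluded), force-conditioned
samples give a periodic density $p_{r,F}(\varphi, \psi)$, and the cost of
remodeling the backbone to its chaperone-bound values is

$$\Delta G(F) = -\sum_r \ln p_{r,F}(\varphi_r^*, \psi_r^*) \quad [k_BT],$$

averaged over replicates (default five), with the replicate SD computed
*before* the mean profile is shifted so its minimum over force is zero
(the reporting convention; shifting after taking SDs keeps the error bars
meaningful). We use the free-energy (log-probability) form throughout; a
plain sum of probabilities is dimensionally inconsistent with an energy and
is not implemented. Energies are reported in $k_BT$ with no temperature
conversion.

Two density estimators are provided: a 5°-bin histogram with a Laplace
pseudo-count (strictly positive everywhere, so a reference in an unvisited
bin costs a large-but-finite energy rather than an error) and a product
von Mises kernel estimator (default concentration κ = 200, i.e. ~4° kernel
width) which is preferred for point evaluations: at 5° bins a single-bin
count is Poisson with mean of order 10, whereas the kernel pools hundreds
of neighbours. The kernel estimator reproduces analytic von Mises
log-densities to better than 0.1 $k_BT$ at 2×10⁴ samples.

The synthetic generator draws from per-residue two-component von Mises
mixtures whose weights shift with force through a logistic: GLN49/LEU50
move into the extended β/PPII basin around 100 pN, while LYS48, GLU51 and
ASP52 leave their low-force basins only around 200 pN. With the bound
reference at the β values for the first pair and the low-force values for
the other three, the remodeling cost is high at both force extremes and
minimal at intermediate force — the U-shape with an interior minimum
(~150 pN with the defaults) that rationalises force-optimal binding. The
bound-reference dihedrals are *inputs* (in the original workflow they come
from a simulation of the bound complex); `bound_reference_default()` is a
synthetic stand-in consistent with the generator, and absolute ΔG values
from MD (e.g. the ~3 $k_BT$ scale) are not reproducible without the MD
trajectories — only the estimator's correctness is testable, via the
closed-form oracles.

## Sequence scanners

The Hsp40/DnaJ consensus G-X-[LMQ]-{P}-X-{P}-{CIMPVW} is matched as a
literal 7-position pattern (the cited literature's "approximately eight
residues" is noted but not implemented), with all overlapping matches
reported in 1-based inclusive coordinates plus a numbering offset for
fragments cut from longer proteins. Ambiguity codes (B, J, O, U, X, Z)
fail every position, including wildcards — a conservative choice — while
genuinely invalid characters raise an error listing them. The scanner is
verified against a brute-force longhand rule check on random sequences.
`scan_dnak_patches()` is an explicitly heuristic DnaK-site proxy: sliding
five-residue Kyte–Doolittle means with a Leu/Ile bonus at the patch-calling
step only (reported scores stay plain window means).

## Problem sizes and numerical checks in the test suite

The suite runs the stochastic/deterministic agreement at 3,000 domains in
the module test and 10,000 domains at ten checkpoints in the acceptance
suite (3 SE); detector precision/recall on 120 and 500 traces; the
unfolding-rate recovery on the full 195-recording design; and the binding
recovery on three replicate synthetic experiments per chaperone at the
per-condition trajectory counts of the corresponding figure captions.
These sizes make the full suite run in a few minutes while keeping every
statistical tolerance at its stated value.

## Known limitations

* **One-sided identifiability of slow dissociation.** For a collapsed-state
  binder with $k_{off} t_q \lesssim 0.4$, the chi-square profile of
  $k_{off}$ is flat towards zero: the data bound it from above but not
  below, so single-experiment $K_d$ estimates occasionally collapse with
  the $k_{off}$ boundary. The acceptance check uses the median over three
  replicate experiments; real applications should report the profile
  (`identifiability_sweep()`), not just the point estimate.
* The extension renderer idealises collapse remnants (see above) and omits
  drift; the detector is tested on what the renderer produces.
* No nucleotide cycling: the full DnaKJE foldase machinery is emulated
  only through `fold_competence` and the conformational rates, never
  mechanistically.
* No Bell force law: rates are per reference force, so force sweeps act on
  binding (through the energy profile) but not on $k_u$.
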