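---
title: "Virtual lesions, inhibitory homeostasis and compensatory areas: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual lesions, inhibitory homeostasis and compensatory areas: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionkit)
```

This vignette documents the models, the numerical choices and the
limitations of `lesionkit`, in the order a user meets them: the network
model and its homeostat, the virtual-lesion protocol, the similarity
measures, the haemodynamic/FC stage, and the synthetic cohort generator
that makes the whole pipeline testable. It states no empirical result
that the package's tests and acceptance script do not themselves
compute.

## The mean-field network model

Each cortical region is a reduced two-population mean-field node: an
excitatory and an inhibitory pool with synaptic gating variables
$S^{(E)}_i, S^{(I)}_i \in [0,1]$. The input currents are

$$I^{(E)}_i = w_E I_0 + w_+ J_N S^{(E)}_i
  + G J_N \textstyle\sum_j C_{ij} S^{(E)}_j - J_i S^{(I)}_i,
\qquad
I^{(I)}_i = w_I I_0 + J_N S^{(E)}_i - w_{II} S^{(I)}_i,$$

firing rates follow the sigmoidal f–I curve
$r(I) = (aI-b)\,/\,(1-e^{-d(aI-b)})$ for each population, and the gating
evolves as

$$\dot S^{(E)} = -S^{(E)}/\tau_E + (1-S^{(E)})\,\gamma\, r^{(E)} + \sigma\nu(t),
\qquad
\dot S^{(I)} = -S^{(I)}/\tau_I + r^{(I)} + \sigma\nu(t).$$

`dmf_params()` carries the canonical parameter set of this model family
($I_0 = 0.382$ nA, $w_+=1.4$, $J_N = 0.15$ nA, $a_E = 310$ nC$^{-1}$,
$b_E = 125$ Hz, $d_E = 0.16$ s, $a_I = 615$, $b_I = 177$, $d_I = 0.087$,
$\tau_E = 100$ ms, $\tau_I = 10$ ms, $\gamma = 0.641$,
$\sigma = 0.01$ nA). Integration is Euler–Maruyama at $dt = 1$ ms with
gating clipped to $[0,1]$ after every step; FC-generating runs last 10
simulated minutes with the first 2 minutes discarded (the worked
defaults), and the test profile scales this to 60 s with a 12 s
transient. The compiled core is cross-checked in the test suite against
an independent RK4 integrator at $dt = 0.01$ ms on 3-node systems
(agreement to $10^{-4}$ at $t = 1$ s).

**Noise convention.** The same $\sigma$ drives both gating equations,
independent across regions and populations, entering as
$\sigma\sqrt{dt}\,\mathcal N(0,1)$ per step. All randomness flows
through R's RNG, so `set.seed()` (or the `seed` arguments) makes every
simulation bit-reproducible.

**Global coupling.** $G$ is the one parameter this model family fits to
data rather than tabulating. `fit_global_coupling()` implements the
standard procedure: sweep a grid, keep only values whose regional firing
stays in the balanced band, and pick the best FC–FC correlation against
a target. The package default $G = 0.5$ was chosen once, before the
acceptance checks were written, as a value at which the balanced
low-firing state is dynamically stable under the default noise for
max-normalized synthetic connectomes across many generator seeds. For
$G \gtrsim 0.6$–$1$ (depending on the connectome's strength
distribution) the balanced state coexists with, and escapes to, a
high-firing attractor that no inhibitory re-tuning can stabilize — the
same constraint that motivates selecting $G$ "where firing sustains at
the set point" when fitting real data.

## Feedback inhibition control

`fic()` is the homeostat: it tunes each region's local inhibitory weight
$J_i$ so the region's long-run excitatory drive sits at the balanced
working point. The working point is a band on the mean excitatory input
current, $-0.026 \pm 0.005$ nA relative to $b_E/a_E$; its image under
the excitatory f–I curve is a mean firing rate between 2.63 and 3.55 Hz,
and that printed firing band is the operational contract the package
enforces and tests.

Numerical choices that matter:

* **Rate-space compliance.** With stochastic input the convex f–I curve
  makes the mean *rate* sit above the rate of the mean *current*
  (roughly +0.3 Hz at the default noise). The controller therefore
  measures compliance on the window-mean firing rate against the band's
  rate image; otherwise a current-compliant network would sit above the
  firing band.
* **Analytic warm start.** At the deterministic balanced fixed point
  every region has the same gating $(S_E^*, S_I^*)$, so the balancing
  weight has a closed form,
  $J^*_i = (w_E I_0 + w_+ J_N S_E^* + G J_N s_i S_E^* - I^*)/S_I^*$,
  with $s_i$ the nodal strength (`fic_warm_start()`). Healthy fits start
  there and only mop up the stochastic Jensen corrections. Post-lesion
  refits start from the healthy weights — the protocol of the
  three-condition analysis.
* **Windowed additive control with hysteresis.** The model runs in 10 s
  windows. Regions outside the *inner* half-band are adjusted by an
  additive step (default 0.02 nA); convergence and the re-adjustment
  clock use the full band. The hysteresis parks converged weights near
  the band centre so that a later refit does not register spurious
  re-adjustments from regions left at a band edge. Steps grow by 1.2
  per same-sign window in healthy fits (fast traversal of large
  distances) and stay fixed in the lesion refit, which makes a region's
  re-adjustment time proportional to its total weight change. A pure
  proportional controller is unstable here: under global coupling the
  collective loop gain exceeds one and the whole network oscillates
  between over- and under-inhibited states.
* **RT definition.** $RT_i$ is `window_length` times the index of the
  *last* window in which region $i$'s mean rate violated the full band
  (0 if never). Window means fluctuate (s.d. $\approx$ 0.2 Hz against a
  band half-width of 0.46 Hz), so isolated noise violations put a noise
  floor under RT; the DSA intersection with $|dJJ|$ (below) filters
  most of it.
* **The lesioned node is exempt** from the refit homeostat: it is
  disconnected, has no balance to restore, and its RT/dJJ are masked in
  every report.

## The three-condition protocol

`virtual_lesion()` runs, per subject and lesion site:

1. **Healthy** — weighted Jaccard profile of the prospective lesion
   site; FIC on the intact connectome ($J$); simulation; healthy FC.
2. **Altered** — lesion applied (`apply_lesion()` zeroes the site's row
   and column), $J$ frozen at healthy values, *no* FIC: the early
   post-lesion state with lost E–I balance; altered FC.
3. **Reorganized** — FIC re-run on the lesioned connectome from the
   healthy $J$, yielding $J'$, $RT$, $dJJ = J' - J$; simulation;
   reorganized FC.

The three FC simulations share one noise stream (common random
numbers). Condition differences then reflect the lesion and the
re-tuned weights rather than the realization, which is what a paired
contrast is after; without it the directional FC effects exist but are
unreliable at test scale.

**SSA** is the top `round(0.25 × n)` of the Jaccard profile (reference
excluded, ties broken by ascending index). **DSA** is the intersection
of the top-25% sets of $RT$ and $|dJJ|$. The overlap fraction is
$|SSA \cap DSA| / |DSA|$ — the share of dynamically identified areas
that are also structurally similar. The denominator convention is a
package decision (the DSA, being an intersection, is the smaller and
more conservative set) and is stamped into every report; `overlap()`
also offers `|SSA|` and union denominators.

**Jaccard neighbourhood convention.** Both self-entries *and* the mutual
edge $C_{AB}$ are excluded from the min/max sums: similarity should
reflect shared third-party wiring, not the pair's own link. This is a
recorded choice; including $C_{AB}$ changes values slightly but not
rankings in practice.

## Haemodynamics and FC statistics

Excitatory gating drives a standard four-state Balloon–Windkessel model
per region ($\kappa = 0.65$ s$^{-1}$, $\gamma_h = 0.41$ s$^{-1}$,
$\tau = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$),
integrated by Euler at the neural sampling interval (10 ms by default —
the haemodynamic time constants are three orders slower) and read out as
percent signal change at TR = 2 s. FC is the Pearson correlation of
z-scored regional BOLD series.

Condition contrasts Fisher-transform each edge, run a paired t-test
across subjects, and apply Benjamini–Hochberg FDR over the upper
triangle at $\alpha = 0.05$ (configurable; the FDR-corrected 0.05
threshold is adopted over the stricter uncorrected variant sometimes
quoted alongside it). Graph metrics zero negative FC weights, use
$1/w$ as edge length for efficiency and characteristic path length, a
geometric-mean triangle intensity for weighted transitivity, and seeded
Louvain (best of 20 restarts) for modularity — each validated against
brute-force oracles on small graphs in the test suite.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` emulate the statistical structure
the analysis assumes, not any real dataset:

* 68 regions, 34 per hemisphere, with contiguous lobe-like modules
  mirrored across hemispheres (default 4 per hemisphere);
* edge presence by block density (0.8 within modules, 0.2 between);
* *weight-coherent* modules: between-module edges are scaled down
  (×0.25), and inter-hemispheric wiring is a damped copy of the modular
  block structure (×0.3). Without weight coherence the weighted-Jaccard
  similarity structure that the whole analysis rests on simply does not
  exist — module membership would be visible in densities but not in
  profiles;
* homotopic links made each region's strongest inter-hemispheric edge
  (×1.5 over the strongest other callosal weight), so lesion analyses
  can recruit contralateral homologues;
* multiplicative log-normal edge noise (sdlog 0.5) and per-subject
  multiplicative jitter (sdlog 0.1) around a shared group skeleton;
* optional planted "twins": regions whose profiles are near-copies of a
  seed region's, giving a ground truth for similarity recovery;
* max-normalization (largest entry = 1). The weight normalization of
  real tractography pipelines varies; max-normalization keeps $G$
  comparable across subjects and is recorded as a modelling choice.

What a green test on this generator does *not* establish: realistic
spatial embedding or distance-dependent wiring, realistic weight tails
beyond log-normal, tractography biases, subject-level differences in
parcellation, or any claim about a specific clinical cohort. The
generator exists so the *machinery* — homeostat, lesion operator,
similarity measures, statistics — is verified end to end; quantitative
claims about real brains require real connectomes.

## Degenerate inputs and edge cases

* Zero-strength reference region: Jaccard profile degenerates to 0 with
  a warning; lesioning such a node leaves dynamics and FC unchanged up
  to haemodynamic start-up.
* All-zero RT (nothing re-adjusted): empty DSA with a warning; overlap
  reported as 0 and flagged.
* Constant vectors in correlation panels: $r$ reported as 0 with a
  `degenerate` flag instead of NA poisoning downstream code.
* Zero-variance BOLD rows: correlations set to 0 with a warning.
* Non-finite states abort the integrator with the step index named.
* FIC budget exhaustion returns the partial fit with per-region
  `converged` flags and a warning, never an error.

## Known limitations

* RT carries a noise floor from windowed band checks (see above); its
  correlation with structural similarity is accordingly weaker than
  that of $|dJJ|$ at desk scale.
* Single-node lesions only; edge deletions and multi-site damage are
  out of scope, as are conduction delays, regional parameter
  heterogeneity, directed or dynamic FC, and lesion-volume effects.
* The balanced-state stability ceiling ties the default $G$ to the
  synthetic generator's strength distribution; users with differently
  normalized connectomes should re-fit $G$ with
  `fit_global_coupling()`.
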