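---
title: "Methods: emergence, ignition hierarchy, controllability and whole-brain models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emergence, ignition hierarchy, controllability and whole-brain models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergentdyn)
```

`emergentdyn` links four quantitative accounts of large-scale brain
organisation on parcellated BOLD timeseries and structural connectomes:

1. **Causal emergence capacity** of pairs of regions, from information
   decomposition of the time-delayed mutual information (TDMI);
2. **Spatiotemporal hierarchy** of intrinsic-driven ignition (IDI);
3. **Average and modal controllability** of the structural network;
4. A **dynamic mean-field (DMF) whole-brain model** with Balloon-Windkessel
   haemodynamics, used to ask whether connectome differences *cause* the
   functional differences.

Because the patient data this pipeline targets are access-restricted, the
package ships a synthetic cohort generator with planted group effects, so
every downstream stage is testable end to end without any download. This
vignette records the model assumptions, the tunable parameters, the
numerical choices, and the design decisions that were genuinely open.

## 1. Emergence capacity

For two regions with binary (mean-thresholded) activity, write
$X_t = (X^1_t, X^2_t)$ and consider the lagged joint distribution of
$(X^1_{t-\tau}, X^2_{t-\tau}, X^1_t, X^2_t)$ estimated by the plug-in
(empirical frequency) estimator over all aligned samples. The TDMI
$I(X_{t-\tau}; X_t)$ is decomposed two ways:

* **Forward partial information decomposition (PID)** with the two past
  states as sources and the composite future $(X^1_t, X^2_t)$ as target.
  The *synergy* of this decomposition upper-bounds the unique predictive
  power of any supervenient macroscopic feature of the pair — the pair's
  **emergence capacity**.
* **The 16-atom lattice** indexed by (past, future) combinations of
  \{Red, Unq1, Unq2, Syn\}. Nine Shannon mutual informations between subsets
  of past and subsets of future variables, six single-sided redundancies and
  one double redundancy give 16 linear equations that pin the atoms down.
  **Downward causation** is `Syn->Red + Syn->Unq1 + Syn->Unq2`; **causal
  decoupling** is `Syn->Syn`; on this lattice capacity = downward +
  decoupling exactly.

Two redundancy functions are implemented:

* **MMI** (minimum mutual information): redundancy is the minimum
  source-target MI. This is the only redundancy used for the full lattice.
* **CCS** (common change in surprisal): redundancy is the expected local
  co-information over states where the three local informations and the
  co-information share a strict sign; a state with any zero local term
  contributes nothing.

**Why CCS is the default capacity.** For two *independent* autocorrelated
chains the CCS co-information is identically zero, so CCS capacity is zero
as it should be. The MMI lattice instead assigns such a system positive
"synergy" inherited from single-region self-predictability (the
two-copy-chain system in the test suite is the canonical example: its
MMI Syn->Syn atom is 2 bits). On slow, strongly autocorrelated BOLD-like
signals this artifact term can dominate and even reverse group orderings,
so the pipeline reports CCS capacity as the primary measure and keeps the
MMI lattice for the downward/decoupling split and for robustness checks.
Both are exposed everywhere.

Defaults and options:

* lag `tau = 1` TR (2 s), with any lag available (e.g. 4 TRs for a slower
  timescale);
* binarisation strictly above the per-region mean (ties, a measure-zero
  event for continuous data, map to 0);
* logarithms base 2: all quantities in bits;
* a **Gaussian estimator** (closed-form MIs from the lagged covariance,
  MMI only) for continuous signals; near-singular covariances are
  ridge-regularised with `1e-9` and a warning;
* optional **HRF deconvolution** before binarisation: a Wiener filter
  against the canonical double-gamma HRF (peak 6 s, undershoot 16 s,
  peak/undershoot ratio 6) with a noise floor of `1e-3` of the peak spectral
  power. Off by default — synthetic and simulated data have no haemodynamic
  convolution to undo; turn it on for empirical BOLD. Whether deconvolution
  should precede the discrete estimator as well as the Gaussian one is not
  settled; it is a toggle applied before both.

The global measure is the mean over all unordered pairs (self-pairs are
degenerate and excluded); constant regions are skipped with a logged count.
The normalised variant divides by the TDMI.

## 2. Intrinsic-driven ignition

The signal is band-passed to 0.04–0.07 Hz (2nd-order zero-phase Butterworth;
the order is a package choice, the band is the conventional ignition band),
z-scored per region, and an *event* occurs when the z-score crosses the
threshold (default 1 SD) from below. Each event at `(i, t)` opens a window
`[t, t + 3]` (window 4 TRs, anchored at the driver event — the anchor is a
package choice); every region with an event inside the window participates.
Since the co-event matrix links all participating regions, its largest
connected component is the participating-set size (the clique equivalence is
asserted against a BFS oracle in the tests). The event's IDI is that size;
per-region mean IDI over the region's driver events forms the ignition
profile; the **hierarchy score** is the sample (n−1) standard deviation of
mean IDI across regions with at least one event. Eventless regions are
excluded by default (a toggle can score them 0). Two regions crossing the
threshold in the same volume are two separate driver events.

No signal-processing package is available in the target environment, so the
Butterworth design and zero-phase (forward-backward, odd-reflection padded)
filtering are implemented in the package and validated coefficient-by-
coefficient against an independent reference implementation in the tests.
A region that is constant on input carries only round-off after filtering;
it is treated as eventless rather than z-scored.

## 3. Network controllability

The linear network model `x(t+1) = A x(t) + B_K u_K(t)` uses the connectome
normalised as `A / (sigma_max + 1)` (Schur stable by construction). With
single-node inputs `B = e_i`:

* **Average controllability** is `trace(W_i)` where the Gramian solves the
  discrete Lyapunov equation `W = A W A' + B B''`. For symmetric stable `A`
  the exact solution gives `trace(W_i) = [(I - A^2)^{-1}]_{ii}`, computed
  via the eigendecomposition — an exact Lyapunov solution, asserted equal to
  the truncated Gramian sum to `1e-10` in the tests.
* **Modal controllability** is `phi_i = sum_j (1 - lambda_j^2) v_{ij}^2`
  with eigenvalues sorted descending. For (numerically) degenerate spectra
  the sum over the degenerate subspace is rotation-invariant, so no special
  handling is needed.

Whole-brain values are unweighted means over regions. The group
**consensus connectome** keeps an edge only when strictly more than half of
the subjects have it, valued as the mean over the subjects that do.

A closed-form caveat discovered while validating the synthetic lesion:
mean modal controllability equals
`1 - sum(lambda^2) / (N (lambda_max + 1)^2)`, and *uniform weight
attenuation alone raises it* (scaling `A` by `a < 1` shrinks the subtracted
term). Edge dropout lowers it, and for heavy-tailed connectomes with
`lambda_max >> 1` the dropout term dominates, which is why the lesioned
synthetic group (attenuation + dropout) still shows the expected *lower*
modal controllability. The tests assert the combined-lesion direction, not
pure attenuation.

## 4. Dynamic mean-field model

Each region holds coupled excitatory (80%) and inhibitory (20%) populations
with sigmoidal rate transfer `r(I) = (aI - b) / (1 - exp(-d (aI - b)))`,
gating-variable relaxation, and inter-regional excitatory coupling
`G * A`. All local constants are the standard literature values and live in
one auditable table, `dmf_params()` (external current 0.382 nA, recurrence
1.4, NMDA coupling 0.15 nA, excitatory gains 310/125/0.16, inhibitory
615/177/0.087, time constants 100 ms and 10 ms, rate-to-gating factor
0.641, noise 0.01 nA). Integration is Euler–Maruyama at `dt = 0.1 ms`; all
noise flows through R's RNG so a seed reproduces a run bit-for-bit.

* **Connectome scaling.** The input matrix is scaled so its maximum entry is
  0.2 — the convention of the reference DMF implementations. With the
  maximum scaled to 1 instead, instability arrives below `G = 1` and the
  conventional `G` grid (0.1–2.5) never brackets criticality.
* **Feedback inhibition control (FIC).** Regional inhibitory weights `J_i`
  clamp the excitatory current at `b_E/a_E - 0.026 nA` (about 3 Hz firing).
  At that target the equilibrium gating levels are identical across
  regions, so `J` has a closed form, which is then verified (and refined if
  off-equilibrium) by short noiseless probe simulations — deterministic and
  much faster than stochastic tuning. Failure of the probes to converge
  means the balanced low-activity state has lost stability: at that
  coupling the model is declared unstable.
* **Stability selection of `G`.** Ascending sweep; a grid value is unstable
  when FIC cannot converge or the time-averaged rate over the last half of
  a 60 s stochastic probe exceeds 10 Hz (the ceiling is a package choice —
  only "became unstable" is specified). The selected `G` is the grid value
  just before the first unstable one; a grid with no unstable value returns
  the grid maximum with a warning (at desk scale with 20-node synthetic
  connectomes this fallback is the norm on the conventional 0.1–2.5 grid:
  instability sits near `G ~ 4.5`).
* **Balloon-Windkessel.** The standard four-state haemodynamic ODE per
  region (signal decay 0.65 s^-1, flow elimination 0.41 s^-1, transit
  0.98 s, Grubb exponent 0.32, resting extraction 0.34, V0 = 0.02), driven
  by the excitatory gating, sampled at the TR; the first 20 s are discarded
  for the haemodynamic transient; band-pass (0.008–0.09 Hz, or
  0.04–0.07 Hz for ignition) is applied afterwards.
* **FCD fitting of `G`.** Sliding-window FC (30 TRs, step 3), FCD as the
  window-by-window correlation matrix, and the two-sample
  Kolmogorov–Smirnov statistic between pooled upper-triangular FCD values
  of empirical and simulated runs; `G*` minimises the mean KS distance.
  Pooling across subjects per group is the default; a per-subject mean is
  exposed as an option.

## 5. The synthetic cohort: what it emulates and what it does not

`generate_var_cohort()` emulates three groups (healthy controls and two
patient analogues) of the sizes the analysed cohorts had (18/11/10), each
subject carrying a structural connectome and a BOLD-like timeseries
(TR = 2 s, 200 timepoints by default, inside the 160–300 range of the
emulated acquisitions). The stated world:

* one heavy-tailed (log-normal weight) base connectome template per cohort,
  edge density 0.6;
* a group-level lesion: a shared dropout mask (0 / 10% / 20% of edges for
  control / MCS / UWS analogues) plus weight attenuation (1 / 0.75 / 0.5);
* per-subject multiplicative log-normal weight jitter (SD 0.2 on the log
  scale);
* microscale dynamics `x(t+1) = W x(t) + eps`, `eps ~ N(0, 1)`, with
  `W = 0.9 * A_subject / sigma_max(A_base)` clamped to spectral radius
  0.95 — a first-order linear stochastic process whose stationary
  covariance is known, giving oracle checks.

Two design points deserve emphasis. First, normalising `W` by the
*unattenuated base template's* largest singular value is what lets the
planted attenuation change effective coupling; normalising each subject by
its own matrix would cancel the lesion exactly. Second, the shared template
and group-level lesion are what make the >50% consensus rule meaningful:
with fully independent per-subject edge supports below density 0.5 the
consensus matrix is empty and nothing downstream is testable.

What a green test does *not* establish: the generator is linear and
Gaussian, has no haemodynamics, no aetiology structure, no spatial
embedding, and its lesion is statistically uniform. In particular, the
CCS synergy of a linear process carries little group information — the
planted coupling differences express themselves mostly in correlation and
autocorrelation — so the parameter-recovery experiment on functional
measures is intrinsically low-powered at the emulated sample sizes, and
which functional measure clears the significance bar varies with the
cohort draw. The tests document this honestly rather than enlarging the
cohort or searching seeds.

## 6. Statistics

One-way ANOVA for the three-level group factor (the analysis has one
factor; the "three-way" phrasing in some descriptions is read as the three
levels). ANCOVA adjusts for arbitrary covariates (scan type, motion
summaries) by comparing covariate-only and covariate+group linear models;
constant covariates are dropped with a message, rank deficiency errors with
the offending column named. Post-hoc inference uses two-sided permutation
t-tests (pooled-variance t, default 10,000 label permutations, p estimated
as `(b+1)/(m+1)` so it is never exactly zero) with Benjamini–Hochberg
correction across the family of three pairwise comparisons, Cohen's d
attached. Summary-statistic t-tests (for comparisons against printed group
summaries) report Hedges' g with the small-sample correction
`J = 1 - 3/(4 df - 1)`. Spearman correlations use tie-corrected ranks with
the t-approximation p-value.

## 7. Known limitations

* The pairwise decomposition does not extend beyond two regions; the global
  measure is a mean over pairs by design.
* CCS capacity and the MMI lattice disagree on systems with strong
  autocorrelation (see §1); results should state the redundancy function.
* The FIC closed form assumes the homogeneous low-activity equilibrium; far
  beyond criticality it has no meaning, which the sweep treats as
  instability rather than attempting to tune there.
* Desk-scale DMF experiments (tens of regions, minutes of BOLD, few
  simulations) stand in for the full-scale versions; the code supports the
  full scale but the defaults do not attempt it.
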