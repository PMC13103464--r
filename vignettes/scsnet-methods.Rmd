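---
title: "Methods: multimodal EEG-fNIRS network analysis of spinal cord stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal EEG-fNIRS network analysis of spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and scientific setting

`scsnet` implements an end-to-end analysis pipeline for synchronized
EEG-fNIRS recordings acquired around epidural cervical spinal cord
stimulation (SCS) in patients with disorders of consciousness. The study
design it targets stimulates at four frequencies (5, 20, 70, 100 Hz) in
cycles of 2 min pre-stimulation, 1 min stimulation, 2 min post-stimulation,
with 32 EEG channels at 1000 Hz (downsampled to 256 Hz) and 45 optical
channels at two wavelengths (730/850 nm, 11 Hz). Both modalities are mapped
to the 46 Desikan-Killiany cortical regions jointly covered by the
electrode montage and the optode array, where functional connectivity,
graph topology, and group statistics are computed.

No patient data are distributed with the package. Instead, a first-class
synthetic-data generator produces multi-subject, multi-phase recordings
with *known* ground truth — planted coupling and correlation effects — so
that every stage, and the pipeline as a whole, is testable.

## The synthetic generator

### EEG oscillations

Each ROI signal is a sum over the five canonical bands (delta 1-4, theta
4-8, alpha 8-15, beta 15-25, gamma 25-45 Hz) of a constant-amplitude
oscillation `A cos(phi_i(t))` plus 1/f background noise. The band phase is
a Brownian-jitter oscillator:

    phi_own(t) = 2 pi f0 t + theta0 + W(t),   Var[dW] = D dt

with `f0` the band center and diffusion rate `D = 0.5 * f0` rad^2/s, so
the oscillator decoheres over roughly two cycles — a realistic coherence
time for resting-state rhythms, and short enough that independent ROIs
measured over a minute sit at a phase-locking value (PLV) near the
estimator's null level.

Pairwise coupling `c` in [0, 1] is realized by phase mixing: one shared
driver phase per connected component of the coupling graph, and ROI `i`
mixes it in with weight `a_i = max_j c_ij`:

    phi_i = (1 - a_i) phi_own,i + a_i phi_shared.

This is the simplest generator for which the estimated PLV is a monotone
function of the coupling weight, with `c = 1` producing identical phases
(PLV = 1) and `c = 0` independent ones. Two consequences matter for
interpretation:

* **Within-component uniformity.** Because every member of a coupling
  component mixes the same driver, all within-component pairs are elevated
  by similar amounts. Phase locking is inherently transitive — two signals
  both locked to a third cannot remain unlocked to each other — so planted
  multi-edge structures should be read as planted *communities*, not as
  arbitrary edge patterns.
* **Directional signature.** A planted within-community coupling increase
  raises PLV on the community edges and, after proportional thresholding,
  raises the clustering coefficient (CC) of the binary graphs. It does
  *not* raise global efficiency: with the edge count fixed by the
  threshold, concentrating reliable edges inside a community slightly
  *lowers* Eglobal (measured at 46 nodes: CC +0.03, Eglobal -0.008 for a
  planted backbone). The end-to-end recovery tests therefore assert the
  generator's true signatures — a positive planted-edge PLV contrast and a
  positive CC contrast — rather than an efficiency increase that this
  class of generative model cannot produce.

Default amplitudes are 3 uV per band with 1/f noise scaled to the summed
band RMS, which yields sensor-level signals of roughly 5-20 uV SD after
projection — comfortably inside the +/-100 uV artifact-rejection bound
while leaving the rejection machinery non-trivial.

### Toy leadfield and EEG forward model

Sensors sit on a unit sphere (Fibonacci lattice); sources are drawn at
seeded random interior positions with radii 0.35-0.9. Gain decays with the
inverse square of the sensor-source distance (a single-layer spherical
conductor), and the matrix is scaled to unit mean column norm so projected
amplitudes stay physiological. This preserves exactly the structure the
inverse solvers care about — distance-dependent mixing and
depth-dependent column norms — while replacing anatomical head modelling
(BEM conductors, photon transport), which is out of scope. Localization
properties are therefore testable: sLORETA's zero localization error is
checked exhaustively, and depth weighting is checked to not hurt (and
typically help) deep-source localization.

### Hemodynamics

Slow ΔHbO/ΔHbR signals are drawn as unit-variance white noise band-passed
to 0.01-0.1 Hz (the band used for fNIRS connectivity), mixed by a matrix
square root of the target correlation matrix, and scaled to 1 umol/L (HbR:
0.4x). Physiological nuisance is added as sinusoids at the three
contaminant bands — Mayer waves (~0.1 Hz), respiration (0.25 Hz), cardiac
pulsation (1.7 Hz) — with default amplitudes 0.4/0.3/0.6 of the signal SD,
plus optional step artifacts (Poisson times, 5 SD) to exercise motion
repair. Signals are emitted as zero-mean concentration changes about an
implicit baseline, which is what makes the optics roundtrip exact (below).

## Preprocessing

The EEG chain is: zero-phase band-pass 1-45 Hz, anti-aliased downsampling
to 256 Hz, segmentation into non-overlapping 2-s epochs with +/-100 uV
rejection, robust bad-channel detection (variance and kurtosis outliers on
a median/MAD score with a sampling-noise floor, plus flatlines),
spherical-spline interpolation (order-4 Perrin spline, ridge 1e-5), and
common average reference. The stage order — filter, downsample,
epoch/reject, interpolate, re-reference — is fixed as the package's
convention; other orderings are defensible. Independent-component
denoising is a
deliberate no-op: component selection is a manual, visual step that cannot
be reproduced computationally, and the surrounding stages are unaffected.

Filters are Butterworth run forward-backward (`signal::filtfilt`) with
odd-reflection padding, because zero-state filtering leaves edge
transients on signals with nonzero boundary values. The EEG band-pass is
split into an order-4 high-pass and order-9 low-pass: a single order-4
band-pass cannot reach 40 dB stop-band attenuation at half the low edge
and at the 60 Hz line, and one very-high-order band-pass at a normalized
frequency of 1/500 is numerically fragile.

The fNIRS chain is: optical density conversion, temporal-derivative
motion repair, third-order zero-phase Butterworth band-pass 0.01-0.1 Hz,
and modified Beer-Lambert inversion at a 3.0 cm source-detector distance.
OD uses the *log-domain* (geometric) temporal mean as baseline,
`OD = -(log10 I - mean log10 I)`: with zero-mean planted concentration
changes this makes forward generation -> OD -> inversion an exact identity
(checked to 1e-10), which an arithmetic-mean baseline cannot achieve
(Jensen gap). Motion repair reweights the temporal derivative with Tukey's
biweight (tuning 4.685, MAD scale, iterated to 1e-6 or 50 iterations) and
reintegrates, preserving the channel mean; a 5 SD planted step is
suppressed by more than 80% while smooth hemodynamics pass through within
5% of their SD. Extinction coefficients at 730/850 nm are compiled
constants from the standard in-vitro hemoglobin spectra (in 1/(mM cm):
HbO 0.390/1.058, HbR 1.1022/0.6913); the differential pathlength factor
defaults to 6.0 at both wavelengths. Hemoglobin series can be aligned onto
EEG epoch-center timestamps by linear interpolation, never extrapolated.

## Inverse solutions

Sources are fixed-orientation (scalar), keeping the sLORETA
standardization scalar per source. With `K` the leadfield, `H` the
average-reference projector, and data average-referenced:

* **sLORETA**: minimum-norm estimate `J = K' (K K' + lambda H)^+ V`,
  standardized per source by the diagonal of the resolution matrix
  `R = K' (K K' + lambda H)^+ K`. The pseudo-inverse is required because
  `H` is rank-deficient. For a single noiseless source the standardized
  power peaks exactly at the true source for any `lambda >= 0`; the test
  suite verifies this exhaustively on an 8-sensor x 20-source problem.
* **wMNE**: `J = W K' (K W K' + lambda I)^+ V` with depth weights
  `w_s = ||k_s||^(-2 gamma)`, `gamma = 0.5` by default; `gamma = 0`
  reduces bitwise to the unweighted MNE.

`lambda` defaults to `trace(K K') / (m SNR^2)` with an assumed SNR of 3 —
the standard whitened-operator heuristic, adopted as the package's
convention. Source series are collapsed to ROIs by a
sign-aligned mean: members are flipped when they correlate negatively with
the ROI's first principal temporal component (preventing anti-phase
cancellation), and the ROI series sign is anchored to the first member.

For fNIRS the pipeline mixes ROI hemodynamics to channels through a
row-normalized toy sensitivity matrix, pushes them through the full optics
chain, and recovers ROI series with wMNE on the same sensitivity matrix —
the 45-channel/46-ROI mismatch is what makes the inverse solution
necessary for this modality.

## Connectivity

EEG: ROI series are band-limited with a zero-phase FFT mask (exact edges,
0.5 Hz raised-cosine transition — chosen over IIR filters because five
band-specific Butterworth designs at 256 Hz would each need their own
order/stability analysis), the analytic phase is taken per 2-s epoch with
10% of samples discarded at each epoch edge (Hilbert edge effects), and

    PLV = | mean_t exp(i (phi_i - phi_j)) |

is computed per epoch and averaged. Continuous and epoch-averaged PLV are
both in common use; epoch averaging matches the epoched preprocessing and
is the package's convention.

fNIRS: Pearson correlation between ROI hemoglobin series in the 0.01-0.1
Hz band, Fisher r-to-z transformed (`z = atanh r`, `|r| = 1` capped at
`atanh(1 - 1e-15)` to keep thresholding finite).

## Graph analysis

Weighted matrices are binarized by proportional thresholding across the
sparsity grid 0.09-0.50 in steps of 0.01 (42 levels): at sparsity `s` the
`round(s N (N-1) / 2)` strongest upper-triangle weights survive, with
deterministic weight-then-index tie-breaking, so edge sets are nested
across the grid. Per level the package computes the standard
binary-undirected metrics — nodal and mean clustering coefficient,
characteristic path length over reachable pairs (unreachable pairs are
excluded and counted; they contribute zero to efficiency), global/nodal
efficiency, nodal local efficiency (global efficiency of the
neighbor-induced subgraph — the definition the tests target; the
alternative nodal "closeness" efficiency is also computed and exported),
degree, and unnormalized Brandes betweenness. Small-worldness is
`sigma = (CC / CC_null) / (CPL / CPL_null)` against 100 degree-preserving
Maslov-Sneppen null networks per level (10 |E| attempted swaps each;
connectedness not enforced). Each metric curve is integrated over the grid
by the trapezoid rule without range normalization, so a constant curve of
1 integrates to 0.41. The metric definitions are the standard
binary-undirected ones used by the field's connectivity toolboxes, and are
verified against exhaustive brute-force oracles on all graphs with up to 6
nodes.

Shortest paths use a dense boolean-matrix BFS (fast for the <= 100-node
graphs used here); betweenness and degree-preserving rewiring use igraph.

## Group statistics

**Network-based statistic.** Edges are screened by two-sided paired t
tests at p < 0.001; suprathreshold edges are clustered into connected
components whose size is their edge count; the null distribution of the
maximal component size is built from per-subject sign flips of the paired
differences — the exchangeability unit of a paired design — vectorized
over all edges and permutations. Permutation p uses the +1 correction,
`p = (1 + #(null >= obs)) / (1 + n_perm)`, and the component threshold
defaults to 0.05/3, Bonferroni-accounting for the three connectivity
families tested (HbO, HbR, EEG PLV). At the study scale this uses 10,000
permutations; calibration tests run 500-1000 permutations on 100-200
simulated datasets, which bounds the type-I rate and detects a planted
five-edge component of standardized difference 1.5 with >= 80% power at
n = 16.

**Metric statistics.** Sparsity-integrated metrics are compared across the
three phases by one-way repeated-measures ANOVA
(`F = MS_condition / MS_error` on `(k-1, (k-1)(n-1))` degrees of freedom,
via `aov` with an `Error(subject)` stratum). No sphericity correction is
applied — the package's default — but the Greenhouse-Geisser
epsilon is reported for transparency. Nodal metrics are corrected across
the 46-ROI family (per band and metric) by Benjamini-Hochberg FDR;
pairwise phase contrasts use paired t tests with Bonferroni adjustment
(x3, capped at 1). Degenerate inputs are handled explicitly: a perfectly
additive subject x phase table (zero error mean square with unequal means)
is flagged and reported at p = 0; identical phases give p = 1.

## Problem sizes used by tests and the acceptance script

Test and acceptance runs scale the study down while keeping the design
shape: 4-8 subjects, 10-24 s per phase at 256 Hz native rate, the theta
band, 20 null networks per sparsity level, and 200-2000 NBS permutations;
the NBS calibration simulations use the full 16-subject, 46-node design
with 500-1000 permutations, and the end-to-end recovery check uses 8
seeded pipeline runs with a planted effect size of 0.7. The acceptance
script's fNIRS arm runs at the full study scale (16 subjects, 120/60/120 s
phases) because the 0.01-0.1 Hz band yields only ~2 effective samples per
10 s. The demonstration hemodynamic effect is an equicorrelated five-region
block (increment 0.6, ten edges): a chain of high pairwise correlations is
not a valid correlation matrix beyond r of about 0.58, whereas an
equicorrelated block is valid for any increment below 1, and its ten edges
give the network-based statistic a connected target that survives the
inverse solution's correlation attenuation. These sizes are
the package's choices for routine verification; all defaults remain at the
study scale (16 subjects, 120/60/120 s phases, 1000 Hz, five bands, 100
nulls, 10,000 permutations).

## What passing tests do and do not show

The generator emulates band-limited oscillations with controllable
synchrony, correlated slow hemodynamics with realistic contaminants, and
linear sensor forward models. It does not emulate volume-conduction
leakage structure of real anatomy, non-sinusoidal or cross-frequency
dynamics, hemodynamic response functions coupling the two modalities, or
non-stationary artifacts beyond steps and spikes. Passing tests therefore
certify the *computational* correctness and calibration of the pipeline —
filters meet their specifications, inverse solutions localize on toy
geometry, estimators hit known ground truth, permutation inference
controls its error rate — not that the pipeline would reproduce any
particular clinical finding.

## Known limitations

* Planted multi-edge EEG effects are community effects (see above);
  edge-disjoint planted pairs are exact.
* The ROI-level fNIRS analysis assumes the toy sensitivity matrix is known
  to the inverse stage; with real optode geometry the mismatch between
  true and modeled sensitivities adds error that the synthetic study does
  not exhibit.
* SNIRF and EDF+ annotation containers are not read natively; EEG I/O is
  16-bit EDF plus a BIDS-style events TSV sidecar, and fNIRS I/O is a
  columnar TSV bundle.
* Betweenness is unnormalized and only comparable within a graph.
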