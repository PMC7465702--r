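---
title: "Methods: an SMR BCI-FES pipeline on synthetic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an SMR BCI-FES pipeline on synthetic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrfes)
```

## The problem

A sensorimotor-rhythm (SMR) brain–computer interface detects the
attenuation of mu (8–12 Hz) and beta (18–26 Hz) oscillations over motor
cortex — event-related desynchronization (ERD) — that accompanies motor
imagery (MI), and uses it to drive functional electrical stimulation (FES)
of a paralyzed hand. This package implements the full computational chain
for a two-class single-hand task (slow one-time grasping, SOG, 1/3 Hz,
versus fast cyclic opening, FCO, 1 Hz) in both an offline, cue-based
setting and a semi-asynchronous online control loop, and pairs it with a
synthetic EEG generator so that every stage is testable against known
ground truth. No raw patient EEG is available for the study population the
pipeline models; the generator is the package's substitute for it and is
first-class, tested code.

## The synthetic EEG model

Each 12-s trial (rest 2.5 s, reference 2.5 s, MI 3 s, FES initiation 1 s,
feedback 3 s; 3072 samples at 256 Hz) is built per channel as

* **1/f background**: Gaussian noise spectrally shaped as
  $f^{-\beta/2}$ with `background_exponent` $\beta = 1$ and standard
  deviation `noise_sd` = 10 µV — a typical broadband EEG floor;
* **rhythms**: constant-amplitude sinusoidal carriers, one per band, at a
  trial-specific random frequency drawn from the interior of the mu and
  beta bands, scaled by a per-channel amplitude (`rhythm_amplitude`,
  default 5 µV RMS at C3/CP3, decaying over the motor topography). A
  carrier rather than band-limited noise keeps within-trial power stable,
  so reference-versus-MI power comparisons estimate the ERD cleanly; the
  carrier frequency still varies across trials. This is the main
  deliberate departure from real EEG, whose rhythm amplitude fluctuates;
* **ERD**: during the MI period the rhythm envelope is multiplied by
  $1 - d\,m(t)$, where $d$ is `erd_depth` (class × channel) and $m(t)$ is
  a raised-cosine modulation at the class rate (SOG 1/3 Hz, FCO 1 Hz).
  ERD is attenuation of an ongoing rhythm, hence multiplicative, not
  additive. Defaults make SOG the deeper desynchronization (0.6 at C3 vs
  0.25 for FCO): the class contrast the decoder must find is an ERD
  *magnitude* difference plus the modulation-rate difference;
* **artifacts**: stereotyped biphasic blinks (~300 ms, `blink_amplitude`
  80 µV) on frontal channels at Poisson times (`blink_rate` 4/min), and a
  biphasic FES pulse train (`fes_pulse_rate` 35 Hz,
  `fes_artifact_amplitude` = 10× the peak rhythm amplitude) during FES
  initiation and, when stimulation continues, the feedback period.

The contralateral focus is fixed at C3/CP3 (an assumed right-hand task)
and configurable. Every generator is a pure function of its inputs and a
seed.

**What a green test establishes.** The generator reproduces the
statistical structure the pipeline assumes — band-limited rhythms,
multiplicative ERD, spatial focality, artifact contamination — but not
volume conduction, patient-specific lesions, amplitude non-stationarity of
real rhythms, or realistic FES artifact spectra. Passing tests certify the
*algorithms* against this stated world, not clinical performance.

One measurement subtlety the tests respect: a single-window periodogram of
carrier + noise contains a coherent cross term, so per-trial band-power
estimates fluctuate far more than the noise power alone suggests.
Zero-ERD equivalence of reference and MI power is therefore asserted on
trial-averaged power, which is the estimator the ERD/ERS map uses anyway.

## Preprocessing

Filters are zero-phase to keep period boundaries aligned: the 60 Hz notch
is a biquad (Q = 30) run forward–backward; the 1–29 Hz band-pass and the
seven 4-Hz sub-band filters are odd-length Hamming windowed-sinc FIRs
applied by centered FFT convolution with reflection padding. The default
FIR length scales as ≈ 3.3·fs/(2·f_low) so the transition band stays below
the low edge. Because the seven sub-band prototypes tile 1–29 Hz, their
sum equals the single 1–29 Hz design up to ripple — a reconstruction
property the tests exploit.

Trial rejection uses three statistics per trial: peak amplitude against a
150 µV limit, and session-level z-scores (limit 3 SD) of the Shannon
entropy of the 20-bin amplitude histogram and of excess kurtosis. The
entropy estimator is a surrogate: the toolbox this emulates names the
criteria without formulas. A trial tripping several criteria is reported
once, with priority amplitude > kurtosis > entropy (heavy-tailed
contamination usually trips both shape statistics; kurtosis is the more
specific name for it).

PCA retains the smallest channel-space basis explaining 95 % of variance.
ICA cleaning is a symmetric fixed-point algorithm (tanh contrast) with
deterministic seeding; components are flagged automatically by absolute
correlation (> 0.7) of their time course with a frontal template — the
original procedure used visual inspection, which is not reproducible. ICA
refuses to run in online mode, matching the real-time constraint. The
surface Laplacian is the discrete small-Laplacian (channel minus neighbor
mean over a montage adjacency list), applied by default only to the
reference + MI segment that feeds ERD/ERS analysis; spherical-spline
estimators are out of scope.

## Features and classification

Band power is the sum of Hamming-windowed periodogram bins over a 640-point
(2.5 s) window, normalized so full-band power matches signal variance;
ERD/ERS is $(A - R)/R \times 100$ with reference-period $R$ and MI-period
$A$ averaged over trials before the ratio.

CSP per sub-band: per-trial covariances are trace-normalized *before*
averaging (so every trial contributes equal total power), the composite
covariance is whitened via its eigendecomposition, and the whitened
class-1 covariance is eigendecomposed; rows of the projection are ordered
by descending class-1 eigenvalue and the first/last `selected_pairs`
(default 1) are kept, giving log-variance features. A printed form of this
construction circulating in the application literature ("W = UᵀλU_cᵀ") is
not a valid projection; the standard whitening construction is what is
implemented. Rank-deficient composite covariances are ridge-regularized by
1e-8 × trace and logged. Fusion weights default to a softmax of per-band
cross-validated accuracies (temperature 0.05): the fusion rule itself is
unspecified in the source literature, and this choice concentrates weight
on informative bands while remaining smooth. A fused score of exactly zero
resolves to SOG for reproducibility.

The classifiers are Fisher LDA (pooled-covariance solve, ridge fallback)
and a least-squares SVM with quadratic kernel $(x^\top y + 1)^2$ and
regularization γ = 1 — neither constant is stated in the source
literature; these are the common defaults. Features are standardized
inside the SVM because the squared kernel otherwise lets raw magnitudes
swamp the regularization term. The ensemble weights member votes by their
normalized cross-validated accuracies (stratified folds, fixed seed); ties
go to the heavier member; an optional feature-union mode stacks member
scores into a logistic combiner but is off by default. The "true chance
level" is the exact binomial bound: the $(1-\alpha)$ quantile of
$\mathrm{Bin}(n, 1/K)/n$. Note that this quantity is *not* globally
monotone in $n$ (discrete quantiles wobble with parity); the property test
asserts the decreasing trend on a doubling grid.

## Pooled-mean adaptation

PMean tracks the running feature mean, $\mu_t = (1-\eta)\mu_{t-1} + \eta
x_t$ with η = 0.1, and recenters the linear classifier's bias at
$-w^\top\mu_t$; weights are untouched, and the SVM member is left
unadapted (the update is defined for a linear bias). Updates are
unsupervised, one per decision window, and begin after the first 10 trials
of a session. In the control loop the reference mean $\mu_0$ per role
comes from a short drift-free calibration run — the analogue of the
cue-based training session that precedes online use, and the quantity a
deployed system would carry over in its fitted classifier. This matters
because the per-role decision streams are not symmetric (the hold step
yields many more "keep" windows than the stop step yields "stop" windows),
so a zero reference would mis-center the threshold.

## The semi-asynchronous control loop

The fixed sequence OPEN → STOP-FES → (move) → GRAB → (move ball) → HOLD is
self-paced: each BCI-gated step polls 1-s decision windows. For trigger
steps, an SMR detection switches the role to ACT *on the same window's
features* (two classifier evaluations, one feature vector); an ACT match
activates FES and records the latency; a mismatch reverts to SMR; a missed
detection is a delay. Any step auto-triggers after the 6-s maximum
analysis time, which also guarantees liveness. Stopping FES is decided by
the SMR detector reporting absence of MI (there is no separate rest
classifier), the timeout applies there too, and a 10-s break (no
classification) always follows. The hold step requires 6 correct
keep-decisions for 100 % — the 6-s analysis window at 1-s cadence — with
the count configurable, since a 5-s FES activation could also justify 5.

Metrics: completion rate interpolates linearly between the two anchors
(success at the first decision → 100 %, timeout → 0 %); only the endpoints
are fixed by the protocol, and linear-in-delay is the simplest consistent
choice. Semi-asynchronous accuracy is correct/(correct + error) with SMR
delays excluded — they cost time, not corrections — and a flag restores
the delay-inclusive denominator. Steps 1 and 3 pool into the No-FES
condition, 2 and 4 into Yes-FES. ITR uses the Wolpaw formula with the
decision rate taken from the actual 1-s cadence.

## The virtual subject

FSM and adaptation tests need decisions without EEG decoding. A virtual
subject emits one scalar feature per window, $x = s\,d/2 + \delta t +
\varepsilon$, with signed truth $s$, separation $d = 2\Phi^{-1}(p)$
calibrated to the per-role correct-decision probability $p$, per-trial
drift $\delta$, and unit Gaussian noise. Thresholding at zero reproduces
$p$ exactly; drift degrades it; PMean tracking of the stream restores it.
The drift-compensation property is exercised at δ = 0.5 (~a quarter of the
class separation per trial), chosen so that a 20-trial session visibly
degrades without adaptation; with slow drift the before-adaptation block
is barely affected and the before/after comparison is uninformative.

## Reference tables and known print inconsistencies

The bundled per-subject tables from the original eight-patient experiment
drive the aggregation and t-ratio arithmetic (df = 7). Two of their
printed averages disagree with their own entries: the grasping completion
column (printed 55.7, entries give 60.7) — left unasserted — and a few
cells that differ by one unit in the last digit from exact re-rounding
(e.g. 53.44 vs recomputed 53.45), which the acceptance tests absorb with a
one-last-digit tolerance. The published chance levels for this protocol
(57.43 %, 50.15 %, 53.77 %) cannot be reconciled with a unique trial
count under any standard formula, so the implementation exposes `n` and
`alpha` explicitly and asserts none of them.

## Numerical choices and limitations

Filter assertions use steady-state RMS away from edges; EDF+ export
quantizes to 16 bits over ±200 µV (step ≈ 0.006 µV) and clips outside the
range; JSON serialization keeps full precision, rounding happens at
display only. Known limitations: the generator's stationary-amplitude
rhythms understate single-trial power variability; the ICA flagging
criterion is template-based and will miss artifacts uncorrelated with the
frontal template; multi-class (> 2) imagery, Riemannian/FBCSP feature
variants, spherical-spline Laplacians, FES hardware control, and any
inference on real patient data are out of scope.
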