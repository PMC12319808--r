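---
title: "Methods: corticothalamic simulation and spectral parameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corticothalamic simulation and spectral parameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, parameter choices and known
limitations of `ctspec`, in the order the pipeline runs them.

## The corticothalamic model

Four neural masses are simulated: cortical excitatory (`e`), cortical
inhibitory (`i`), thalamic relay (`s`) and thalamic reticular (`r`). Each
population's mean membrane potential obeys a second-order synaptodendritic
filter

$$\frac{1}{\alpha\beta}\ddot V_j + \Big(\frac1\alpha+\frac1\beta\Big)\dot V_j
  + V_j = \sum_k \nu_{jk}\,\phi_k(t-\tau_{jk}),$$

where $\alpha$ and $\beta$ are the inverse decay and rise times of the
potential evoked by an impulse and $\nu_{jk}$ (mV·s) is the coupling from
population $k$ to $j$. Potentials convert to rates through the sigmoid
$Q = Q_{max}/(1+\exp(-\pi(V-\theta)/(\sigma\sqrt3)))$; the $\sqrt3$ matches
a logistic to a Gaussian threshold spread of standard deviation $\sigma$.
The cortical excitatory field obeys the damped wave operator
$(1/\gamma^2)\ddot\phi_e + (2/\gamma)\dot\phi_e + \phi_e = Q_e$ — the
spatial Laplacian is set to zero, i.e. only the spatially uniform *global
mode* is studied — while the compact populations have $\phi = Q$. Three
transcription slips in the printed source equations are corrected here and
flagged rather than reproduced: the membrane equation requires $+V_j$ (not
$+1$) on its left side for dimensional consistency, the sigmoid denominator
is $\sigma\sqrt3$ (not $\sigma 3$), and the wave operator is normalized to
unit zero-frequency gain.

Three structural conventions matter and are deliberate:

* **Connectivity of the inhibitory population.** No separate couplings to
  `i` exist in the parameter table; under the standard random-connectivity
  assumption it receives the same afferents as `e` ($\nu_{ie}=\nu_{ee}$,
  $\nu_{ii}=\nu_{ei}$, $\nu_{is}=\nu_{es}$), which makes $V_i = V_e$
  dynamically. It is still integrated separately so perturbed
  configurations remain possible.
* **Delay placement.** The corticothalamic return time is $t_0 = 80$ ms;
  half of it ($40$ ms) is placed on each of the `e`→`r`, `e`→`s`, `s`→`e`
  and `s`→`i` projections, none within cortex or within thalamus. Any loop
  cortex→thalamus→cortex then accumulates exactly $t_0$.
* **Which trace is "EEG".** The global mean membrane voltage of the
  cortical excitatory population, `v_e`, is the default analysis trace,
  with the field `phi_e` selectable. The choice is *not* innocuous: the
  wave operator multiplies the field's spectrum by an extra
  $|1+i\omega/\gamma|^{-4}$, steepening the high-frequency aperiodic slope
  by roughly 2 (measured: exponent over 10–50 Hz ≈ 2.9 for `v_e` versus
  ≈ 5.5 for `phi_e` at normative parameters). `v_e` is the physiologically
  stated EEG proxy and is used throughout.

### Integration and noise

Explicit Euler–Maruyama on the first-order companion form, `dt = 1 ms` by
default; the delay is a ring buffer of $t_0/(2\,dt)$ steps, and the
configuration validates that this is a whole number. Histories are
initialized at the numerically solved fixed point; the first 5 s are
discarded (configurable), and the default run keeps 60 s — one trial of the
study design the analysis settings assume. The relay's stochastic drive is
$\nu_{sn}(\bar\phi_n + \xi_t)$ with $\xi_t$ i.i.d. Gaussian of per-sample
standard deviation `noise_sd` (default 0.5 s⁻¹), so its one-sided spectral
density is $2\,\mathrm{sd}^2\,dt$; this discrete convention is also what
the linearized oracle assumes. Traces are guarded (default $10^4$):
crossing the guard raises a divergence error, or flags the run when called
from a sweep.

### Operating point and stability

The drive mean sets the fixed point, and the fixed point sets the loop
gains. At the normative couplings the fixed point is stable only for drive
means below roughly 0.5 s⁻¹; above that a Hopf bifurcation produces a
self-sustained ~9.4 Hz limit cycle whose amplitude is independent of the
noise level. The package defaults to `noise_mean = 0`, well inside the
stable regime, where the alpha rhythm is a noise-driven damped resonance —
the regime in which spectral parameterization of a 1/f background plus
peaks is meaningful, and in which the linearized oracle applies. The
steady-state solver exploits sigmoid boundedness: for a given $V_e$ the
thalamic pair reduces to a bracketed scalar root, and $V_e$ itself is
bracketed by a sign-change scan; the low-firing branch is returned when
several fixed points coexist, and the residual must pass $10^{-9}$.

### The linearized oracle

`linearized_spectrum()` is an independent closed form used to verify the
integrator: the model is linearized about the fixed point (sigmoid slopes
as gains), and the response of `v_e` (or `phi_e`) to the relay noise is
assembled per frequency from the dendritic filter
$1/((1+i\omega/\alpha)(1+i\omega/\beta))$, the wave operator
$(1+i\omega/\gamma)^2$, and $e^{-i\omega t_0/2}$ delay factors, solving a
4×4 complex system per frequency. Agreement is checked as the median
relative error over 4–40 Hz (excluding one resolution width around the
alpha peak, where small frequency offsets dominate). At `dt = 1 ms` the
explicit Euler scheme leaves a measurable discrete-time bias (~35% median);
at `dt = 0.5 ms` agreement is ~13%, which is near the multitaper estimation
floor for 45 tapers. The oracle-equivalence check therefore runs at
`dt = 0.5 ms`.

## Multitaper spectra

`multitaper_psd()` averages one-sided eigenspectra over DPSS tapers after
linear detrending. The half-bandwidth is given in Hz (default 0.6), so a
60-s epoch has time–bandwidth product 36; taper counts are settings, not
derived (45 for 60-s epochs, 5 for 5-s prestimulus epochs, per the study
convention), with the $2TW-1$ concentration bound enforced. The tapers are
computed from the Slepian tridiagonal eigenproblem via LAPACK's bisection
and inverse-iteration routines. One numerical subtlety is handled
explicitly: at epoch lengths above ~10⁵ samples the tridiagonal spectrum's
symmetric/antisymmetric pairs are degenerate to machine precision and naive
inverse iteration returns invalid mixtures; the matrix is therefore folded
into its even and odd half-problems (well-separated eigenvalues) and the
eigenvectors unfolded. The implementation is validated against an
independent reference implementation of Slepian sequences (frozen values in
the test suite) and against white-noise flatness and Parseval identities.

## Spectral parameterization

`fit_spectral_model()` decomposes $\log_{10}$ power over the fit range
(default 4–40 Hz) into a power law $b - X\log_{10}f$ plus Gaussian peaks
$a\,\exp(-(f-c)^2/2\omega^2)$, following the standard iterative scheme:

1. *Robust aperiodic fit*: least squares, flattening, retention of the bins
   whose positive residual is at or below the 2.5th percentile, refit.
2. *Peak extraction*: repeatedly take the maximum of the flattened
   spectrum while it exceeds `peak_threshold` (2.0) standard deviations of
   the current residual and `min_peak_height` (0.0); guess the width from
   the half-height crossing (clipped to half the configured width limits,
   0.25–6 Hz in sd units); fit that single Gaussian to the residual and
   subtract it. Candidates within one guessed sd of the range edge are
   dropped, overlapping candidates (closer than 0.75 sd) pruned in favor of
   the taller, and the survivors refit jointly by bounded
   Levenberg–Marquardt (centers constrained to ±3 guessed sd).
3. *Refinement*: the peak set is decided once, in step 2; afterwards the
   aperiodic component is refit on the peak-removed spectrum and the
   Gaussians refit on the re-flattened one, alternating to convergence
   (tolerance $10^{-5}$, at most 8 passes). Re-deciding the peak set each
   pass was tried and rejected: it makes the decomposition bistable, so
   that nearly identical spectra can land on different peak counts, adding
   avoidable jitter to parameter sweeps. With the set fixed the iteration
   is continuous and contracts geometrically; on noiseless model spectra it
   recovers all five parameters to ~10⁻⁵.

Two intentional differences from the common reference implementation of
this algorithm: each candidate Gaussian is *fitted* to the residual before
subtraction (rather than subtracting the raw guess), and the
aperiodic/periodic alternation of step 3 runs to convergence rather than
once. Both remove systematic residue that otherwise seeds spurious
candidates. With `min_peak_height = 0` (the study's setting) small
noise-scale peaks are still accepted by design; on fine frequency grids
roughly half of peak-free epochs yield some sub-0.15 log₁₀-unit "peak"
somewhere in the alpha band. Downstream analyses are insensitive to these
(alpha power enters as the fitted log-height, and the missingness filter
uses counts of detected peaks), but users wanting sparser peak lists should
raise `min_peak_height`.

Alpha "power" downstream always means the Gaussian height $a$ in log₁₀
power units *above the aperiodic fit*, never linear band power. When
several peaks fall in 8–12 Hz, the one with maximum height is selected.

The fit range excludes 0 Hz by construction (log frequency) and the model
operates strictly inside `freq_range`. Knee mode
($b - \log_{10}(\kappa + f^X)$) is implemented for completeness but the
fixed mode is the supported, tested path.

## Mixed models

`fit_global_lmm()` fits, by REML,
`task ~ prestimulus + arousal * valence` with by-subject random intercepts
and random slopes for arousal and valence (ratings used raw on the 1–9
scale; within-subject centering is deliberately not applied, matching the
model's literal form). Marginal F-tests use Satterthwaite denominator
degrees of freedom via `lmerTest`. A singular fit (a variance component
estimated at zero) is a valid REML solution and is kept but recorded;
only actual optimizer failure triggers the documented fallback sequence
(uncorrelated slopes, then intercept-only), recorded in the result.
`fit_cluster_lmm()` interacts the prestimulus covariate, arousal and
valence with the electrode cluster (so each cluster has its own slope)
plus a global arousal×valence term, with the same random structure;
per-cluster slopes are reported as Wald statistics with Holm-adjusted
p-values, the Holm family being all cluster×arousal and cluster×valence
contrasts of that one response model. A single-cluster input collapses, by
construction, to the global model. Trial filtering drops trials with
non-positive task exponent and subjects with fewer than `min_alpha_trials`
(default 10 of 40; the criterion behind the reported subject exclusions is
not published, so the threshold is exposed as configuration) alpha-peak
trials, reporting every exclusion with its reason.

Cluster reduction uses the first principal component of each cluster's
channels-by-time matrix per trial (channels centered over time; loading
sign fixed so loadings sum positive; loadings returned for mapping
estimates back to channels). Averaging PSDs across channels, rather than
averaging time series before the PSD, is the default for whole-head
features: it is robust to phase cancellation across sensors.

## The synthetic study generator

`generate_study()` emulates the *statistical* structure of a DEAP-shaped
affective study: 32 subjects × 40 trials, continuous arousal/valence
ratings drawn from a clipped normal (mean 5, sd 2) on 1–9, per-subject
random intercepts and slopes, prestimulus features sharing the subject
intercept (so the task–prestimulus coupling β₁ is recoverable), and task
features generated from exactly the mixed-model structure the estimator
assumes. Defaults with published provenance: arousal→exponent effect
0.0162; prestimulus couplings 0.2587 (exponent) and 0.2017 (offset);
subject intercept sds 0.2770 / 0.3507 / 0.2669 (exponent / offset /
alpha). The remaining defaults are this package's own choices and have no
external provenance: arousal→offset +0.01 and arousal→alpha −0.01 (signs
matching the observed directions), all valence effects 0, random slope sds
0.005, residual sds 0.18 / 0.18 / 0.25 (the exponent value back-derived
from the scale of the published F statistics), 5% of trials with an
undetected alpha peak. What the generator does *not* emulate: artifacts
and their removal, non-Gaussian residuals, rating–rating correlation,
temporal drift within a session, and any genuine biophysical link between
ratings and spectra — so passing recovery tests validates the estimation
chain, not the neuroscience.

`synthesize_epoch()` inverts the spectral model: white noise is shaped in
the frequency domain to the aperiodic spectrum $10^b/f^X$, and an
independent narrowband component is shaped to the *linear difference*
$10^{L+G} - 10^L$. Because independent components add in power, the sum's
expected PSD equals the log-additive model exactly, and the alpha
log-height equals $a$ in closed form — no numerical amplitude calibration
is needed (a numerical calibration step was considered and dropped for
this reason). The synthetic sampling rate defaults to 256 Hz rather than a
hardware-style 512 Hz to halve the cost of full-pipeline runs; parameter
recovery is verified to be invariant to doubling `fs`.

## Problem sizes and observed performance

The validation suite uses: 60-s simulated epochs at 1 kHz for the
normative run and sweeps (8 points per coupling, three couplings); one
oracle-equivalence run at 0.5 ms steps; 20-seed Monte-Carlo round trips of
60-s synthetic epochs at 256 Hz; and 100 coverage replicates plus 100 null
replicates of 28-subject × 40-trial studies for the mixed model. Observed
on one CPU: full suite ≈ 1–2 minutes. At those sizes the measured results
are: alpha peak of the normative spectrum at 9.2–9.3 Hz across seeds;
monotone sweep trends (exponent up, signed offset up, alpha power down
with increasing net relay inhibition; one-sided Spearman tests all
p < 0.05); oracle agreement ≈ 13% median relative error; noiseless
parameter recovery to ~10⁻⁵; Monte-Carlo mean errors ≈ 0.05 (exponent) and
≈ 0.12 Hz (alpha center); mixed-model coverage 0.95, relative bias ≈ 2.5%,
Holm familywise null rate 0.03.

Two caveats deserve emphasis:

* **The 10–50 Hz aperiodic slope.** A commonly cited expectation for EEG
  is an aperiodic exponent near 2 over 10–50 Hz. At the normative
  parameter values this model yields ≈ 2.9–3.0 (and the exact linearized
  spectrum, free of integration and estimation error, gives ≈ 3.4): with
  $\alpha = 50$ s⁻¹ and $\beta = 240$ s⁻¹ the dendritic-filter corners (8
  and 38 Hz) sit at or below that window, contributing ≈ 2.3 on their own,
  and the closed thalamocortical loop steepens it further. The
  corresponding check in the acceptance suite is left failing rather than
  loosened, with this analysis as the explanation.
* **Offset direction is unit-dependent.** Scale equivariance means
  multiplying a spectrum by $k$ shifts the offset by $\log_{10}k$; the
  *absolute value* of the offset therefore has no unit-free direction of
  change. The invariant statement, and what the sweeps test, is that the
  signed offset increases with net relay inhibition (at these noise
  scales the offsets themselves are negative).

## Other limitations

Spatially resolved fields (the Laplacian term), receptor-resolved
inhibition (GABA-A vs GABA-B time scales), and fitting the model to
empirical spectra (e.g. by simulation-based inference or a Fourier-domain
solution) are out of scope. Real EEG enters only through delimited numeric
epoch tables (`read_epoch_table()`); binary acquisition formats are not
parsed. The limit-cycle regime above the Hopf bifurcation is simulated
faithfully (bounded, flagged only if the guard is exceeded) but its
spectra are dominated by the oscillation and its harmonics, and the
aperiodic/periodic decomposition is not a meaningful summary there.
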