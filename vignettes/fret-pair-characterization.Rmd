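---
title: "Characterizing FRET acceptors for mTurquoise2: models and methods"
author: "fretchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing FRET acceptors for mTurquoise2: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretchar)
```

# Scope

`fretchar` implements the computational workflow used to characterize
fluorescent proteins as FRET (Förster resonance energy transfer) acceptors
for the cyan donor mTurquoise2:

1. **Förster theory from spectra** — overlap integral $J(\lambda)$ and
   Förster radius $R_0$;
2. **frequency-domain FLIM** — per-pixel phasor estimation from homodyne
   phase stacks, reference calibration, phase/modulation lifetimes and the
   lifetime-based FRET efficiency;
3. **spectral unmixing** — decomposition of single-cell emission spectra
   into donor, sensitized-emission, green-contaminant and direct-excitation
   components, and the apparent efficiency $E_D$;
4. **trace analysis** — photobleaching curves, ratiometric biosensor
   step responses and relative brightness;
5. **a synthetic-data generator** that emulates all of these inputs with
   known ground truth, so every stage is testable without a microscope.

Cell biology (cloning, transfection, oligomerization assays) and microscope
control are out of scope; the package starts from spectra, phase stacks and
intensity traces.

# Förster theory

For an area-normalized donor emission shape $f_D(\lambda)$ and the acceptor
extinction spectrum $\varepsilon_A(\lambda)$ (peak-normalized absorbance
scaled to $\varepsilon_{max}$ in M$^{-1}$cm$^{-1}$), the overlap integral is

$$J = \int f_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,d\lambda
\quad [\mathrm{M^{-1}cm^{-1}nm^4}],$$

and the Förster radius in Ångström is

$$R_0^6 = 8.79\times10^{-5}\,\kappa^2 n^{-4} Q_D\, J .$$

Defaults are the conventional isotropic orientation factor
$\kappa^2 = 2/3$, aqueous refractive index $n = 1.33$ and the mTurquoise2
quantum yield $Q_D = 0.93$. With these constants and the published overlap
integrals of the fourteen-acceptor panel bundled in `acceptorConstants()`,
`reproduceTables()` recovers every published $R_0$ after rounding
(round-half-up, matching the printed integer Ångström precision):

```{r}
rep <- reproduceTables()
all(rep$R0_match)
```

Numerical choices: $J$ is integrated trapezoidally on a 1 nm grid spanning
the union of the two spectral supports; spectra are never extrapolated
(values outside the measured support are zero). A 1 nm grid agrees with a
0.01 nm brute-force integral to better than $10^{-3}$ relative for
realistic band widths, and reproduces the printed radii to integer
Ångström. Transfer efficiency versus distance is
$E(r) = 1/(1 + (r/R_0)^6)$, and `simulatePairSpectrum()` produces the mixed
emission $(1-E)\,Q_D f_D + (E + d)\,Q_A f_A$ for a direct-excitation
fraction $d$.

# Frequency-domain FLIM

A homodyne acquisition records $K \ge 3$ frames at detector phase steps
$\theta_k$; each pixel follows
$I_k = DC + AC\cos(\theta_k - \varphi)$. `fitPhasor()` solves this by
linear least squares on the $(1, \cos\theta_k, \sin\theta_k)$ design, which
reduces to the first-harmonic discrete Fourier coefficients for equally
spaced steps and handles pseudorandom acquisition orders and missing frames
identically — estimates are invariant to the temporal order in which phase
steps were visited. Pixels with $AC/DC < 10^{-3}$ are flagged *undefined*
(the phase of a flat signal is arctan noise) instead of propagating NaN.

Calibration uses a reference of known lifetime (e.g. mTurquoise2 with
3.8/4.0 ns phase/modulation lifetimes, Erythrosin B at 0.086 ns, or
reflected excitation at 0 ns): the instrument phase offset and modulation
factor are those that map the measured reference phasor onto its theoretical
$\varphi = \arctan(\omega\tau)$, $M = 1/\sqrt{1+(\omega\tau)^2}$. Calibrated
phasors convert to lifetimes via

$$\tau_\varphi = \tan(\varphi)/\omega, \qquad
  \tau_M = \sqrt{1/M^2 - 1}\,/\,\omega, \qquad \omega = 2\pi f .$$

For mono-exponential decays $\tau_\varphi = \tau_M$; lifetime mixtures pull
$\tau_\varphi$ below $\tau_M$. Region averaging is always done in
rectangular phasor coordinates $(G, S) = (M\cos\varphi, M\sin\varphi)$, not
on lifetimes, because lifetimes are nonlinear in the phasor and per-pixel
noise would bias region means. The FRET efficiency from donor quenching is
$E = (1 - \tau_{DA}/\tau_D)\cdot 100\%$; the unquenched donor references
are the measured 3.77 ns (phase) and 4.01 ns (modulation) cohort values
rather than the nominal 3.8/4.0 ns calibration constants — the published
efficiency columns are only reproduced with the measured values.

Recomputing the efficiencies from the published lifetime table:
all fourteen phase-lifetime efficiencies match, and twelve of fourteen
modulation-lifetime efficiencies match. For TagRFP-T and mScarlet-I the
published $\tau_M$ and $E_{\tau M}$ columns are mutually inconsistent (no
value of $E = 1 - \tau_M/4.01$ rounds to the printed percentage), so these
two are reported as mismatches by `reproduceTables()` rather than forced:

```{r}
rep[!rep$E_mod_match, c("name", "E_mod_calc")]
```

`roiLifetimeTimecourse()` chains background subtraction (mean over a
background mask, per frame), an optional 3×3 mean blur (replicated edges),
the phasor fit, calibration, ROI phasor averaging and lifetime conversion —
the pipeline used for biosensor activation time courses, where the change
in phase lifetime after agonist/antagonist addition is the readout.

# Spectral unmixing and the apparent efficiency

Single-cell spectra are acquired twice: under donor excitation
($F(\lambda)$) and under acceptor excitation. $F$ is normalized to the
peak of the acceptor-excitation spectrum; because direct acceptor
excitation scales with acceptor abundance, which the acceptor-excitation
spectrum measures, an acceptor-only control normalized the same way can be
subtracted directly to remove the direct-excitation contribution.

The corrected spectrum is decomposed by non-negative linear regression
(components are photon counts, so negative coefficients are physically
meaningless) against area-normalized reference shapes. The fit range
depends on the acceptor class: green/yellow acceptors use donor + acceptor
shapes over 450–650 nm; orange/red acceptors with a green maturation
contaminant use donor + EGFP shapes over 450–525 nm (where the acceptor
does not emit) with the sensitized emission as the remainder; red acceptors
without a green component use the donor shape alone over 450–500 nm.
Outputs are rescaled to the unmixed donor peak for presentation; the
efficiency estimator is scale-invariant, so this is cosmetic.

The wavelength-resolved apparent efficiency is

$$E_D(\lambda) = 1 - \frac{F_D(\lambda)}
 {\frac{Q_D f_D(\lambda)}{Q_A f_A(\lambda)} F_S(\lambda) + F_D(\lambda)},$$

whose denominator reconstructs the total (unquenched) donor emission from
the sensitized emission via the quantum-yield ratio. For any exact mixture
of the reference shapes $E_D(\lambda)$ is constant in $\lambda$; in noisy
data the spectrum edges deviate, so a weighted average with
$w(\lambda) = f_D(\lambda) f_A(\lambda)$ is taken over a flat region.

**Flat-region default.** The evaluation region keeps wavelengths where both
reference shapes exceed 1% of their maxima, intersected with the 450–650 nm
acquisition window, and always excludes wavelengths where
$f_A < 10^{-6}\cdot\max f_A$ (the quantum-yield ratio would blow up there,
which the weighting alone does not fully suppress). The region is
deliberately *not* intersected with the regression fit range: for red
acceptors the fit range (450–500 nm) contains essentially no acceptor
emission, so that intersection would always be empty — the fit range
controls the regression only, while $E_D$ must be evaluated where both
donor and acceptor actually emit. The region is user-overridable.

# Trace analysis

Two-channel (donor/acceptor) time series are background-subtracted and
normalized per channel to the mean of the first $n$ frames ($n = 1$ for
bleaching curves, $n = 5$ for biosensor recordings); the operation is
idempotent. Percent-remaining values are read at the nearest acquired frame
at or before the probe time (no interpolation — acquisition is
frame-based). During acceptor photobleaching the donor channel *rises*
(dequenching): with acceptor survival $a(t)$ and initial efficiency $E_0$,
the normalized donor equals $(1 - E_0 a(t))/(1 - E_0)$, which the bleach
generator and analyzer satisfy to $10^{-9}$.

Ratiometric responses use the acceptor/donor ratio by default
(configurable): baseline from pre-agonist frames, amplitude as the maximal
relative deviation between agonist and antagonist, recovery as the fraction
of that deviation reversed at the post-antagonist plateau (mean of the last
five frames by default). The responder threshold defaults to 5% amplitude —
the characterization study excluded cells "without a visible response" but
stated no number, so the threshold is explicit, configurable and reported.
For cohort averaging, traces are re-indexed so the agonist event is $t = 0$
and interpolated onto a common grid; cohort summaries use the mean with a
normal-approximation 95% confidence band.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is validated:

* **Spectra** (`genSpectra()`): skewed-Gaussian (log-normal in wavelength)
  absorbance and emission bands on a 1 nm, 350–800 nm grid; absorbance
  blue-skewed, emission red-tailed, peaks exact to the grid. Measured
  fluorescent-protein spectra are not parametric, but every correctness
  argument in the package is shape-agnostic, so the functional form only
  needs to be smooth, peaked and realistically overlapping.
* **Phase stacks** (`genPhaseStack()`): homodyne frames
  $DC(1 + M\cos(\theta_k - \varphi))$ from the DC-weighted mixture phasor
  of the requested lifetime components, with an instrument phase offset and
  modulation factor applied identically to the emitted reference stack;
  optional per-pixel Poisson noise. Defaults: 75.1 MHz, 12 equally spaced
  phase steps, $10^4$ counts/pixel — the modulation frequency and step
  count of the characterization study and a realistic camera count level.
* **Cell spectra** (`genCellSpectra()`): $F = N[(1-E)Q_D f_D + E Q_A f_A]
  + N d Q_A f_A + N g f_G$ plus a consistent acceptor-excitation spectrum,
  on the 450–650 nm acquisition grid. The acceptor-only control that
  provides the direct-excitation shape is *also generated as a measurement*
  — with the same noise model and the same normalization procedure — so
  the peak-normalization bias cancels between sample and control exactly as
  it does in the experiment. Gaussian noise defaults to 1% of the spectrum
  peak (detector noise at typical spectral-image count levels), clamped at
  zero since photon counts are non-negative.
* **Traces** (`genBleachTrace()`, `genGpcrTrace()`): mono/bi-exponential
  acceptor bleaching with donor dequenching, and exponential step responses
  between a resting and an activated FRET level with agonist/antagonist
  events (defaults: agonist at 44 s, antagonist at 150 s, 2 s frames over
  240 s for biosensor traces; 4 s frames over 900 s for bleaching, matching
  the recording protocols the package is meant to analyze).

All generators are bit-reproducible under a fixed seed and restore the
caller's RNG state.

What the generator does **not** emulate: detector spectral-sensitivity
curves (inputs are assumed corrected), monochromator drift and filter
edges, spatial cell structure in FLIM images (stacks are spatially
homogeneous up to noise), photochromism, and maturation heterogeneity
between cells. Passing the recovery tests therefore demonstrates the
correctness of the estimators under the stated statistical model, not
robustness to every instrument artifact of real microscopes.

# Validation strategy and problem sizes

The test suite validates each estimator against independent oracles:
closed-form Fourier orthogonality and brute-force phasor addition for FLIM,
constructed mixtures and algebraic identities for unmixing, closed-form
decay/step levels for traces, and fine-grid (0.01 nm) integration for the
overlap integral. End-to-end checks recover the generator's ground truth:
exactly (tolerances $10^{-6}$–$10^{-9}$) without noise, and within the 95%
confidence interval of the mean over 100 seeds with noise. Stochastic
checks use 100-seed cohorts, 16×16-pixel stacks at $10^4$ counts and
201-point spectra — sizes at which the whole suite runs in seconds while
keeping Monte-Carlo error well below the tolerances tested.

# Known limitations

* Single modulation frequency per phase stack; no multi-harmonic or
  global multi-frequency analysis, and no time-domain (TCSPC) fitting.
* No errors-in-variables model in the unmixing regression; reference
  shapes are treated as noise-free.
* No image segmentation: ROI and background masks are user-supplied.
* The published modulation-lifetime efficiency column is reproduced only
  where it is internally consistent (12 of 14 rows, see above).
* $\kappa^2$ and $n$ are parameters, not fitted quantities; no orientation
  modelling.
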