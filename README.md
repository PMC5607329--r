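# fretchar

Characterization of FRET donor–acceptor pairs built on the cyan donor
mTurquoise2, for cell biologists and microscopists evaluating acceptor
fluorescent proteins for FRET biosensors.

Förster resonance energy transfer (FRET) is the radiationless transfer of
energy from an excited donor fluorophore to a nearby acceptor. How good an
acceptor is depends on theory — the spectral overlap integral

*J* = ∫ *f*<sub>D</sub>(λ) ε<sub>A</sub>(λ) λ⁴ dλ  [M⁻¹cm⁻¹nm⁴]

and the Förster radius (the distance giving 50% transfer)

*R*₀⁶ = 8.79×10⁻⁵ κ² *n*⁻⁴ *Q*<sub>D</sub> *J*  [*R*₀ in Å]

— and on practice: the donor lifetime reduction measured by
frequency-domain FLIM (*E* = 1 − τ<sub>DA</sub>/τ<sub>D</sub>), the
sensitized emission isolated by spectral unmixing with the apparent
efficiency

*E*<sub>D</sub>(λ) = 1 − *F*<sub>D</sub> / [ (*Q*<sub>D</sub>*f*<sub>D</sub> / *Q*<sub>A</sub>*f*<sub>A</sub>) *F*<sub>S</sub> + *F*<sub>D</sub> ],

photostability under FRET imaging conditions, and the dynamic range of
ratiometric biosensor responses. `fretchar` implements all four analysis
stages plus a synthetic-data generator that produces every input with known
ground truth, so the whole pipeline is testable without microscope data.
The published spectroscopic and lifetime constants of the fourteen-acceptor
mTurquoise2 panel ship with the package (`acceptorConstants()`), and
`reproduceTables()` recomputes the derived columns from them.

## Worked example

```r
library(fretchar)

## Förster theory from (generated) spectra
donor    <- genSpectra("mTurquoise2", c(434, 474), epsilonMax = 30000,
                       quantumYield = 0.93)
acceptor <- genSpectra("mNeonGreen", c(505, 517), epsilonMax = 116000,
                       quantumYield = 0.80)
fretPairTheory(donor, acceptor)
#> FretPairTheory mTurquoise2 -> mNeonGreen: J = 3.78e+15 /M/cm nm^4, R0 = 63.6 Angstrom

## Forster radius from the published overlap integral of this pair
forsterRadius(3.15e15)      # kappa^2 = 2/3, n = 1.33, Q_D = 0.93
#> [1] 61.64257               # rounds to the published 62 Angstrom

## FD-FLIM: simulate a 2.0 ns sample at 75.1 MHz with Poisson noise,
## calibrate against the emitted reference stack, estimate lifetimes
g   <- genPhaseStack(tausNs = 2.0, frequencyHz = 75.1e6, dimPx = c(16, 16),
                     countsPerPixel = 1e4, instrumentPhaseRad = 0.2,
                     instrumentModFactor = 0.9, noise = "poisson", seed = 1)
ref <- calibrationReference(fitPhasor(g$reference), g$referenceTauNs)
cal <- calibratePhasor(averagePhasor(fitPhasor(g$sample)), ref, 75.1e6)
(lt <- lifetimesFromPhasor(cal, 75.1e6))
#> LifetimePair: tau_phi = 1.9971 ns, tau_M = 2.0026 ns
fretEfficiencyFromLifetime(tauPhase(lt), 3.77)   # percent
#> [1] 47.02659

## Spectral unmixing: cell spectra at a known true E = 0.42, 1% noise
cells <- genCellSpectra(donor, acceptor, trueE = 0.42,
                        directExcitationFraction = 0.1,
                        noise = "gaussian", seed = 1)
round(spectralFretEfficiency(cells$cell, cells$refs)$E, 4)
#> [1] 0.4203

## Photobleaching: acceptor with a 450 s half-time dequenches the donor
bl <- genBleachTrace(E0 = 0.46, acceptorBleach = log(2) / 450)
bleachSummary(bl$trace)
#>   t_probe_s donor_pct acceptor_pct
#> 1        48  106.0710     92.87314
#> 2       900  163.8889     25.00000

## Ratiometric biosensor step response (FRET loss on activation)
ratioResponse(genGpcrTrace(baselineE = 0.30, activatedE = 0.21)$trace)
#> RatioResponse: baseline 1.000, amplitude 38.0%, recovery 100.0%, responder (threshold 5.0%)
```

Reading the numbers: the generated cyan–green pair has a Förster radius
near the published 62 Å value; the noisy FLIM stack recovers the 2.0 ns
ground truth to about 0.3%, corresponding to 47% FRET efficiency against
the 3.77 ns unquenched donor; the unmixing chain returns the true
efficiency 0.42 within noise; acceptor bleaching to 25% at 900 s raises the
donor channel to 164% of its initial value (dequenching); and the biosensor
trace responds with a 38% ratio change that fully recovers after the
antagonist.

A thin command-line wrapper is available at `inst/scripts/fretchar`
(subcommands `r0`, `efficiency`, `reproduce`).

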