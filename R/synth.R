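#' @title Synthetic-data generators with known ground truth
#' @description Every input the analysis pipeline consumes can be generated
#' with known ground truth: peaked fluorophore spectra, homodyne FLIM phase
#' stacks, mixed single-cell emission spectra, and two-channel bleaching and
#' biosensor traces. All generators are deterministic under a fixed seed.
#' @name synth
NULL

# Run code with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    code
}

# Skewed-Gaussian band shape (log-normal in wavelength). Zero asymmetry
# reduces to a symmetric Gaussian; the peak sits exactly at `peak`.
.skewPeak <- function(lambda, peak, width, asymmetry = 0) {
    if (width <= 0) stop("peak width must be positive")
    if (asymmetry == 0)
        return(exp(-0.5 * ((lambda - peak) / width)^2))
    u <- 1 + asymmetry * (lambda - peak) / width
    v <- numeric(length(lambda))
    ok <- u > 0
    v[ok] <- exp(-0.5 * (log(u[ok]) / asymmetry)^2)
    v
}

#' Generate a fluorophore record with skewed-Gaussian spectra
#'
#' Emulates measured fluorescent-protein spectra: a smooth absorbance band
#' (typically blue-skewed, i.e. a vibronic shoulder towards shorter
#' wavelengths) and a Stokes-shifted emission band (typically red-tailed) on
#' a 1 nm grid spanning 350-800 nm, with peak positions exact to the grid.
#'
#' @param name identifier, e.g. `"mTurquoise2"`.
#' @param peaksNm length-2: absorption and emission peak, nm; the Stokes
#'   shift must be positive.
#' @param widthsNm length-2 band widths (nm) of absorbance and emission.
#' @param asymmetry length-2 skew parameters (0 = symmetric Gaussian;
#'   negative skews the tail towards shorter wavelengths).
#' @param epsilonMax peak extinction coefficient, M^-1 cm^-1.
#' @param quantumYield fluorescence quantum yield.
#' @param gridNm wavelength grid.
#' @return A [FluorophoreRecord-class] with peak-normalized spectra.
#' @examples
#' mtq2 <- genSpectra("mTurquoise2", c(434, 474), epsilonMax = 30000,
#'                    quantumYield = 0.93)
#' peakWavelength(mtq2@emission)
#' @export
genSpectra <- function(name, peaksNm, widthsNm = c(25, 30),
                       asymmetry = c(-0.35, 0.35), epsilonMax,
                       quantumYield, gridNm = seq(350, 800, by = 1)) {
    if (peaksNm[2] <= peaksNm[1])
        stop("emission peak must lie red of the absorption peak ",
             "(positive Stokes shift)")
    absv <- .skewPeak(gridNm, peaksNm[1], widthsNm[1], asymmetry[1])
    emv <- .skewPeak(gridNm, peaksNm[2], widthsNm[2], asymmetry[2])
    FluorophoreRecord(
        name = name, absorptionPeakNm = peaksNm[1], epsilonMax = epsilonMax,
        quantumYield = quantumYield,
        absorbance = new("Spectrum", wavelengths = as.numeric(gridNm),
                         values = absv / max(absv), kind = "absorbance",
                         normalization = "peak"),
        emission = new("Spectrum", wavelengths = as.numeric(gridNm),
                       values = emv / max(emv), kind = "emission",
                       normalization = "peak"))
}

#' Generate a homodyne FLIM phase stack with known lifetimes
#'
#' Forward model: frames I_k = DC (1 + M cos(theta_k - phi)), where
#' (phi, M) is the DC-weighted mixture phasor of the requested lifetime
#' components, distorted by an instrument phase offset and modulation factor.
#' Optional Poisson photon noise per pixel. A reference stack of declared
#' known lifetime, distorted identically, is emitted alongside for
#' calibration.
#'
#' @param tausNs lifetime component(s), ns.
#' @param weights DC intensity weights of the components.
#' @param frequencyHz modulation frequency (default 75.1 MHz).
#' @param kSteps number of equally spaced phase steps (default 12).
#' @param dimPx image size, `c(rows, cols)`.
#' @param countsPerPixel mean DC counts per pixel per frame.
#' @param instrumentPhaseRad,instrumentModFactor instrument distortion
#'   applied to sample and reference alike.
#' @param acquisitionOrder temporal permutation of the phase steps (frames
#'   are stored in acquisition order, each paired with its phase step).
#' @param noise `"none"` or `"poisson"`.
#' @param referenceTauNs mono-exponential lifetime of the emitted reference
#'   stack (default 3.8 ns); NULL suppresses the reference.
#' @param seed RNG seed for the noise.
#' @return list with `sample` ([PhaseStack-class]), `reference`
#'   ([PhaseStack-class] or NULL), `referenceTauNs`, and `truth` (list with
#'   the ground-truth phasor and apparent lifetimes).
#' @export
genPhaseStack <- function(tausNs, weights = rep(1, length(tausNs)),
                          frequencyHz = 75.1e6, kSteps = 12,
                          dimPx = c(16, 16), countsPerPixel = 1e4,
                          instrumentPhaseRad = 0, instrumentModFactor = 1,
                          acquisitionOrder = seq_len(kSteps),
                          noise = c("none", "poisson"),
                          referenceTauNs = 3.8, seed = NULL) {
    noise <- match.arg(noise)
    if (countsPerPixel <= 0) stop("countsPerPixel must be positive")
    if (kSteps < 3) stop("at least 3 phase steps are required")
    theta <- 2 * pi * (seq_len(kSteps) - 1) / kSteps
    thetaAcq <- theta[acquisitionOrder]

    buildStack <- function(phase, modulation) {
        frames <- array(0, dim = c(dimPx[1], dimPx[2], kSteps))
        for (k in seq_len(kSteps))
            frames[, , k] <- countsPerPixel *
                (1 + modulation * cos(thetaAcq[k] - phase))
        if (noise == "poisson")
            frames <- array(stats::rpois(length(frames), frames),
                            dim = dim(frames))
        PhaseStack(frames, thetaAcq, frequencyHz,
                   acquisitionOrder = acquisitionOrder)
    }

    mix <- mixturePhasor(tausNs, weights, frequencyHz)
    phiObs <- mix$phase + instrumentPhaseRad
    modObs <- mix$modulation * instrumentModFactor
    omega <- 2 * pi * frequencyHz
    truth <- list(
        tausNs = tausNs, weights = weights / sum(weights),
        phase = mix$phase, modulation = mix$modulation,
        tauPhaseNs = tan(mix$phase) / omega * 1e9,
        tauModNs = sqrt(1 / mix$modulation^2 - 1) / omega * 1e9)

    .withSeed(seed, {
        sample <- buildStack(phiObs, modObs)
        reference <- if (is.null(referenceTauNs)) NULL else {
            rp <- .phasorFromTau(referenceTauNs, frequencyHz)
            buildStack(rp$phase + instrumentPhaseRad,
                       rp$modulation * instrumentModFactor)
        }
        list(sample = sample, reference = reference,
             referenceTauNs = referenceTauNs, truth = truth)
    })
}

#' Generate single-cell spectra with a known true FRET efficiency
#'
#' Builds the donor-excitation spectrum as
#' F = N ((1-E) Q_D f_D + E Q_A f_A) + N d Q_A f_A + N g f_G (+ noise)
#' with f_D, f_A the area-normalized donor/acceptor emission shapes, d the
#' direct-excitation fraction and g an optional green-contaminant amplitude,
#' together with a consistent acceptor-excitation spectrum
#' F_Aexc = N Q_A f_A and the matching [ReferenceSet-class] (whose
#' direct-excitation shape is derived from a noiseless acceptor-only
#' control processed identically to the sample).
#'
#' @param donor,acceptor [FluorophoreRecord-class]s (e.g. from
#'   [genSpectra()]).
#' @param trueE ground-truth FRET efficiency in `[0, 1]`.
#' @param donorAbundance overall expression scale N.
#' @param directExcitationFraction direct acceptor excitation relative to
#'   donor excitation, `>= 0`.
#' @param greenFraction amplitude of an EGFP-like green contaminant relative
#'   to N (orange/red acceptors only).
#' @param green optional [FluorophoreRecord-class] for the contaminant.
#' @param acceptorClass unmixing class; defaults to `"green_yellow"`, or
#'   `"orange_red_with_green"` when `greenFraction > 0`.
#' @param noise `"none"` or `"gaussian"` (sd = `sigma` times the spectrum
#'   peak, clamped at zero: photon counts are non-negative).
#' @param sigma Gaussian noise level relative to the peak (default 0.01).
#' @param gridNm acquisition wavelength grid (default 450-650 nm, 1 nm).
#' @param seed RNG seed.
#' @return list with `cell` ([CellSpectra-class]), `refs`
#'   ([ReferenceSet-class]) and `truth` (list with `E` and component
#'   amplitudes).
#' @export
genCellSpectra <- function(donor, acceptor, trueE, donorAbundance = 1000,
                           directExcitationFraction = 0.1, greenFraction = 0,
                           green = NULL, acceptorClass = NULL,
                           noise = c("none", "gaussian"), sigma = 0.01,
                           gridNm = seq(450, 650, by = 1), seed = NULL) {
    noise <- match.arg(noise)
    if (trueE < 0 || trueE > 1) stop("trueE must lie in [0, 1]")
    if (directExcitationFraction < 0 || greenFraction < 0)
        stop("fractions must be >= 0")
    if (greenFraction > 0 && is.null(green))
        stop("greenFraction > 0 requires a green fluorophore record")
    if (is.null(acceptorClass))
        acceptorClass <- if (greenFraction > 0) "orange_red_with_green"
                         else "green_yellow"
    N <- donorAbundance
    qD <- donor@quantumYield
    qA <- acceptor@quantumYield
    fD <- normalizeAfterResample(donor@emission, gridNm)
    fA <- normalizeAfterResample(acceptor@emission, gridNm)
    fG <- if (!is.null(green)) normalizeAfterResample(green@emission, gridNm)
          else numeric(length(gridNm))

    Fdon <- N * ((1 - trueE) * qD * fD + trueE * qA * fA) +
        N * directExcitationFraction * qA * fA + N * greenFraction * fG
    Facc <- N * qA * fA

    .withSeed(seed, {
        addNoise <- function(v) {
            if (noise == "gaussian")
                pmax(0, v + stats::rnorm(length(v), sd = sigma * max(v)))
            else v
        }
        Fdon <- addNoise(Fdon)
        Facc <- addNoise(Facc)
        mk <- function(v) new("Spectrum", wavelengths = as.numeric(gridNm),
                              values = v, kind = "emission",
                              normalization = "raw")
        cell <- CellSpectra(mk(Fdon), mk(Facc), acceptorClass)
        # acceptor-only control: F_ctrl = N' d Q_A f_A under donor excitation,
        # normalized to the peak of its own acceptor-excitation spectrum
        # N' Q_A f_A (the N' and Q_A cancel). The control is a measurement
        # too: it carries the same noise and is normalized by the same noisy
        # peak-reading procedure as the sample, so normalization biases
        # cancel between sample and control as they do in the experiment.
        ctrlDon <- addNoise(N * directExcitationFraction * qA * fA)
        ctrlAcc <- addNoise(N * qA * fA)
        directShape <- mk(ctrlDon / max(ctrlAcc))
        refs <- ReferenceSet(
            donorRef = mk(fD), acceptorRef = mk(fA),
            directShape = directShape,
            greenRef = if (is.null(green)) NULL else mk(fG),
            qD = qD, qA = qA)
        list(cell = cell, refs = refs,
             truth = list(E = trueE, donorAbundance = N,
                          directExcitationFraction = directExcitationFraction,
                          greenFraction = greenFraction))
    })
}

.survival <- function(t, model) {
    if (is.numeric(model))
        model <- list(rates = model)
    rates <- model$rates
    if (any(rates < 0)) stop("bleach rates must be >= 0")
    if (length(rates) == 1L) return(exp(-rates * t))
    fr <- model$fractions
    if (is.null(fr)) fr <- rep(1 / length(rates), length(rates))
    fr <- fr / sum(fr)
    rowSums(vapply(seq_along(rates),
                   function(i) fr[i] * exp(-rates[i] * t),
                   numeric(length(t))))
}

#' Generate a donor-dequenching photobleaching trace
#'
#' Under continuous donor excitation the acceptor bleaches with survival
#' fraction a(t) (mono- or bi-exponential); lost acceptors no longer quench
#' their donors, so the donor channel rises as
#' donor(t) = (1 - E0 a(t)) exp(-k_D t) while the acceptor channel decays
#' proportionally to a(t).
#'
#' @param E0 initial FRET efficiency in `[0, 1)`.
#' @param acceptorBleach a single rate (1/s) or
#'   `list(rates = c(k1, k2), fractions = c(f, 1-f))` for bi-exponential
#'   bleaching.
#' @param donorBleachRate intrinsic donor bleach rate, 1/s.
#' @param directFraction direct acceptor excitation contribution to the
#'   acceptor channel.
#' @param qA acceptor quantum yield.
#' @param durationS,dtS trace duration and frame interval, s (defaults: the
#'   900 s continuous-illumination protocol sampled every 4 s).
#' @param amplitude overall intensity scale.
#' @param backgroundDonor,backgroundAcceptor additive backgrounds.
#' @param noise `"none"` or `"gaussian"` (sd = `sigma` x initial intensity).
#' @param sigma relative noise level.
#' @param seed RNG seed.
#' @return list with `trace` ([IntensityTrace-class]) and `truth` (list with
#'   `E0`, the survival curve `a`, and the rates).
#' @export
genBleachTrace <- function(E0, acceptorBleach, donorBleachRate = 0,
                           directFraction = 0.1, qA = 0.68,
                           durationS = 900, dtS = 4, amplitude = 1000,
                           backgroundDonor = 0, backgroundAcceptor = 0,
                           noise = c("none", "gaussian"), sigma = 0.01,
                           seed = NULL) {
    noise <- match.arg(noise)
    if (E0 < 0 || E0 >= 1) stop("E0 must lie in [0, 1)")
    if (donorBleachRate < 0) stop("rates must be >= 0")
    if (dtS <= 0) stop("dtS must be positive")
    t <- seq(0, durationS, by = dtS)
    a <- .survival(t, acceptorBleach)
    donor <- amplitude * (1 - E0 * a) * exp(-donorBleachRate * t)
    acceptor <- amplitude * a * (E0 * qA + directFraction)
    .withSeed(seed, {
        if (noise == "gaussian") {
            donor <- pmax(0, donor + stats::rnorm(length(t),
                                                  sd = sigma * donor[1]))
            acceptor <- pmax(0, acceptor +
                stats::rnorm(length(t), sd = sigma * acceptor[1]))
        }
        trace <- IntensityTrace(t, donor + backgroundDonor,
                                acceptor + backgroundAcceptor,
                                backgroundDonor, backgroundAcceptor)
        list(trace = trace,
             truth = list(E0 = E0, survival = a, timeS = t,
                          donorBleachRate = donorBleachRate))
    })
}

#' Generate a GPCR-activation biosensor ratio trace
#'
#' The sensor reports receptor activation as FRET loss: E(t) relaxes
#' exponentially from `baselineE` towards `activatedE` after agonist
#' addition and back after antagonist addition. Channels follow
#' donor = 1 - E(t) and acceptor = Q_A E(t) (times the amplitude), so the
#' donor rises by the factor (1 - activatedE) / (1 - baselineE) at full
#' activation.
#'
#' @param baselineE resting FRET efficiency.
#' @param activatedE FRET efficiency of the activated (low-FRET) state;
#'   must satisfy `0 <= activatedE < baselineE < 1`.
#' @param agonistS,antagonistS event times, s.
#' @param transitionTauS exponential relaxation time of the switch, s.
#' @param durationS,dtS trace duration and frame interval, s.
#' @param qA acceptor quantum yield.
#' @param amplitude overall intensity scale.
#' @param backgroundDonor,backgroundAcceptor additive backgrounds.
#' @param noise `"none"` or `"gaussian"`.
#' @param sigma relative noise level.
#' @param seed RNG seed.
#' @return list with `trace` (events annotated) and `truth` (list with the
#'   efficiency time course and the closed-form donor amplitude).
#' @export
genGpcrTrace <- function(baselineE = 0.30, activatedE = 0.21,
                         agonistS = 44, antagonistS = 150,
                         transitionTauS = 3, durationS = 240, dtS = 2,
                         qA = 0.68, amplitude = 1000,
                         backgroundDonor = 0, backgroundAcceptor = 0,
                         noise = c("none", "gaussian"), sigma = 0.01,
                         seed = NULL) {
    noise <- match.arg(noise)
    if (!(activatedE >= 0 && activatedE <= baselineE && baselineE < 1))
        stop("need 0 <= activatedE <= baselineE < 1 (activation is FRET loss)")
    if (agonistS <= 0 || antagonistS <= agonistS || antagonistS >= durationS)
        stop("events must satisfy 0 < agonistS < antagonistS < durationS")
    t <- seq(0, durationS, by = dtS)
    E <- rep(baselineE, length(t))
    on <- t >= agonistS
    E[on] <- activatedE + (baselineE - activatedE) *
        exp(-(t[on] - agonistS) / transitionTauS)
    eAtAnt <- activatedE + (baselineE - activatedE) *
        exp(-(antagonistS - agonistS) / transitionTauS)
    off <- t >= antagonistS
    E[off] <- baselineE + (eAtAnt - baselineE) *
        exp(-(t[off] - antagonistS) / transitionTauS)
    donor <- amplitude * (1 - E)
    acceptor <- amplitude * qA * E
    .withSeed(seed, {
        if (noise == "gaussian") {
            donor <- pmax(0, donor + stats::rnorm(length(t),
                                                  sd = sigma * donor[1]))
            acceptor <- pmax(0, acceptor +
                stats::rnorm(length(t), sd = sigma * acceptor[1]))
        }
        trace <- IntensityTrace(t, donor + backgroundDonor,
                                acceptor + backgroundAcceptor,
                                backgroundDonor, backgroundAcceptor,
                                events = c(agonist = agonistS,
                                           antagonist = antagonistS))
        list(trace = trace,
             truth = list(
                 baselineE = baselineE, activatedE = activatedE,
                 efficiency = E, timeS = t,
                 donorAmplitudeFactor = (1 - activatedE) / (1 - baselineE)))
    })
}
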