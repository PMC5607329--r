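#' @import methods
NULL

.SPECTRUM_KINDS <- c("absorbance", "emission", "excitation")
.NORMALIZATIONS <- c("raw", "peak", "area")
.ACCEPTOR_CLASSES <- c("green_yellow", "orange_red_with_green", "red_no_green")

#' Sampled fluorescence spectrum
#'
#' A wavelength/value curve sampled on a strictly increasing wavelength grid,
#' with a declared kind (absorbance, emission or excitation) and a
#' normalization state (`raw`, `peak` or `area`).
#'
#' @slot wavelengths numeric, strictly increasing wavelength grid in nm.
#' @slot values numeric, intensities (arbitrary units; extinction in
#'   M^-1 cm^-1 for absorbance spectra scaled to epsilon).
#' @slot kind one of `"absorbance"`, `"emission"`, `"excitation"`.
#' @slot normalization one of `"raw"`, `"peak"`, `"area"`.
#' @seealso [Spectrum()], [normalizeSpectrum()], [resampleSpectrum()]
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        wavelengths = "numeric",
        values = "numeric",
        kind = "character",
        normalization = "character"
    )
)

setValidity("Spectrum", function(object) {
    w <- object@wavelengths
    v <- object@values
    msgs <- character()
    if (length(w) != length(v))
        msgs <- c(msgs, "wavelengths and values must have the same length")
    if (length(w) >= 2 && any(diff(w) <= 0))
        msgs <- c(msgs, "wavelengths must be strictly increasing")
    if (anyNA(w) || any(!is.finite(w)))
        msgs <- c(msgs, "wavelengths must be finite")
    if (anyNA(v) || any(!is.finite(v)))
        msgs <- c(msgs, "values must be finite")
    if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
        msgs <- c(msgs, sprintf("kind must be one of: %s",
                                paste(.SPECTRUM_KINDS, collapse = ", ")))
    if (length(object@normalization) != 1L ||
        !object@normalization %in% .NORMALIZATIONS)
        msgs <- c(msgs, sprintf("normalization must be one of: %s",
                                paste(.NORMALIZATIONS, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' Named fluorophore with spectra and scalar photophysics
#'
#' Bundles the absorbance and emission spectra of a fluorescent protein with
#' its absorption peak position, peak molar extinction coefficient and
#' fluorescence quantum yield.
#'
#' @slot name character identifier.
#' @slot absorptionPeakNm absorption maximum in nm.
#' @slot epsilonMax peak molar extinction coefficient, M^-1 cm^-1.
#' @slot quantumYield fluorescence quantum yield in `[0, 1]`.
#' @slot absorbance,emission [Spectrum-class] objects.
#' @seealso [FluorophoreRecord()], [genSpectra()]
#' @exportClass FluorophoreRecord
setClass("FluorophoreRecord",
    representation(
        name = "character",
        absorptionPeakNm = "numeric",
        epsilonMax = "numeric",
        quantumYield = "numeric",
        absorbance = "Spectrum",
        emission = "Spectrum"
    )
)

setValidity("FluorophoreRecord", function(object) {
    msgs <- character()
    if (object@epsilonMax <= 0)
        msgs <- c(msgs, "epsilonMax must be positive")
    if (object@quantumYield < 0 || object@quantumYield > 1)
        msgs <- c(msgs, "quantumYield must lie in [0, 1]")
    if (object@absorbance@kind != "absorbance")
        msgs <- c(msgs, "absorbance slot must hold an absorbance spectrum")
    if (object@emission@kind != "emission")
        msgs <- c(msgs, "emission slot must hold an emission spectrum")
    w <- object@absorbance@wavelengths
    if (length(w) >= 2) {
        step <- max(diff(w))
        peak <- w[which.max(object@absorbance@values)]
        if (abs(peak - object@absorptionPeakNm) > step + 1e-9)
            msgs <- c(msgs, sprintf(
                "absorbance peak (%.1f nm) disagrees with absorptionPeakNm (%.1f nm) by more than one grid step",
                peak, object@absorptionPeakNm))
    }
    if (length(msgs)) msgs else TRUE
})

#' Parameters of Forster theory
#'
#' Orientation factor kappa^2, medium refractive index n and donor quantum
#' yield Q_D entering the Forster radius. Defaults are the conventional
#' isotropic-averaging kappa^2 = 2/3, aqueous n = 1.33 and the mTurquoise2
#' quantum yield of 0.93.
#'
#' @slot kappaSq dipole orientation factor, in `[0, 4]`.
#' @slot refractiveIndex medium refractive index, `>= 1`.
#' @slot donorQY donor fluorescence quantum yield, in `(0, 1]`.
#' @seealso [FretTheoryParams()], [forsterRadius()]
#' @exportClass FretTheoryParams
setClass("FretTheoryParams",
    representation(
        kappaSq = "numeric",
        refractiveIndex = "numeric",
        donorQY = "numeric"
    )
)

setValidity("FretTheoryParams", function(object) {
    msgs <- character()
    if (object@kappaSq < 0 || object@kappaSq > 4)
        msgs <- c(msgs, "kappaSq must lie in [0, 4]")
    if (object@refractiveIndex < 1)
        msgs <- c(msgs, "refractiveIndex must be >= 1")
    if (object@donorQY <= 0 || object@donorQY > 1)
        msgs <- c(msgs, "donorQY must lie in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Forster theory summary of a donor-acceptor pair
#'
#' Holds the overlap integral J and Forster radius R0 computed for a
#' donor-acceptor pair together with the parameters used.
#'
#' @slot donor,acceptor [FluorophoreRecord-class] objects.
#' @slot overlapJ overlap integral, M^-1 cm^-1 nm^4.
#' @slot R0Angstrom Forster radius, Angstrom.
#' @slot params [FretTheoryParams-class].
#' @seealso [fretPairTheory()]
#' @exportClass FretPairTheory
setClass("FretPairTheory",
    representation(
        donor = "FluorophoreRecord",
        acceptor = "FluorophoreRecord",
        overlapJ = "numeric",
        R0Angstrom = "numeric",
        params = "FretTheoryParams"
    )
)

setValidity("FretPairTheory", function(object) {
    msgs <- character()
    if (object@overlapJ < 0) msgs <- c(msgs, "overlapJ must be >= 0")
    if (object@R0Angstrom < 0) msgs <- c(msgs, "R0Angstrom must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Homodyne frequency-domain FLIM phase stack
#'
#' An ordered set of modulated-intensity frames recorded at distinct detector
#' phase steps, together with the modulation frequency and the temporal order
#' in which the frames were acquired (phase steps are often visited in
#' pseudorandom order to decorrelate photobleaching from phase).
#'
#' @slot frames numeric array, rows x cols x K, photon counts or intensity.
#' @slot phaseStepsRad numeric length-K phase angles in `[0, 2*pi)`; the k-th
#'   frame corresponds to the k-th phase step, whatever the acquisition order.
#' @slot frequencyHz modulation frequency f in Hz (omega = 2*pi*f).
#' @slot acquisitionOrder integer permutation of `1:K` giving the temporal
#'   acquisition position of each frame.
#' @seealso [PhaseStack()], [fitPhasor()], [genPhaseStack()]
#' @exportClass PhaseStack
setClass("PhaseStack",
    representation(
        frames = "array",
        phaseStepsRad = "numeric",
        frequencyHz = "numeric",
        acquisitionOrder = "integer"
    )
)

setValidity("PhaseStack", function(object) {
    msgs <- character()
    d <- dim(object@frames)
    k <- length(object@phaseStepsRad)
    if (length(d) != 3L)
        msgs <- c(msgs, "frames must be a rows x cols x K array")
    else if (d[3] != k)
        msgs <- c(msgs, "third array dimension must match the number of phase steps")
    if (k < 3L)
        msgs <- c(msgs, "at least 3 phase steps are required")
    if (anyDuplicated(round(object@phaseStepsRad %% (2 * pi), 12)))
        msgs <- c(msgs, "phase steps must be distinct")
    if (any(object@frames < 0))
        msgs <- c(msgs, "frames must be non-negative")
    if (object@frequencyHz <= 0)
        msgs <- c(msgs, "frequencyHz must be positive")
    if (length(object@acquisitionOrder) != k ||
        !setequal(object@acquisitionOrder, seq_len(k)))
        msgs <- c(msgs, "acquisitionOrder must be a permutation of 1:K")
    if (length(msgs)) msgs else TRUE
})

#' First-harmonic phasor estimate
#'
#' Per-pixel (or scalar, after region averaging) estimate of the mean
#' intensity (DC), first-harmonic amplitude (AC), phase and modulation depth
#' M = AC/DC of a homodyne phase stack.
#'
#' @slot dc,ac,phaseRad,modulation numeric arrays of identical shape.
#' @slot undefined logical array flagging pixels whose relative first-harmonic
#'   amplitude fell below the estimator floor (phase undefined there).
#' @seealso [fitPhasor()], [calibratePhasor()], [lifetimesFromPhasor()]
#' @exportClass PhasorEstimate
setClass("PhasorEstimate",
    representation(
        dc = "array",
        ac = "array",
        phaseRad = "array",
        modulation = "array",
        undefined = "array"
    )
)

setValidity("PhasorEstimate", function(object) {
    msgs <- character()
    dims <- list(dim(object@dc), dim(object@ac), dim(object@phaseRad),
                 dim(object@modulation), dim(object@undefined))
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        msgs <- c(msgs, "all phasor components must share the same shape")
    if (any(object@ac[!object@undefined] < 0, na.rm = TRUE))
        msgs <- c(msgs, "ac must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' FLIM calibration reference
#'
#' A measured phasor of a reference sample of known phase and modulation
#' lifetime, used to remove the instrument phase offset and modulation factor
#' from sample measurements.
#'
#' @slot measured scalar [PhasorEstimate-class] of the reference.
#' @slot knownTauPhaseNs,knownTauModNs reference phase/modulation lifetimes, ns.
#' @seealso [calibrationReference()], [calibratePhasor()]
#' @exportClass CalibrationReference
setClass("CalibrationReference",
    representation(
        measured = "PhasorEstimate",
        knownTauPhaseNs = "numeric",
        knownTauModNs = "numeric"
    )
)

setValidity("CalibrationReference", function(object) {
    msgs <- character()
    if (object@knownTauPhaseNs < 0 || object@knownTauModNs < 0)
        msgs <- c(msgs, "known lifetimes must be >= 0")
    if (length(object@measured@dc) != 1L)
        msgs <- c(msgs, "measured reference phasor must be scalar (region-averaged)")
    if (length(msgs)) msgs else TRUE
})

#' Phase and modulation lifetime pair
#'
#' For a mono-exponential decay the two agree; for lifetime mixtures the
#' phase lifetime is pulled below the modulation lifetime.
#'
#' @slot tauPhaseNs,tauModNs lifetimes in ns (may carry a `dim` attribute for
#'   per-pixel maps).
#' @seealso [lifetimesFromPhasor()]
#' @exportClass LifetimePair
setClass("LifetimePair",
    representation(tauPhaseNs = "numeric", tauModNs = "numeric")
)

#' Reference spectra and quantum yields for spectral unmixing
#'
#' Area-normalized donor and acceptor emission reference shapes, the
#' direct-excitation shape measured from an acceptor-only control under donor
#' excitation (normalized to the peak of its own acceptor-excitation
#' spectrum), an optional EGFP-like green contaminant shape, and the two
#' quantum yields entering the apparent-efficiency estimator.
#'
#' @slot donorRef,acceptorRef area-normalized emission [Spectrum-class]s.
#' @slot directShape [Spectrum-class] or NULL-like zero-length spectrum; see
#'   [subtractDirectExcitation()].
#' @slot greenRef optional green contaminant emission shape.
#' @slot qD,qA donor and acceptor quantum yields.
#' @seealso [ReferenceSet()], [unmixSpectrum()], [apparentEfficiency()]
#' @exportClass ReferenceSet
setClass("ReferenceSet",
    representation(
        donorRef = "Spectrum",
        acceptorRef = "Spectrum",
        directShape = "ANY",
        greenRef = "ANY",
        qD = "numeric",
        qA = "numeric"
    )
)

setValidity("ReferenceSet", function(object) {
    msgs <- character()
    if (object@qD <= 0 || object@qD > 1) msgs <- c(msgs, "qD must lie in (0, 1]")
    if (object@qA <= 0 || object@qA > 1) msgs <- c(msgs, "qA must lie in (0, 1]")
    for (nm in c("directShape", "greenRef")) {
        s <- slot(object, nm)
        if (!is.null(s) && !is(s, "Spectrum"))
            msgs <- c(msgs, sprintf("%s must be a Spectrum or NULL", nm))
    }
    if (length(msgs)) msgs else TRUE
})

#' Single-cell emission spectra under donor and acceptor excitation
#'
#' @slot donorExc emission spectrum acquired with donor excitation.
#' @slot acceptorExc emission spectrum acquired with acceptor excitation.
#' @slot acceptorClass one of `"green_yellow"`, `"orange_red_with_green"`,
#'   `"red_no_green"`; selects the unmixing strategy and fit range.
#' @slot normalized logical; TRUE once [alignAndNormalize()] has divided the
#'   donor-excitation spectrum by the acceptor-excitation peak.
#' @seealso [CellSpectra()], [alignAndNormalize()], [genCellSpectra()]
#' @exportClass CellSpectra
setClass("CellSpectra",
    representation(
        donorExc = "Spectrum",
        acceptorExc = "Spectrum",
        acceptorClass = "character",
        normalized = "logical"
    )
)

setValidity("CellSpectra", function(object) {
    msgs <- character()
    if (!object@acceptorClass %in% .ACCEPTOR_CLASSES)
        msgs <- c(msgs, sprintf("acceptorClass must be one of: %s",
                                paste(.ACCEPTOR_CLASSES, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' Result of spectral decomposition of a cell spectrum
#'
#' Donor, sensitized-emission, green and direct-excitation components of a
#' measured cell spectrum, the regression coefficients and the residual norm
#' on the fit range. Apparent efficiencies are computed from this object by
#' [apparentEfficiency()].
#'
#' @slot FD,FS,FG,FA component [Spectrum-class]s on the cell grid (FG and FA
#'   may be zero-valued when absent).
#' @slot coefficients named regression coefficients.
#' @slot residualNorm L2 norm of the fit residual on the fit range.
#' @slot fitRangeNm numeric length-2 wavelength window used for regression.
#' @slot acceptorClass the class that selected the strategy.
#' @exportClass UnmixResult
setClass("UnmixResult",
    representation(
        FD = "Spectrum",
        FS = "Spectrum",
        FG = "Spectrum",
        FA = "Spectrum",
        coefficients = "numeric",
        residualNorm = "numeric",
        fitRangeNm = "numeric",
        acceptorClass = "character"
    )
)

#' Two-channel intensity time series
#'
#' Timestamped donor/acceptor intensity trace from a bleaching or biosensor
#' experiment, with per-channel backgrounds and optional labelled event times
#' (e.g. agonist and antagonist addition).
#'
#' @slot timeS strictly increasing timestamps, s.
#' @slot donor,acceptor per-timepoint intensities.
#' @slot backgroundDonor,backgroundAcceptor scalar or per-timepoint background.
#' @slot events named numeric vector of event times (names such as
#'   `"agonist"`, `"antagonist"`), possibly empty.
#' @slot normalized logical; TRUE after [normalizeTrace()].
#' @seealso [IntensityTrace()], [normalizeTrace()], [ratioResponse()]
#' @exportClass IntensityTrace
setClass("IntensityTrace",
    representation(
        timeS = "numeric",
        donor = "numeric",
        acceptor = "numeric",
        backgroundDonor = "numeric",
        backgroundAcceptor = "numeric",
        events = "numeric",
        normalized = "logical"
    )
)

setValidity("IntensityTrace", function(object) {
    msgs <- character()
    n <- length(object@timeS)
    if (length(object@donor) != n || length(object@acceptor) != n)
        msgs <- c(msgs, "time, donor and acceptor must have equal lengths")
    if (n >= 2 && any(diff(object@timeS) <= 0))
        msgs <- c(msgs, "timestamps must be strictly increasing")
    for (nm in c("backgroundDonor", "backgroundAcceptor")) {
        b <- slot(object, nm)
        if (!length(b) %in% c(1L, n))
            msgs <- c(msgs, sprintf("%s must be scalar or per-timepoint", nm))
    }
    if (length(object@events) && is.null(names(object@events)))
        msgs <- c(msgs, "events must be a named numeric vector")
    if (length(msgs)) msgs else TRUE
})

#' Ratiometric biosensor response summary
#'
#' @slot timeS,ratio the per-frame FRET ratio trace.
#' @slot baseline mean pre-agonist ratio.
#' @slot amplitudePct maximal relative ratio deviation after agonist, percent.
#' @slot recoveryPct fraction of the response reversed after antagonist,
#'   percent (may exceed 100 on overshoot).
#' @slot responder logical, amplitude at or above the responder threshold.
#' @slot thresholdPct the threshold applied.
#' @seealso [ratioResponse()]
#' @exportClass RatioResponse
setClass("RatioResponse",
    representation(
        timeS = "numeric",
        ratio = "numeric",
        baseline = "numeric",
        amplitudePct = "numeric",
        recoveryPct = "numeric",
        responder = "logical",
        thresholdPct = "numeric"
    )
)
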