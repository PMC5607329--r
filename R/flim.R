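#' Construct a homodyne phase stack
#'
#' @param frames rows x cols x K array of non-negative intensities, or a
#'   K-row matrix of single-pixel intensities which is promoted to 1 x 1 x K.
#' @param phaseStepsRad length-K phase angles (radians); frame k corresponds
#'   to phase step k.
#' @param frequencyHz modulation frequency, Hz.
#' @param acquisitionOrder permutation of `1:K` recording the temporal order
#'   in which the phase steps were visited (default: sequential).
#' @return A [PhaseStack-class] object.
#' @export
PhaseStack <- function(frames, phaseStepsRad, frequencyHz,
                       acquisitionOrder = seq_along(phaseStepsRad)) {
    if (is.null(dim(frames)))
        frames <- array(frames, dim = c(1L, 1L, length(frames)))
    new("PhaseStack", frames = frames,
        phaseStepsRad = as.numeric(phaseStepsRad),
        frequencyHz = as.numeric(frequencyHz),
        acquisitionOrder = as.integer(acquisitionOrder))
}

setMethod("show", "PhaseStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf(
        "PhaseStack: %d x %d pixels, %d phase steps, f = %.3g MHz\n",
        d[1], d[2], d[3], object@frequencyHz / 1e6))
})

#' @describeIn PhaseStack number of phase steps.
#' @param x a `PhaseStack`.
#' @export
nPhaseSteps <- function(x) length(x@phaseStepsRad)

#' @describeIn PhaseStack modulation frequency accessor (Hz).
#' @export
modulationFrequency <- function(x) x@frequencyHz

.wrap2pi <- function(phi) phi %% (2 * pi)
.wrapPi <- function(phi) ((phi + pi) %% (2 * pi)) - pi

# Theoretical single-lifetime phasor at modulation frequency f.
.phasorFromTau <- function(tauNs, frequencyHz) {
    wt <- 2 * pi * frequencyHz * tauNs * 1e-9
    list(phase = atan(wt), modulation = 1 / sqrt(1 + wt^2))
}

#' Phasor of a lifetime mixture
#'
#' Phasor coordinates add linearly under intensity (DC) weighting:
#' G = sum w_i / (1 + (omega tau_i)^2), S = sum w_i omega tau_i /
#' (1 + (omega tau_i)^2). The apparent phase lifetime of a mixture is pulled
#' below its apparent modulation lifetime.
#'
#' @param tausNs component lifetimes, ns.
#' @param weights DC intensity weights (normalized internally).
#' @param frequencyHz modulation frequency, Hz.
#' @return list with `phase` (rad), `modulation`, `g`, `s`.
#' @export
mixturePhasor <- function(tausNs, weights = rep(1, length(tausNs)),
                          frequencyHz) {
    if (length(weights) != length(tausNs))
        stop("weights must match tausNs in length")
    w <- weights / sum(weights)
    wt <- 2 * pi * frequencyHz * tausNs * 1e-9
    g <- sum(w / (1 + wt^2))
    s <- sum(w * wt / (1 + wt^2))
    list(phase = atan2(s, g), modulation = sqrt(g^2 + s^2), g = g, s = s)
}

.scalarPhasor <- function(dc, phase, modulation, undefined = FALSE) {
    new("PhasorEstimate",
        dc = as.array(dc), ac = as.array(modulation * dc),
        phaseRad = as.array(.wrap2pi(phase)),
        modulation = as.array(modulation),
        undefined = as.array(undefined))
}

# Least-squares first-harmonic fit of a frames array against phase steps.
# For equally spaced steps this reduces to the discrete Fourier coefficients.
.fitPhasorArray <- function(frames, phaseStepsRad, acFloor = 1e-3) {
    d <- dim(frames)
    npix <- d[1] * d[2]
    Y <- matrix(frames, nrow = npix, ncol = d[3])   # pixels x K
    X <- cbind(1, cos(phaseStepsRad), sin(phaseStepsRad))
    B <- solve(crossprod(X), crossprod(X, t(Y)))    # 3 x pixels
    dc <- B[1, ]
    a <- B[2, ]
    b <- B[3, ]
    ac <- sqrt(a^2 + b^2)
    undefined <- dc <= 0 | ac / pmax(dc, .Machine$double.eps) < acFloor
    phase <- .wrap2pi(atan2(b, a))
    modulation <- ac / dc
    phase[undefined] <- NA_real_
    modulation[undefined] <- NA_real_
    shape <- d[1:2]
    new("PhasorEstimate",
        dc = array(dc, shape), ac = array(ac, shape),
        phaseRad = array(phase, shape),
        modulation = array(modulation, shape),
        undefined = array(undefined, shape))
}

#' Per-pixel first-harmonic phasor fit of a phase stack
#'
#' Fits I_k = DC + AC * cos(theta_k - phi) per pixel by linear least squares
#' on the (1, cos theta_k, sin theta_k) design. For equally spaced phase
#' steps the estimate equals the first-harmonic discrete Fourier coefficients;
#' because frames are paired with their phase steps, the result does not
#' depend on the temporal acquisition order. Pixels whose relative harmonic
#' amplitude AC/DC falls below `acFloor` are flagged `undefined` (their phase
#' is meaningless noise) rather than propagating NaN.
#'
#' @param stack a [PhaseStack-class].
#' @param pixelMask optional logical matrix; pixels outside the mask are
#'   flagged undefined.
#' @param acFloor undefined-phase floor on AC/DC (default 1e-3).
#' @return A [PhasorEstimate-class] map with the stack's pixel shape.
#' @export
fitPhasor <- function(stack, pixelMask = NULL, acFloor = 1e-3) {
    est <- .fitPhasorArray(stack@frames, stack@phaseStepsRad, acFloor)
    if (!is.null(pixelMask)) {
        if (!all(dim(pixelMask) == dim(est@dc)))
            stop("pixelMask shape must match the stack frames")
        est@undefined <- est@undefined | !pixelMask
        est@phaseRad[!pixelMask] <- NA_real_
        est@modulation[!pixelMask] <- NA_real_
    }
    est
}

setMethod("show", "PhasorEstimate", function(object) {
    n <- length(object@dc)
    if (n == 1L) {
        cat(sprintf(
            "PhasorEstimate: DC = %.4g, phase = %.4f rad, M = %.4f%s\n",
            object@dc, object@phaseRad, object@modulation,
            if (object@undefined) " (undefined)" else ""))
    } else {
        cat(sprintf(
            "PhasorEstimate map: %s pixels, %d undefined\n",
            paste(dim(object@dc), collapse = " x "), sum(object@undefined)))
    }
})

#' Average a phasor map over a region of interest
#'
#' Averaging is done in rectangular phasor coordinates
#' (G, S) = (M cos phi, M sin phi), not on lifetimes, because lifetimes are
#' nonlinear in the phasor and per-pixel noise would bias region means.
#'
#' @param p a [PhasorEstimate-class] map.
#' @param mask optional logical matrix selecting pixels.
#' @param intensityWeighted weight pixels by their DC intensity.
#' @return A scalar [PhasorEstimate-class].
#' @export
averagePhasor <- function(p, mask = NULL, intensityWeighted = FALSE) {
    keep <- !p@undefined
    if (!is.null(mask)) keep <- keep & mask
    if (!any(keep)) {
        if (!is.null(mask) && any(mask))
            return(.scalarPhasor(mean(p@dc[mask]), NA_real_, NA_real_,
                                 undefined = TRUE))
        stop("empty ROI: no defined pixels to average")
    }
    w <- if (intensityWeighted) p@dc[keep] else rep(1, sum(keep))
    w <- w / sum(w)
    g <- sum(w * p@modulation[keep] * cos(p@phaseRad[keep]))
    s <- sum(w * p@modulation[keep] * sin(p@phaseRad[keep]))
    .scalarPhasor(mean(p@dc[keep]), atan2(s, g), sqrt(g^2 + s^2))
}

#' Construct a FLIM calibration reference
#'
#' @param measured a scalar [PhasorEstimate-class], a phasor map (averaged
#'   internally) or a [PhaseStack-class] of the reference sample (fitted and
#'   averaged internally).
#' @param knownTauPhaseNs,knownTauModNs the reference's known phase and
#'   modulation lifetimes, ns (e.g. 3.8/4.0 for mTurquoise2, 0.086/0.086 for
#'   Erythrosin B, 0/0 for reflected excitation light).
#' @return A [CalibrationReference-class].
#' @export
calibrationReference <- function(measured, knownTauPhaseNs,
                                 knownTauModNs = knownTauPhaseNs) {
    if (is(measured, "PhaseStack")) measured <- fitPhasor(measured)
    if (length(measured@dc) > 1L) measured <- averagePhasor(measured)
    new("CalibrationReference", measured = measured,
        knownTauPhaseNs = as.numeric(knownTauPhaseNs),
        knownTauModNs = as.numeric(knownTauModNs))
}

setMethod("show", "CalibrationReference", function(object) {
    cat(sprintf(
        "CalibrationReference: known tau_phi/tau_M = %.3f/%.3f ns, measured phase %.4f rad, M %.4f\n",
        object@knownTauPhaseNs, object@knownTauModNs,
        object@measured@phaseRad, object@measured@modulation))
})

#' Calibrate a phasor estimate against a reference of known lifetime
#'
#' Subtracts the instrument phase offset and divides out the instrument
#' modulation factor. The reference's true phase and modulation are obtained
#' from its known lifetimes: phi_true = arctan(omega tau), M_true =
#' 1 / sqrt(1 + (omega tau)^2).
#'
#' @param sample a [PhasorEstimate-class] (scalar or map).
#' @param ref a [CalibrationReference-class] measured at the same frequency.
#' @param frequencyHz modulation frequency, Hz.
#' @return The calibrated [PhasorEstimate-class].
#' @export
calibratePhasor <- function(sample, ref, frequencyHz) {
    m <- ref@measured
    if (m@undefined[1] || !is.finite(m@modulation[1]) || m@modulation[1] <= 0)
        stop("calibration error: reference modulation is zero or undefined")
    phiTrue <- .phasorFromTau(ref@knownTauPhaseNs, frequencyHz)$phase
    modTrue <- .phasorFromTau(ref@knownTauModNs, frequencyHz)$modulation
    phaseOffset <- m@phaseRad[1] - phiTrue
    modFactor <- m@modulation[1] / modTrue
    out <- sample
    out@phaseRad <- array(.wrap2pi(sample@phaseRad - phaseOffset),
                          dim(sample@phaseRad))
    out@modulation <- sample@modulation / modFactor
    out@ac <- out@modulation * out@dc
    out
}

#' Phase and modulation lifetimes from a calibrated phasor
#'
#' tau_phi = tan(phi) / omega and tau_M = sqrt(1/M^2 - 1) / omega with
#' omega = 2 pi f. Requires a calibrated phasor; M slightly above 1 (within
#' `tol`) is clamped, larger values are unphysical for single-frequency data.
#'
#' @param p a [PhasorEstimate-class] (scalar or map).
#' @param frequencyHz modulation frequency, Hz.
#' @param tol tolerance on M above 1 before declaring the phasor unphysical.
#' @param onUnphysical `"error"` (default) or `"na"` to flag offending pixels
#'   with NA (useful for noisy per-pixel maps).
#' @return A [LifetimePair-class]; slots keep the input shape for maps.
#' @export
lifetimesFromPhasor <- function(p, frequencyHz, tol = 1e-6,
                                onUnphysical = c("error", "na")) {
    onUnphysical <- match.arg(onUnphysical)
    omega <- 2 * pi * frequencyHz
    phi <- .wrapPi(p@phaseRad)
    m <- p@modulation
    badPhi <- is.finite(phi) & phi >= pi / 2
    badM <- is.finite(m) & m > 1 + tol
    if (onUnphysical == "error") {
        if (any(badM))
            stop("unphysical modulation: M > 1 after calibration")
        if (any(badPhi))
            stop("unphysical phase: phi >= pi/2")
    } else {
        phi[badPhi] <- NA_real_
        m[badM] <- NA_real_
    }
    m <- pmin(m, 1)
    tphi <- tan(phi) / omega * 1e9
    tmod <- sqrt(1 / m^2 - 1) / omega * 1e9
    dm <- dim(p@phaseRad)
    if (!is.null(dm) && length(p@phaseRad) > 1L) {
        dim(tphi) <- dm
        dim(tmod) <- dm
    } else {
        tphi <- as.numeric(tphi)
        tmod <- as.numeric(tmod)
    }
    new("LifetimePair", tauPhaseNs = tphi, tauModNs = tmod)
}

#' @describeIn lifetimesFromPhasor phase-lifetime accessor (ns).
#' @param x a `LifetimePair`.
#' @export
tauPhase <- function(x) x@tauPhaseNs

#' @describeIn lifetimesFromPhasor modulation-lifetime accessor (ns).
#' @export
tauMod <- function(x) x@tauModNs

setMethod("show", "LifetimePair", function(object) {
    if (length(object@tauPhaseNs) == 1L)
        cat(sprintf("LifetimePair: tau_phi = %.4f ns, tau_M = %.4f ns\n",
                    object@tauPhaseNs, object@tauModNs))
    else
        cat(sprintf("LifetimePair map: %d pixels, mean tau_phi = %.3f ns\n",
                    length(object@tauPhaseNs),
                    mean(object@tauPhaseNs, na.rm = TRUE)))
})

#' FRET efficiency from donor lifetime quenching
#'
#' E = (1 - tau_DA / tau_D) * 100 percent, where tau_DA is the donor lifetime
#' in presence of the acceptor and tau_D the unquenched donor lifetime. A
#' tau_DA above tau_D yields a negative E with a warning (donor dequenching
#' or an artifact).
#'
#' @param tauDaNs donor lifetime with acceptor, ns (vectorized).
#' @param tauDNs unquenched donor lifetime, ns.
#' @return Efficiency in percent.
#' @examples
#' fretEfficiencyFromLifetime(2.02, 3.77)  # ~46 percent
#' @export
fretEfficiencyFromLifetime <- function(tauDaNs, tauDNs) {
    if (tauDNs <= 0) stop("tauDNs must be positive")
    if (any(tauDaNs < 0)) stop("tauDaNs must be >= 0")
    e <- (1 - tauDaNs / tauDNs) * 100
    if (any(e < 0))
        warning("tau_DA exceeds tau_D: negative efficiency indicates donor ",
                "dequenching or a calibration artifact")
    e
}

# 3x3 mean blur with replicated edges.
.box3 <- function(m) {
    nr <- nrow(m)
    nc <- ncol(m)
    mp <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
    out <- matrix(0, nr, nc)
    for (di in 0:2)
        for (dj in 0:2)
            out <- out + mp[di + seq_len(nr), dj + seq_len(nc)]
    out / 9
}

#' Region-of-interest lifetime time course from a series of phase stacks
#'
#' Per timepoint: background subtraction (mean over a background mask),
#' optional 3x3 mean blur, per-pixel phasor fit, reference calibration,
#' phasor averaging over the ROI and conversion to lifetimes. Returns the
#' phase-lifetime trace used for agonist/antagonist activation analysis.
#'
#' @param stacks time-ordered list of [PhaseStack-class]s with consistent
#'   geometry.
#' @param ref a [CalibrationReference-class].
#' @param roiMask logical matrix selecting the cell pixels.
#' @param backgroundMask optional logical matrix of background pixels.
#' @param smoothing `"none"` or `"box3"` (3x3 mean blur per frame).
#' @param timeS optional timestamps (defaults to the stack index).
#' @return data.frame with columns `time_s`, `tau_phase_ns`, `tau_mod_ns`,
#'   `delta_tau_phase_ns` (change from the first timepoint).
#' @export
roiLifetimeTimecourse <- function(stacks, ref, roiMask, backgroundMask = NULL,
                                  smoothing = c("none", "box3"),
                                  timeS = seq_along(stacks) - 1) {
    smoothing <- match.arg(smoothing)
    if (!any(roiMask)) stop("empty ROI")
    tphi <- tmod <- rep(NA_real_, length(stacks))
    for (i in seq_along(stacks)) {
        st <- stacks[[i]]
        frames <- st@frames
        if (!all(dim(frames)[1:2] == dim(roiMask)))
            stop("ROI mask shape must match the stack frames")
        if (!is.null(backgroundMask)) {
            for (k in seq_len(dim(frames)[3]))
                frames[, , k] <- frames[, , k] -
                    mean(frames[, , k][backgroundMask])
        }
        if (smoothing == "box3")
            for (k in seq_len(dim(frames)[3]))
                frames[, , k] <- .box3(frames[, , k])
        est <- .fitPhasorArray(frames, st@phaseStepsRad)
        avg <- averagePhasor(est, roiMask)
        if (avg@undefined[1]) next   # all-background ROI at this timepoint
        cal <- calibratePhasor(avg, ref, st@frequencyHz)
        lt <- lifetimesFromPhasor(cal, st@frequencyHz, onUnphysical = "na")
        tphi[i] <- lt@tauPhaseNs
        tmod[i] <- lt@tauModNs
    }
    data.frame(time_s = timeS, tau_phase_ns = tphi, tau_mod_ns = tmod,
               delta_tau_phase_ns = tphi - tphi[1])
}
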