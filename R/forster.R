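#' Construct Forster theory parameters
#'
#' @param kappaSq orientation factor kappa^2 (default 2/3, isotropic dynamic
#'   averaging).
#' @param refractiveIndex medium refractive index (default 1.33, aqueous).
#' @param donorQY donor quantum yield (default 0.93, mTurquoise2).
#' @return A [FretTheoryParams-class] object.
#' @export
FretTheoryParams <- function(kappaSq = 2 / 3, refractiveIndex = 1.33,
                             donorQY = 0.93) {
    new("FretTheoryParams", kappaSq = kappaSq,
        refractiveIndex = refractiveIndex, donorQY = donorQY)
}

setMethod("show", "FretTheoryParams", function(object) {
    cat(sprintf("FretTheoryParams: kappa^2 = %.4f, n = %.3f, Q_D = %.3f\n",
                object@kappaSq, object@refractiveIndex, object@donorQY))
})

#' Construct a FluorophoreRecord
#'
#' @param name identifier.
#' @param absorptionPeakNm absorption maximum, nm.
#' @param epsilonMax peak molar extinction coefficient, M^-1 cm^-1.
#' @param quantumYield fluorescence quantum yield in `[0, 1]`.
#' @param absorbance,emission [Spectrum-class] objects of matching kind.
#' @return A [FluorophoreRecord-class] object.
#' @export
FluorophoreRecord <- function(name, absorptionPeakNm, epsilonMax, quantumYield,
                              absorbance, emission) {
    new("FluorophoreRecord", name = name,
        absorptionPeakNm = as.numeric(absorptionPeakNm),
        epsilonMax = as.numeric(epsilonMax),
        quantumYield = as.numeric(quantumYield),
        absorbance = absorbance, emission = emission)
}

setMethod("show", "FluorophoreRecord", function(object) {
    cat(sprintf(
        "FluorophoreRecord '%s': abs peak %.0f nm, eps_max %.3g /M/cm, QY %.2f\n",
        object@name, object@absorptionPeakNm, object@epsilonMax,
        object@quantumYield))
    cat(sprintf("  emission peak %.0f nm\n", peakWavelength(object@emission)))
})

#' Spectral overlap integral J
#'
#' J = integral over lambda of f_D(lambda) * eps_A(lambda) * lambda^4, with
#' f_D the area-normalized donor emission and eps_A the acceptor extinction
#' spectrum (peak-normalized absorbance scaled to `epsilonMax`). Both inputs
#' are re-normalized internally, so the result is invariant to the arbitrary
#' amplitude of either input. Integration is trapezoidal on the shared grid.
#'
#' @param donorEmission donor emission [Spectrum-class].
#' @param acceptorAbsorbance acceptor absorbance [Spectrum-class]; must share
#'   the wavelength grid of `donorEmission`.
#' @param epsilonMax acceptor peak extinction, M^-1 cm^-1.
#' @return J in M^-1 cm^-1 nm^4.
#' @export
overlapIntegral <- function(donorEmission, acceptorAbsorbance, epsilonMax) {
    w <- donorEmission@wavelengths
    wa <- acceptorAbsorbance@wavelengths
    if (length(w) != length(wa) || any(abs(w - wa) > 1e-9))
        stop("grid mismatch: donor emission and acceptor absorbance must be ",
             "resampled to a common wavelength grid")
    if (epsilonMax <= 0) stop("epsilonMax must be positive")
    if (any(donorEmission@values < 0) || any(acceptorAbsorbance@values < 0))
        stop("spectra entering the overlap integral must be non-negative")
    fD <- normalizeSpectrum(donorEmission, "area")@values
    absA <- acceptorAbsorbance@values
    epsA <- absA / max(absA) * epsilonMax
    J <- pracma::trapz(w, fD * epsA * w^4)
    max(J, 0)
}

#' Forster radius from the overlap integral
#'
#' R0^6 = 8.79e-5 * kappa^2 * n^-4 * Q_D * J with J in M^-1 cm^-1 nm^4 gives
#' R0 in Angstrom (equivalently R0 = 0.2108 * (kappa^2 n^-4 Q_D J)^(1/6)).
#'
#' @param J overlap integral, M^-1 cm^-1 nm^4 (vectorized).
#' @param params a [FretTheoryParams-class].
#' @return Forster radius in Angstrom.
#' @examples
#' forsterRadius(3.15e15)  # ~62 Angstrom for a cyan-green pair
#' @export
forsterRadius <- function(J, params = FretTheoryParams()) {
    if (any(J < 0)) stop("overlap integral J must be >= 0")
    validObject(params)
    (8.79e-5 * params@kappaSq * params@refractiveIndex^-4 *
        params@donorQY * J)^(1 / 6)
}

#' FRET efficiency at a donor-acceptor distance
#'
#' E = 1 / (1 + (r/R0)^6); strictly decreasing in r, E = 1/2 at r = R0.
#'
#' @param R0 Forster radius (any length unit).
#' @param r donor-acceptor distance, same unit (vectorized).
#' @return Transfer efficiency as a fraction in `[0, 1]`.
#' @export
efficiencyAtDistance <- function(R0, r) {
    if (R0 <= 0) stop("R0 must be positive")
    if (any(r < 0)) stop("distance must be >= 0")
    1 / (1 + (r / R0)^6)
}

#' Forster theory for a donor-acceptor pair
#'
#' Resamples donor emission and acceptor absorbance onto a common grid
#' spanning the union of their supports, computes the overlap integral and
#' the Forster radius.
#'
#' @param donor,acceptor [FluorophoreRecord-class] objects.
#' @param params a [FretTheoryParams-class]; `donorQY` defaults to the donor
#'   record's quantum yield.
#' @param stepNm integration grid step, nm.
#' @return A [FretPairTheory-class] object.
#' @export
fretPairTheory <- function(donor, acceptor, params = NULL, stepNm = 1) {
    if (is.null(params))
        params <- FretTheoryParams(donorQY = donor@quantumYield)
    grid <- commonGrid(donor@emission, acceptor@absorbance, stepNm = stepNm)
    em <- resampleSpectrumOnto(donor@emission, grid)
    ab <- resampleSpectrumOnto(acceptor@absorbance, grid)
    J <- overlapIntegral(em, ab, acceptor@epsilonMax)
    new("FretPairTheory", donor = donor, acceptor = acceptor,
        overlapJ = J, R0Angstrom = forsterRadius(J, params), params = params)
}

#' @describeIn fretPairTheory overlap-integral accessor.
#' @param x a `FretPairTheory`.
#' @export
overlapJ <- function(x) x@overlapJ

#' @describeIn fretPairTheory Forster-radius accessor (Angstrom).
#' @export
R0Angstrom <- function(x) x@R0Angstrom

setMethod("show", "FretPairTheory", function(object) {
    cat(sprintf(
        "FretPairTheory %s -> %s: J = %.3g /M/cm nm^4, R0 = %.1f Angstrom\n",
        object@donor@name, object@acceptor@name,
        object@overlapJ, object@R0Angstrom))
})

#' Simulate the emission spectrum of a FRET pair at a given efficiency
#'
#' Photon bookkeeping on area-normalized emission shapes: the donor
#' contributes (1 - E) * Q_D * f_D, transfer contributes E * Q_A * f_A, and
#' direct acceptor excitation adds a further Q_A * f_A term.
#'
#' @param donor,acceptor [FluorophoreRecord-class] objects.
#' @param E transfer efficiency in `[0, 1]`.
#' @param directExcitationFraction direct acceptor excitation rate relative to
#'   donor excitation (>= 0).
#' @param stepNm output grid step, nm.
#' @return An emission [Spectrum-class] on the union-of-supports grid.
#' @export
simulatePairSpectrum <- function(donor, acceptor, E,
                                 directExcitationFraction = 0, stepNm = 1) {
    if (E < 0 || E > 1) stop("E must lie in [0, 1]")
    if (directExcitationFraction < 0)
        stop("directExcitationFraction must be >= 0")
    grid <- commonGrid(donor@emission, acceptor@emission, stepNm = stepNm)
    fD <- normalizeAfterResample(donor@emission, grid)
    fA <- normalizeAfterResample(acceptor@emission, grid)
    v <- (1 - E) * donor@quantumYield * fD +
        (E + directExcitationFraction) * acceptor@quantumYield * fA
    new("Spectrum", wavelengths = as.numeric(grid), values = v,
        kind = "emission", normalization = "raw")
}

# Resample then area-normalize on the target grid.
normalizeAfterResample <- function(spec, grid) {
    s <- resampleSpectrumOnto(spec, grid)
    s@values / pracma::trapz(s@wavelengths, s@values)
}
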