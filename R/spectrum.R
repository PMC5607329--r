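#' Construct a Spectrum
#'
#' @param wavelengths numeric wavelength grid in nm (any order; sorted
#'   internally). Duplicate wavelengths are rejected.
#' @param values intensities, same length as `wavelengths`; must be
#'   non-negative unless `allowNegative = TRUE` (used internally for
#'   background-corrected difference spectra).
#' @param kind `"absorbance"`, `"emission"` or `"excitation"`.
#' @param normalization `"raw"`, `"peak"` or `"area"`.
#' @param allowNegative permit negative values (difference spectra).
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(c(400, 450, 500), c(0, 1, 0), kind = "emission")
#' peakWavelength(s)
#' @export
Spectrum <- function(wavelengths, values, kind = "emission",
                     normalization = "raw", allowNegative = FALSE) {
    if (length(wavelengths) < 2L)
        stop("degenerate input: a spectrum needs at least 2 samples")
    if (anyDuplicated(wavelengths))
        stop("duplicate wavelengths in spectrum")
    o <- order(wavelengths)
    wavelengths <- as.numeric(wavelengths[o])
    values <- as.numeric(values[o])
    if (!allowNegative && any(values < 0))
        stop("spectrum values must be non-negative")
    new("Spectrum", wavelengths = wavelengths, values = values,
        kind = kind, normalization = normalization)
}

#' @describeIn Spectrum wavelength grid accessor (nm).
#' @param x,object a `Spectrum`.
#' @export
wavelengths <- function(x) x@wavelengths

#' @describeIn Spectrum intensity accessor.
#' @export
intensities <- function(x) x@values

#' @describeIn Spectrum declared kind accessor.
#' @export
spectrumKind <- function(x) x@kind

#' @describeIn Spectrum normalization-state accessor.
#' @export
normalizationState <- function(x) x@normalization

#' @describeIn Spectrum wavelength of the maximum value (nm).
#' @export
peakWavelength <- function(x) x@wavelengths[which.max(x@values)]

#' @export
setMethod("length", "Spectrum", function(x) length(x@wavelengths))

setMethod("show", "Spectrum", function(object) {
    w <- object@wavelengths
    cat(sprintf("Spectrum (%s, %s): %d samples, %.1f-%.1f nm, peak at %.1f nm\n",
                object@kind, object@normalization, length(w),
                min(w), max(w), peakWavelength(object)))
})

#' Trapezoidal integral of a spectrum over its grid
#'
#' @param spec a [Spectrum-class].
#' @return The trapezoidal integral of value over wavelength.
#' @export
spectrumIntegral <- function(spec) {
    pracma::trapz(spec@wavelengths, spec@values)
}

#' Normalize a spectrum to unit peak or unit area
#'
#' Peak normalization divides by the maximum value so that `max(values) == 1`;
#' area normalization divides by the trapezoidal integral so the spectrum
#' integrates to 1 over its grid.
#'
#' @param spec a [Spectrum-class].
#' @param method `"peak"` or `"area"`.
#' @return The normalized [Spectrum-class].
#' @export
normalizeSpectrum <- function(spec, method = c("peak", "area")) {
    method <- match.arg(method)
    denom <- switch(method,
        peak = max(spec@values),
        area = spectrumIntegral(spec))
    if (!is.finite(denom) || denom <= 0)
        stop("cannot normalize: spectrum has non-positive ", method)
    new("Spectrum", wavelengths = spec@wavelengths,
        values = spec@values / denom, kind = spec@kind, normalization = method)
}

#' Read a two-column wavelength/value spectrum from CSV
#'
#' Accepts `wavelength_nm,value` tables with an optional header row. Rows are
#' sorted by wavelength; duplicate wavelengths and non-numeric rows are
#' rejected with the offending line named.
#'
#' @param path file path.
#' @param kind declared spectrum kind, see [Spectrum-class].
#' @return A raw [Spectrum-class].
#' @export
readSpectrum <- function(path, kind = c("emission", "absorbance", "excitation")) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("degenerate input: empty spectrum file ", path)
    fields <- strsplit(lines, "[,;\t]")
    first <- suppressWarnings(as.numeric(fields[[1]]))
    start <- if (anyNA(first)) 2L else 1L   # header row
    if (length(lines) - start + 1L < 2L)
        stop("degenerate input: fewer than 2 data rows in ", path)
    w <- v <- numeric(length(lines) - start + 1L)
    for (i in seq(start, length(lines))) {
        f <- suppressWarnings(as.numeric(fields[[i]]))
        if (length(f) < 2L || anyNA(f[1:2]))
            stop(sprintf("parse error in %s at line %d: '%s'",
                         path, i, lines[i]))
        w[i - start + 1L] <- f[1]
        v[i - start + 1L] <- f[2]
    }
    Spectrum(w, v, kind = kind, normalization = "raw")
}

#' Write a spectrum as a two-column CSV
#'
#' @param spec a [Spectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spec, path) {
    utils::write.csv(
        data.frame(wavelength_nm = spec@wavelengths, value = spec@values),
        path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Resample a spectrum onto a regular wavelength grid
#'
#' Linear interpolation inside the measured support; wavelengths outside the
#' source range are set to zero (spectra are not extrapolated).
#'
#' @param spec a [Spectrum-class].
#' @param gridStartNm,gridEndNm,stepNm target grid, nm.
#' @return The resampled [Spectrum-class] (kind preserved, normalization
#'   reset to `"raw"` unless the grid is identical).
#' @export
resampleSpectrum <- function(spec, gridStartNm, gridEndNm, stepNm = 1) {
    if (stepNm <= 0) stop("stepNm must be positive")
    grid <- seq(gridStartNm, gridEndNm, by = stepNm)
    resampleSpectrumOnto(spec, grid)
}

#' @describeIn resampleSpectrum resample onto an explicit wavelength vector.
#' @param grid explicit target wavelength grid, nm.
#' @export
resampleSpectrumOnto <- function(spec, grid) {
    w <- spec@wavelengths
    if (max(grid) < min(w) || min(grid) > max(w))
        stop("empty support: requested grid does not overlap the spectrum")
    if (length(grid) == length(w) && all(grid == w)) return(spec)
    v <- stats::approx(w, spec@values, xout = grid, rule = 1)$y
    v[is.na(v)] <- 0
    new("Spectrum", wavelengths = as.numeric(grid), values = v,
        kind = spec@kind, normalization = "raw")
}

# Common 1 nm (default) grid spanning the union of supports of several spectra.
commonGrid <- function(..., stepNm = 1) {
    specs <- list(...)
    lo <- min(vapply(specs, function(s) min(s@wavelengths), 0))
    hi <- max(vapply(specs, function(s) max(s@wavelengths), 0))
    seq(floor(lo), ceiling(hi), by = stepNm)
}
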