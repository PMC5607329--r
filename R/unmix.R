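#' Construct a reference set for spectral unmixing
#'
#' Donor and acceptor emission references are area-normalized internally and
#' resampled to the donor reference grid, as are the optional direct-excitation
#' and green-contaminant shapes.
#'
#' @param donorRef donor-only emission [Spectrum-class] (donor excitation).
#' @param acceptorRef acceptor emission [Spectrum-class].
#' @param directShape acceptor-only control spectrum under donor excitation,
#'   normalized to the peak of its own acceptor-excitation spectrum (see
#'   [subtractDirectExcitation()]); NULL if unavailable.
#' @param greenRef EGFP-like green contaminant emission shape, or NULL.
#' @param qD,qA donor and acceptor quantum yields.
#' @return A [ReferenceSet-class].
#' @export
ReferenceSet <- function(donorRef, acceptorRef, directShape = NULL,
                         greenRef = NULL, qD = 0.93, qA) {
    grid <- donorRef@wavelengths
    donorRef <- normalizeSpectrum(donorRef, "area")
    acceptorRef <- normalizeSpectrum(resampleSpectrumOnto(acceptorRef, grid),
                                     "area")
    if (!is.null(greenRef))
        greenRef <- normalizeSpectrum(resampleSpectrumOnto(greenRef, grid),
                                      "area")
    if (!is.null(directShape))
        directShape <- resampleSpectrumOnto(directShape, grid)
    new("ReferenceSet", donorRef = donorRef, acceptorRef = acceptorRef,
        directShape = directShape, greenRef = greenRef,
        qD = as.numeric(qD), qA = as.numeric(qA))
}

setMethod("show", "ReferenceSet", function(object) {
    cat(sprintf(
        "ReferenceSet: Q_D = %.2f, Q_A = %.2f, direct shape %s, green ref %s\n",
        object@qD, object@qA,
        if (is.null(object@directShape)) "absent" else "present",
        if (is.null(object@greenRef)) "absent" else "present"))
})

#' Construct single-cell spectra
#'
#' @param donorExc emission [Spectrum-class] under donor excitation.
#' @param acceptorExc emission [Spectrum-class] under acceptor excitation.
#' @param acceptorClass `"green_yellow"`, `"orange_red_with_green"` or
#'   `"red_no_green"`.
#' @return A [CellSpectra-class].
#' @export
CellSpectra <- function(donorExc, acceptorExc,
                        acceptorClass = c("green_yellow",
                                          "orange_red_with_green",
                                          "red_no_green")) {
    acceptorClass <- match.arg(acceptorClass)
    new("CellSpectra", donorExc = donorExc, acceptorExc = acceptorExc,
        acceptorClass = acceptorClass, normalized = FALSE)
}

setMethod("show", "CellSpectra", function(object) {
    cat(sprintf("CellSpectra (%s%s): donor-excitation %d samples, acceptor-excitation %d samples\n",
                object@acceptorClass,
                if (object@normalized) ", normalized" else "",
                length(object@donorExc), length(object@acceptorExc)))
})

#' Align cell spectra and normalize to the acceptor-excitation peak
#'
#' Both spectra are brought onto the donor-excitation grid (restricted to
#' their overlap) and the donor-excitation spectrum is divided by the peak
#' intensity of the acceptor-excitation spectrum. This makes the direct
#' acceptor excitation contribution directly comparable between a sample and
#' an acceptor-only control, since direct excitation scales with acceptor
#' abundance, which the acceptor-excitation spectrum measures.
#'
#' @param cell a [CellSpectra-class].
#' @return The aligned and normalized [CellSpectra-class].
#' @export
alignAndNormalize <- function(cell) {
    dn <- cell@donorExc
    ax <- cell@acceptorExc
    lo <- max(min(dn@wavelengths), min(ax@wavelengths))
    hi <- min(max(dn@wavelengths), max(ax@wavelengths))
    if (lo >= hi) stop("cell spectra do not overlap in wavelength")
    grid <- dn@wavelengths[dn@wavelengths >= lo & dn@wavelengths <= hi]
    dn <- resampleSpectrumOnto(dn, grid)
    ax <- resampleSpectrumOnto(ax, grid)
    peak <- max(ax@values)
    if (peak <= 0)
        stop("normalization error: acceptor-excitation spectrum peak is zero")
    dn@values <- dn@values / peak
    out <- cell
    out@donorExc <- dn
    out@acceptorExc <- ax
    out@normalized <- TRUE
    out
}

#' Remove the direct acceptor excitation contribution
#'
#' Subtracts the direct-excitation spectrum (the acceptor-only control under
#' donor excitation, normalized identically to the sample) from the
#' normalized donor-excitation spectrum. Negative residuals are permitted
#' (noise) but a warning is raised if they are systematic.
#'
#' @param cell a normalized [CellSpectra-class] (see [alignAndNormalize()]).
#' @param refs a [ReferenceSet-class] whose `directShape` is present.
#' @return The corrected donor-excitation [Spectrum-class] (may contain
#'   negative noise residuals).
#' @export
subtractDirectExcitation <- function(cell, refs) {
    if (is.null(refs@directShape))
        stop("configuration error: no acceptor-only control (directShape) ",
             "in the reference set")
    if (!cell@normalized)
        cell <- alignAndNormalize(cell)
    dn <- cell@donorExc
    direct <- resampleSpectrumOnto(refs@directShape, dn@wavelengths)
    v <- dn@values - direct@values
    neg <- sum(pmin(v, 0))
    if (neg < -0.02 * sum(abs(v)))
        warning("systematic negative residuals after direct-excitation ",
                "subtraction; check the acceptor-only control")
    new("Spectrum", wavelengths = dn@wavelengths, values = v,
        kind = "emission", normalization = "raw")
}

.fitRangeForClass <- function(acceptorClass) {
    switch(acceptorClass,
        green_yellow = c(450, 650),
        orange_red_with_green = c(450, 525),
        red_no_green = c(450, 500))
}

#' Unmix a corrected cell spectrum into its components
#'
#' Strategy depends on the acceptor class. Green/yellow acceptors: joint
#' non-negative linear regression of donor and acceptor reference shapes over
#' 450-650 nm; the two fitted components are the donor emission F_D and the
#' sensitized emission F_S. Orange/red acceptors with a green contaminant:
#' donor and green shapes are regressed over 450-525 nm (where the acceptor
#' does not emit) and F_S is the remainder. Red acceptors without a green
#' component: donor-only regression over 450-500 nm, F_S the remainder.
#' Coefficients are constrained non-negative (components are photon counts).
#' All outputs are normalized to the peak of the unmixed donor component.
#'
#' @param corrected the direct-excitation-corrected [Spectrum-class].
#' @param refs a [ReferenceSet-class].
#' @param acceptorClass see [CellSpectra()]; defaults per-class fit range.
#' @param fitRangeNm optional length-2 override of the regression window, nm.
#' @param directComponent optional [Spectrum-class]: the subtracted direct
#'   excitation, stored in the result for bookkeeping.
#' @return An [UnmixResult-class].
#' @export
unmixSpectrum <- function(corrected, refs,
                          acceptorClass = c("green_yellow",
                                            "orange_red_with_green",
                                            "red_no_green"),
                          fitRangeNm = NULL, directComponent = NULL) {
    acceptorClass <- match.arg(acceptorClass)
    if (is.null(fitRangeNm)) fitRangeNm <- .fitRangeForClass(acceptorClass)
    grid <- corrected@wavelengths
    fD <- resampleSpectrumOnto(refs@donorRef, grid)@values
    fA <- resampleSpectrumOnto(refs@acceptorRef, grid)@values
    inFit <- grid >= fitRangeNm[1] & grid <= fitRangeNm[2]
    if (sum(inFit) < 3L)
        stop("fit range contains too few wavelength samples")

    design <- switch(acceptorClass,
        green_yellow = cbind(donor = fD, sensitized = fA),
        orange_red_with_green = {
            if (is.null(refs@greenRef))
                stop("configuration error: no green reference for class ",
                     "orange_red_with_green")
            cbind(donor = fD,
                  green = resampleSpectrumOnto(refs@greenRef, grid)@values)
        },
        red_no_green = cbind(donor = fD))

    A <- design[inFit, , drop = FALSE]
    if (ncol(A) > 1L) {
        qrA <- qr(A)
        if (qrA$rank < ncol(A) ||
            kappa(crossprod(A), exact = TRUE) > 1e12)
            stop("conditioning error: reference spectra are collinear on ",
                 "the fit range")
    } else if (all(A == 0)) {
        stop("conditioning error: donor reference vanishes on the fit range")
    }
    y <- corrected@values[inFit]
    beta <- pracma::lsqnonneg(A, y)$x
    names(beta) <- colnames(design)

    FDv <- beta[["donor"]] * fD
    FGv <- if ("green" %in% names(beta))
        beta[["green"]] * resampleSpectrumOnto(refs@greenRef, grid)@values
    else
        numeric(length(grid))
    FSv <- if (acceptorClass == "green_yellow")
        beta[["sensitized"]] * fA
    else
        corrected@values - FDv - FGv
    # regression residual on the fit range (for the remainder classes F_S
    # absorbs it outside the regression, so this is the informative number)
    residualNorm <- sqrt(sum((y - A %*% beta)^2))

    # paper-style presentation scale: everything relative to the donor peak
    scale <- max(FDv)
    if (scale > 0) {
        FDv <- FDv / scale
        FSv <- FSv / scale
        FGv <- FGv / scale
    }
    mkSpec <- function(v) new("Spectrum", wavelengths = grid, values = v,
                              kind = "emission", normalization = "raw")
    FAspec <- if (is.null(directComponent))
        mkSpec(numeric(length(grid))) else
        resampleSpectrumOnto(directComponent, grid)
    new("UnmixResult", FD = mkSpec(FDv), FS = mkSpec(FSv), FG = mkSpec(FGv),
        FA = FAspec, coefficients = beta, residualNorm = residualNorm,
        fitRangeNm = as.numeric(fitRangeNm), acceptorClass = acceptorClass)
}

setMethod("show", "UnmixResult", function(object) {
    cat(sprintf(
        "UnmixResult (%s): coefficients [%s], residual norm %.3g, fit range %g-%g nm\n",
        object@acceptorClass,
        paste(sprintf("%s = %.4g", names(object@coefficients),
                      object@coefficients), collapse = ", "),
        object@residualNorm, object@fitRangeNm[1], object@fitRangeNm[2]))
})

#' @describeIn unmixSpectrum unmixed donor component accessor.
#' @param x an `UnmixResult`.
#' @export
donorComponent <- function(x) x@FD

#' @describeIn unmixSpectrum sensitized-emission component accessor.
#' @export
sensitizedComponent <- function(x) x@FS

#' Apparent FRET efficiency from unmixed components
#'
#' Wavelength-resolved estimator
#' E_D(lambda) = 1 - F_D / ((Q_D f_D / (Q_A f_A)) F_S + F_D):
#' the numerator is the quenched donor emission and the denominator
#' reconstructs the total donor emission from the sensitized emission via the
#' quantum-yield ratio and the reference shapes. For any mixture of the
#' reference shapes E_D(lambda) is constant in lambda; spectrum edges deviate
#' in real data, so a weighted average with weights
#' w(lambda) = f_D(lambda) f_A(lambda) is taken over a flat region.
#'
#' The default region keeps wavelengths where both reference shapes exceed 1
#' percent of their maxima, intersected with the 450-650 nm acquisition
#' window. Wavelengths where f_A falls below `faFloor` times its peak are
#' always excluded (the quantum-yield ratio would blow up).
#'
#' @param result an [UnmixResult-class].
#' @param refs the [ReferenceSet-class] used for unmixing.
#' @param flatRegionNm optional length-2 wavelength window overriding the
#'   default flat region.
#' @param faFloor exclusion floor on f_A relative to its peak.
#' @return list with `E` (weighted-average efficiency, fraction),
#'   `wavelengths`, `ED_lambda`, `weights` on the evaluation region.
#' @export
apparentEfficiency <- function(result, refs, flatRegionNm = NULL,
                               faFloor = 1e-6) {
    grid <- result@FD@wavelengths
    fD <- resampleSpectrumOnto(refs@donorRef, grid)@values
    fA <- resampleSpectrumOnto(refs@acceptorRef, grid)@values
    FDv <- result@FD@values
    FSv <- result@FS@values

    keep <- fA > faFloor * max(fA)
    if (is.null(flatRegionNm)) {
        keep <- keep & fD > 0.01 * max(fD) & fA > 0.01 * max(fA) &
            grid >= 450 & grid <= 650
    } else {
        keep <- keep & grid >= flatRegionNm[1] & grid <= flatRegionNm[2]
    }
    if (!any(keep))
        stop("region error: empty flat region after f_A floor filtering")

    denom <- (refs@qD * fD[keep]) / (refs@qA * fA[keep]) * FSv[keep] +
        FDv[keep]
    ed <- 1 - FDv[keep] / denom
    ed[denom == 0] <- NA_real_
    w <- fD[keep] * fA[keep]
    ok <- is.finite(ed)
    if (!any(ok))
        stop("region error: no finite efficiency values on the flat region")
    list(E = sum(w[ok] * ed[ok]) / sum(w[ok]),
         wavelengths = grid[keep][ok], ED_lambda = ed[ok], weights = w[ok])
}

#' Full spectral FRET analysis of one cell
#'
#' Convenience chain: [alignAndNormalize()], [subtractDirectExcitation()],
#' [unmixSpectrum()], [apparentEfficiency()].
#'
#' @param cell a [CellSpectra-class].
#' @param refs a [ReferenceSet-class].
#' @param ... passed to [apparentEfficiency()].
#' @return list with `E`, `unmix` (the [UnmixResult-class]) and the
#'   wavelength-resolved efficiency fields of [apparentEfficiency()].
#' @export
spectralFretEfficiency <- function(cell, refs, ...) {
    cell <- alignAndNormalize(cell)
    corrected <- subtractDirectExcitation(cell, refs)
    direct <- resampleSpectrumOnto(refs@directShape,
                                   corrected@wavelengths)
    um <- unmixSpectrum(corrected, refs, cell@acceptorClass,
                        directComponent = direct)
    ae <- apparentEfficiency(um, refs, ...)
    c(ae, list(unmix = um))
}
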