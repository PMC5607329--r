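#' Write a phase stack as a multi-page TIFF with a YAML sidecar
#'
#' Frames are written as 32-bit float TIFF pages; the phase steps,
#' modulation frequency and acquisition order go into `<path>.yaml`.
#'
#' @param stack a [PhaseStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writePhaseStack <- function(stack, path) {
    d <- dim(stack@frames)
    pages <- lapply(seq_len(d[3]), function(k) stack@frames[, , k])
    scale <- max(stack@frames)
    if (scale <= 0) scale <- 1
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L)
    yaml::write_yaml(
        list(phase_steps_rad = as.numeric(stack@phaseStepsRad),
             modulation_frequency_hz = stack@frequencyHz,
             acquisition_order = as.integer(stack@acquisitionOrder),
             intensity_scale = scale),
        paste0(path, ".yaml"))
    invisible(path)
}

#' Read a phase stack written by [writePhaseStack()]
#'
#' @param path TIFF path; `<path>.yaml` must exist alongside.
#' @return A [PhaseStack-class].
#' @export
readPhaseStack <- function(path) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
        stop("missing sidecar metadata file: ", sidecar)
    meta <- yaml::read_yaml(sidecar)
    pages <- tiff::readTIFF(path, all = TRUE)
    scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
    frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * scale
    PhaseStack(frames, meta$phase_steps_rad, meta$modulation_frequency_hz,
               as.integer(meta$acquisition_order))
}
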