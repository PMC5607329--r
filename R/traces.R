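#' Construct a two-channel intensity trace
#'
#' @param timeS strictly increasing timestamps, s.
#' @param donor,acceptor per-timepoint channel intensities.
#' @param backgroundDonor,backgroundAcceptor scalar or per-timepoint
#'   background levels.
#' @param events named numeric vector of event times, e.g.
#'   `c(agonist = 44, antagonist = 150)`.
#' @return An [IntensityTrace-class].
#' @export
IntensityTrace <- function(timeS, donor, acceptor,
                           backgroundDonor = 0, backgroundAcceptor = 0,
                           events = numeric()) {
    new("IntensityTrace", timeS = as.numeric(timeS),
        donor = as.numeric(donor), acceptor = as.numeric(acceptor),
        backgroundDonor = as.numeric(backgroundDonor),
        backgroundAcceptor = as.numeric(backgroundAcceptor),
        events = events, normalized = FALSE)
}

setMethod("show", "IntensityTrace", function(object) {
    cat(sprintf(
        "IntensityTrace: %d frames, %.0f-%.0f s%s%s\n",
        length(object@timeS), min(object@timeS), max(object@timeS),
        if (object@normalized) ", normalized" else "",
        if (length(object@events))
            paste0(", events: ", paste(sprintf("%s@%gs", names(object@events),
                                               object@events),
                                       collapse = ", "))
        else ""))
})

#' @describeIn IntensityTrace number of frames.
#' @param x an `IntensityTrace`.
#' @export
setMethod("length", "IntensityTrace", function(x) length(x@timeS))

#' @describeIn IntensityTrace data.frame view (time_s, donor, acceptor).
#' @export
traceFrame <- function(x) {
    data.frame(time_s = x@timeS, donor = x@donor, acceptor = x@acceptor)
}

#' Background-subtract and baseline-normalize a trace
#'
#' Per channel: subtract the background, then divide by the mean of the first
#' `nBaselineFrames` frames so the baseline maps to 1. The operation is
#' idempotent for a fixed `nBaselineFrames`.
#'
#' @param trace an [IntensityTrace-class].
#' @param nBaselineFrames number of initial frames defining the baseline
#'   (1 for photobleaching curves, 5 for ratiometric biosensor recordings).
#' @return The normalized [IntensityTrace-class] (backgrounds reset to 0).
#' @export
normalizeTrace <- function(trace, nBaselineFrames = 1) {
    n <- length(trace@timeS)
    if (nBaselineFrames < 1 || nBaselineFrames > n)
        stop("nBaselineFrames must lie in [1, length(trace)]")
    d <- trace@donor - trace@backgroundDonor
    a <- trace@acceptor - trace@backgroundAcceptor
    bd <- mean(d[seq_len(nBaselineFrames)])
    ba <- mean(a[seq_len(nBaselineFrames)])
    if (bd <= 0 || ba <= 0)
        stop("normalization error: non-positive baseline after background ",
             "subtraction")
    out <- trace
    out@donor <- d / bd
    out@acceptor <- a / ba
    out@backgroundDonor <- 0
    out@backgroundAcceptor <- 0
    out@normalized <- TRUE
    out
}

#' Percent of initial intensity remaining at a probe time
#'
#' The value at the nearest acquired frame at or before `tProbeS`, as a
#' percentage of the normalized initial intensity (no interpolation:
#' acquisition is frame-based).
#'
#' @param trace an [IntensityTrace-class]; normalized with
#'   `nBaselineFrames = 1` internally if not already normalized.
#' @param channel `"donor"` or `"acceptor"`.
#' @param tProbeS probe time(s), s, within the trace span.
#' @return Percentages (100 at t = 0; donor dequenching during acceptor
#'   bleaching yields values above 100).
#' @export
percentRemaining <- function(trace, channel = c("donor", "acceptor"),
                             tProbeS) {
    channel <- match.arg(channel)
    if (!trace@normalized) trace <- normalizeTrace(trace, 1)
    v <- slot(trace, channel)
    vapply(tProbeS, function(t) {
        if (t < trace@timeS[1] || t > trace@timeS[length(trace@timeS)])
            stop("range error: probe time outside the trace span")
        100 * v[max(which(trace@timeS <= t))]
    }, numeric(1))
}

#' Bleach summary at standard probe times
#'
#' @param trace an [IntensityTrace-class].
#' @param tProbeS probe times, s (default 48 s, a typical FRET time-lapse
#'   exposure total, and 900 s of continuous illumination).
#' @return data.frame with per-channel percent remaining at each probe time.
#' @export
bleachSummary <- function(trace, tProbeS = c(48, 900)) {
    data.frame(
        t_probe_s = tProbeS,
        donor_pct = percentRemaining(trace, "donor", tProbeS),
        acceptor_pct = percentRemaining(trace, "acceptor", tProbeS))
}

#' Ratiometric biosensor response analysis
#'
#' Computes the FRET ratio per frame, the baseline from pre-agonist frames,
#' the response amplitude as the maximal relative ratio deviation between
#' agonist and antagonist, and the recovery as the fraction of that deviation
#' reversed at the post-antagonist plateau (mean of the final
#' `plateauFrames` frames). A cell is a responder when the amplitude reaches
#' `responderThresholdPct`.
#'
#' @param trace an [IntensityTrace-class] with `agonist` and `antagonist`
#'   events; normalized with `nBaselineFrames = 5` internally if needed.
#' @param responderThresholdPct responder threshold on the amplitude, percent.
#' @param ratio `"acceptor_donor"` (default) or `"donor_acceptor"`.
#' @param plateauFrames frames at the trace end defining the recovery plateau.
#' @return A [RatioResponse-class].
#' @export
ratioResponse <- function(trace, responderThresholdPct = 5,
                          ratio = c("acceptor_donor", "donor_acceptor"),
                          plateauFrames = 5) {
    ratio <- match.arg(ratio)
    ev <- trace@events
    if (!all(c("agonist", "antagonist") %in% names(ev)))
        stop("event error: trace must carry 'agonist' and 'antagonist' events")
    tAg <- ev[["agonist"]]
    tAnt <- ev[["antagonist"]]
    tt <- trace@timeS
    if (tAg >= tAnt || tAg <= tt[1] || tAnt >= tt[length(tt)])
        stop("event error: events must be ordered and inside the trace span")
    if (!trace@normalized) trace <- normalizeTrace(trace, 5)
    r <- if (ratio == "acceptor_donor") trace@acceptor / trace@donor
         else trace@donor / trace@acceptor
    baseline <- mean(r[tt < tAg])
    if (!is.finite(baseline) || baseline <= 0)
        stop("event error: no usable pre-agonist baseline")
    during <- tt >= tAg & tt <= tAnt
    dev <- abs(r[during] - baseline) / baseline * 100
    amplitude <- max(dev)
    peakDev <- (r[during])[which.max(dev)] - baseline
    post <- r[seq(max(1, length(r) - plateauFrames + 1), length(r))]
    recovery <- if (amplitude == 0) NA_real_ else
        (1 - abs(mean(post) - baseline) / abs(peakDev)) * 100
    new("RatioResponse", timeS = tt, ratio = r, baseline = baseline,
        amplitudePct = amplitude, recoveryPct = recovery,
        responder = amplitude >= responderThresholdPct,
        thresholdPct = responderThresholdPct)
}

setMethod("show", "RatioResponse", function(object) {
    cat(sprintf(
        "RatioResponse: baseline %.3f, amplitude %.1f%%, recovery %s, %s (threshold %.1f%%)\n",
        object@baseline, object@amplitudePct,
        if (is.na(object@recoveryPct)) "NA" else
            sprintf("%.1f%%", object@recoveryPct),
        if (object@responder) "responder" else "non-responder",
        object@thresholdPct))
})

#' Re-index traces so the agonist event is time zero
#'
#' For cohort averaging, traces whose drugs were added at slightly different
#' times are shifted so the agonist addition sits at t = 0 and interpolated
#' onto a common grid.
#'
#' @param traces list of [IntensityTrace-class]s with an `agonist` event.
#' @param dtS grid spacing, s (default: median frame interval).
#' @return list of shifted, grid-aligned [IntensityTrace-class]s.
#' @export
alignTracesToAgonist <- function(traces, dtS = NULL) {
    shifted <- lapply(traces, function(tr) {
        if (!"agonist" %in% names(tr@events))
            stop("event error: trace lacks an 'agonist' event")
        tr@timeS <- tr@timeS - tr@events[["agonist"]]
        tr@events <- tr@events - tr@events[["agonist"]]
        tr
    })
    if (is.null(dtS))
        dtS <- stats::median(unlist(lapply(shifted,
                                           function(tr) diff(tr@timeS))))
    lo <- max(vapply(shifted, function(tr) min(tr@timeS), 0))
    hi <- min(vapply(shifted, function(tr) max(tr@timeS), 0))
    grid <- seq(lo, hi, by = dtS)
    lapply(shifted, function(tr) {
        IntensityTrace(grid,
            stats::approx(tr@timeS, tr@donor, grid)$y,
            stats::approx(tr@timeS, tr@acceptor, grid)$y,
            events = tr@events)
    })
}

#' Cohort mean and 95 percent confidence band of aligned traces
#'
#' @param traces list of grid-aligned [IntensityTrace-class]s (see
#'   [alignTracesToAgonist()]).
#' @param channel `"donor"`, `"acceptor"` or `"ratio"` (acceptor/donor).
#' @param confLevel confidence level (normal approximation).
#' @return data.frame with `time_s`, `mean`, `lower`, `upper`, `n`.
#' @export
cohortSummary <- function(traces, channel = c("donor", "acceptor", "ratio"),
                          confLevel = 0.95) {
    channel <- match.arg(channel)
    vals <- vapply(traces, function(tr) {
        switch(channel, donor = tr@donor, acceptor = tr@acceptor,
               ratio = tr@acceptor / tr@donor)
    }, numeric(length(traces[[1]]@timeS)))
    z <- stats::qnorm(1 - (1 - confLevel) / 2)
    m <- rowMeans(vals)
    se <- apply(vals, 1, stats::sd) / sqrt(ncol(vals))
    data.frame(time_s = traces[[1]]@timeS, mean = m,
               lower = m - z * se, upper = m + z * se, n = ncol(vals))
}

#' Relative brightness against a co-expressed reference
#'
#' Per cell, the background-subtracted mean intensity of the protein of
#' interest divided by that of a quantitatively co-expressed reference; the
#' cohort is summarized as mean with a normal-approximation confidence
#' interval.
#'
#' @param sampleIntensity,referenceIntensity per-cell background-subtracted
#'   mean intensities (equal length).
#' @param confLevel confidence level.
#' @return list with `ratios`, `mean`, `ci` (length 2), `n`.
#' @export
relativeBrightness <- function(sampleIntensity, referenceIntensity,
                               confLevel = 0.95) {
    if (length(sampleIntensity) != length(referenceIntensity))
        stop("sample and reference must have equal length")
    if (any(referenceIntensity <= 0))
        stop("non-positive reference intensity")
    ratios <- sampleIntensity / referenceIntensity
    n <- length(ratios)
    z <- stats::qnorm(1 - (1 - confLevel) / 2)
    se <- if (n > 1) stats::sd(ratios) / sqrt(n) else NA_real_
    list(ratios = ratios, mean = mean(ratios),
         ci = mean(ratios) + c(-1, 1) * z * se, n = n)
}

#' Read a two-channel trace from CSV
#'
#' Expects columns `time_s`, `donor`, `acceptor`.
#'
#' @param path CSV file path.
#' @param backgroundDonor,backgroundAcceptor background levels.
#' @param events named numeric vector of event times.
#' @return An [IntensityTrace-class].
#' @export
readTrace <- function(path, backgroundDonor = 0, backgroundAcceptor = 0,
                      events = numeric()) {
    df <- utils::read.csv(path)
    need <- c("time_s", "donor", "acceptor")
    if (!all(need %in% names(df)))
        stop("trace CSV must have columns: ", paste(need, collapse = ", "))
    IntensityTrace(df$time_s, df$donor, df$acceptor,
                   backgroundDonor, backgroundAcceptor, events)
}

#' Write a two-channel trace to CSV
#'
#' @param trace an [IntensityTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
    utils::write.csv(traceFrame(trace), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
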