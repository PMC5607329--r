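test_that("the harmonic fit recovers DC, AC and phase exactly for uniform steps", {
  theta <- 2 * pi * (0:11) / 12
  frames <- array(homodyneFrames(100, 50, 0.5, theta), c(1, 1, 12))
  st <- PhaseStack(frames, theta, 75.1e6)
  est <- fitPhasor(st)
  expect_equal(as.numeric(est@dc), 100, tolerance = 1e-12)
  expect_equal(as.numeric(est@ac), 50, tolerance = 1e-12)
  expect_equal(as.numeric(est@phaseRad), 0.5, tolerance = 1e-12)
  # equals the first-harmonic discrete Fourier coefficients
  y <- homodyneFrames(100, 50, 0.5, theta)
  g <- 2 * mean(y * cos(theta))
  s <- 2 * mean(y * sin(theta))
  expect_equal(as.numeric(est@ac), sqrt(g^2 + s^2), tolerance = 1e-12)
  expect_equal(as.numeric(est@phaseRad), atan2(s, g), tolerance = 1e-12)
})

test_that("constant frames are flagged undefined rather than propagating NaN", {
  theta <- 2 * pi * (0:7) / 8
  st <- PhaseStack(array(100, c(2, 2, 8)), theta, 75.1e6)
  est <- fitPhasor(st)
  expect_true(all(est@undefined))
  expect_true(all(is.na(est@phaseRad)))
  expect_true(all(is.finite(est@dc)))
})

test_that("the estimate is invariant to the acquisition order of the frames", {
  theta <- 2 * pi * (0:11) / 12
  y <- homodyneFrames(200, 80, 1.1, theta)
  set.seed(42)
  perm <- sample(12)
  stOrdered <- PhaseStack(array(y, c(1, 1, 12)), theta, 75.1e6)
  stShuffled <- PhaseStack(array(y[perm], c(1, 1, 12)), theta[perm], 75.1e6,
                           acquisitionOrder = perm)
  e1 <- fitPhasor(stOrdered)
  e2 <- fitPhasor(stShuffled)
  expect_equal(as.numeric(e1@phaseRad), as.numeric(e2@phaseRad),
               tolerance = 1e-12)
  expect_equal(as.numeric(e1@modulation), as.numeric(e2@modulation),
               tolerance = 1e-12)
})

test_that("a zero-lifetime reflection reference measures the instrument phase", {
  ref <- calibrationReference(scalarPhasor(100, 0.7, 0.9), 0, 0)
  sample <- scalarPhasor(50, 1.0, 0.45)
  cal <- calibratePhasor(sample, ref, 75.1e6)
  # phi_true = 0, M_true = 1: offset is the measured reference phase itself
  expect_equal(as.numeric(cal@phaseRad), 1.0 - 0.7, tolerance = 1e-12)
  expect_equal(as.numeric(cal@modulation), 0.45 / 0.9, tolerance = 1e-12)
})

test_that("calibration inverts a synthetic instrument distortion", {
  f <- 75.1e6
  truePhasor <- function(tau) {
    wt <- 2 * pi * f * tau * 1e-9
    list(phase = atan(wt), mod = 1 / sqrt(1 + wt^2))
  }
  s <- truePhasor(2.5)
  r <- truePhasor(3.8)
  distort <- function(p) scalarPhasor(100, p$phase + 0.3, p$mod * 0.8)
  ref <- calibrationReference(distort(r), 3.8, 3.8)
  cal <- calibratePhasor(distort(s), ref, f)
  expect_equal(as.numeric(cal@phaseRad), s$phase, tolerance = 1e-9)
  expect_equal(as.numeric(cal@modulation), s$mod, tolerance = 1e-9)
  # calibrating the reference against itself returns its known phasor
  self <- calibratePhasor(distort(r), ref, f)
  expect_equal(as.numeric(self@phaseRad), r$phase, tolerance = 1e-12)
  expect_equal(as.numeric(self@modulation), r$mod, tolerance = 1e-12)
})

test_that("zero reference modulation is a calibration error", {
  ref <- calibrationReference(scalarPhasor(100, 0.5, 0), 3.8, 4.0)
  expect_error(calibratePhasor(scalarPhasor(10, 0.3, 0.5), ref, 75.1e6),
               "calibration error")
})

test_that("lifetimes at the omega*tau = 1 fixed point equal 1/omega", {
  for (f in c(40e6, 75.1e6)) {
    p <- scalarPhasor(1, atan(1), 1 / sqrt(2))
    lt <- lifetimesFromPhasor(p, f)
    expect_equal(tauPhase(lt), 1e9 / (2 * pi * f), tolerance = 1e-9)
    expect_equal(tauMod(lt), 1e9 / (2 * pi * f), tolerance = 1e-9)
  }
})

test_that("unphysical calibrated phasors are rejected", {
  expect_error(lifetimesFromPhasor(scalarPhasor(1, 0.3, 1.2), 75.1e6),
               "unphysical modulation")
  expect_error(lifetimesFromPhasor(scalarPhasor(1, 1.7, 0.5), 75.1e6),
               "unphysical phase")
})

test_that("noiseless synthetic stacks recover mono-exponential lifetimes", {
  for (f in c(75.1e6, 40e6)) {
    for (tau in c(0.5, 1.8, 3.8, 6)) {
      g <- genPhaseStack(tau, frequencyHz = f, dimPx = c(2, 2),
                         instrumentPhaseRad = 0.25,
                         instrumentModFactor = 0.85)
      ref <- calibrationReference(fitPhasor(g$reference), g$referenceTauNs)
      cal <- calibratePhasor(averagePhasor(fitPhasor(g$sample)), ref, f)
      lt <- lifetimesFromPhasor(cal, f)
      expect_equal(tauPhase(lt), tau, tolerance = 1e-9)
      expect_equal(tauMod(lt), tau, tolerance = 1e-9)
    }
  }
})

test_that("a lifetime mixture pulls the phase lifetime below the modulation lifetime", {
  f <- 75.1e6
  # brute-force phasor addition oracle, independent of the package path
  w <- 2 * pi * f
  taus <- c(1e-9, 4e-9)
  g <- mean(1 / (1 + (w * taus)^2))
  s <- mean((w * taus) / (1 + (w * taus)^2))
  oraclePhi <- atan2(s, g)
  oracleMod <- sqrt(g^2 + s^2)
  oracleTphi <- tan(oraclePhi) / w * 1e9
  oracleTmod <- sqrt(1 / oracleMod^2 - 1) / w * 1e9

  gen <- genPhaseStack(c(1, 4), weights = c(0.5, 0.5), frequencyHz = f,
                       dimPx = c(2, 2))
  ref <- calibrationReference(fitPhasor(gen$reference), gen$referenceTauNs)
  cal <- calibratePhasor(averagePhasor(fitPhasor(gen$sample)), ref, f)
  lt <- lifetimesFromPhasor(cal, f)
  expect_equal(tauPhase(lt), oracleTphi, tolerance = 1e-9)
  expect_equal(tauMod(lt), oracleTmod, tolerance = 1e-9)
  expect_lt(tauPhase(lt), tauMod(lt))
})

test_that("donor quenching converts to the published efficiencies", {
  expect_equal(round(fretEfficiencyFromLifetime(2.02, 3.77)), 46)
  expect_equal(round(fretEfficiencyFromLifetime(2.83, 3.77)), 25)
  expect_equal(fretEfficiencyFromLifetime(3.77, 3.77), 0)
  expect_warning(fretEfficiencyFromLifetime(4.2, 3.77), "dequenching")
})

test_that("ROI time courses recover a stepped lifetime series", {
  f <- 75.1e6
  taus <- c(2.6, 2.8, 2.6)
  stacks <- lapply(taus, function(tau)
    genPhaseStack(tau, frequencyHz = f, dimPx = c(6, 6),
                  instrumentPhaseRad = 0.1,
                  instrumentModFactor = 0.9)$sample)
  refStack <- genPhaseStack(3.8, frequencyHz = f, dimPx = c(6, 6),
                            instrumentPhaseRad = 0.1,
                            instrumentModFactor = 0.9)$sample
  ref <- calibrationReference(refStack, 3.8)
  roi <- matrix(TRUE, 6, 6)
  tc <- roiLifetimeTimecourse(stacks, ref, roi)
  expect_equal(tc$tau_phase_ns, taus, tolerance = 1e-9)
  expect_equal(tc$delta_tau_phase_ns, c(0, 0.2, 0), tolerance = 1e-9)
})

test_that("3x3 smoothing leaves a spatially uniform stack unchanged", {
  f <- 75.1e6
  g <- genPhaseStack(3.0, frequencyHz = f, dimPx = c(8, 8))
  ref <- calibrationReference(fitPhasor(g$reference), g$referenceTauNs)
  roi <- matrix(TRUE, 8, 8)
  a <- roiLifetimeTimecourse(list(g$sample), ref, roi, smoothing = "none")
  b <- roiLifetimeTimecourse(list(g$sample), ref, roi, smoothing = "box3")
  expect_equal(a$tau_phase_ns, b$tau_phase_ns, tolerance = 1e-12)
})

test_that("background subtraction removes an additive offset", {
  f <- 75.1e6
  g <- genPhaseStack(2.5, frequencyHz = f, dimPx = c(8, 8))
  ref <- calibrationReference(fitPhasor(g$reference), g$referenceTauNs)
  st <- g$sample
  # signal confined to the top rows plus a constant background everywhere
  st@frames[5:8, , ] <- 0
  st@frames <- st@frames + 500
  roi <- matrix(FALSE, 8, 8); roi[1:4, ] <- TRUE
  bg <- matrix(FALSE, 8, 8); bg[5:8, ] <- TRUE
  biased <- roiLifetimeTimecourse(list(st), ref, roi)
  corrected <- roiLifetimeTimecourse(list(st), ref, roi,
                                     backgroundMask = bg)
  expect_equal(corrected$tau_phase_ns, 2.5, tolerance = 1e-9)
  expect_equal(corrected$tau_mod_ns, 2.5, tolerance = 1e-9)
  # an additive offset inflates DC, so the uncorrected modulation lifetime
  # is biased (the phase lifetime is immune to a constant background)
  expect_gt(abs(biased$tau_mod_ns - 2.5), 1e-3)
})

test_that("an empty or all-background ROI is handled explicitly", {
  f <- 75.1e6
  g <- genPhaseStack(2.5, frequencyHz = f, dimPx = c(4, 4))
  ref <- calibrationReference(fitPhasor(g$reference), g$referenceTauNs)
  expect_error(roiLifetimeTimecourse(list(g$sample), ref,
                                     matrix(FALSE, 4, 4)), "empty ROI")
  # constant (zero-contrast) frames inside the ROI: flagged, not an error
  flat <- PhaseStack(array(100, c(4, 4, 12)), g$sample@phaseStepsRad, f)
  tc <- roiLifetimeTimecourse(list(flat), ref, matrix(TRUE, 4, 4))
  expect_true(is.na(tc$tau_phase_ns))
})
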