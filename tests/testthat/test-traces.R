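test_that("background subtraction and baseline normalization behave as defined", {
  tr <- IntensityTrace(0:9, rep(7, 10), rep(9, 10),
                       backgroundDonor = 2, backgroundAcceptor = 4)
  n <- normalizeTrace(tr, 1)
  expect_equal(n@donor, rep(1, 10))
  expect_equal(n@acceptor, rep(1, 10))

  ramp <- IntensityTrace(0:9, 1:10, 10:1)
  n5 <- normalizeTrace(ramp, 5)
  expect_equal(mean(n5@donor[1:5]), 1)
  expect_equal(mean(n5@acceptor[1:5]), 1)

  # hand-computed spreadsheet check
  tr2 <- IntensityTrace(c(0, 4, 8), c(110, 60, 35), c(210, 110, 60),
                        backgroundDonor = 10, backgroundAcceptor = 10)
  n2 <- normalizeTrace(tr2, 1)
  expect_equal(n2@donor, c(1, 0.5, 0.25))
  expect_equal(n2@acceptor, c(1, 0.5, 0.25))

  expect_error(normalizeTrace(tr, 0), "nBaselineFrames")
  expect_error(normalizeTrace(
    IntensityTrace(0:2, c(1, 2, 3), c(5, 5, 5), backgroundDonor = 2), 1),
    "normalization error")
})

test_that("normalization is idempotent", {
  tr <- IntensityTrace(0:9, 100 * exp(-0.1 * (0:9)) + 3,
                       50 * exp(-0.05 * (0:9)) + 1,
                       backgroundDonor = 3, backgroundAcceptor = 1)
  once <- normalizeTrace(tr, 5)
  twice <- normalizeTrace(once, 5)
  expect_equal(twice@donor, once@donor, tolerance = 1e-12)
  expect_equal(twice@acceptor, once@acceptor, tolerance = 1e-12)
})

test_that("percent remaining reads the nearest preceding frame", {
  tr <- IntensityTrace(seq(0, 900, 4), rep(5, 226), rep(5, 226))
  expect_equal(percentRemaining(tr, "donor", c(0, 48, 900)),
               c(100, 100, 100))

  halfTime <- 450
  t <- seq(0, 900, 4)
  decay <- IntensityTrace(t, exp(-log(2) / halfTime * t),
                          exp(-log(2) / halfTime * t))
  expect_equal(percentRemaining(decay, "acceptor", 900), 25, tolerance = 1e-9)
  expect_error(percentRemaining(decay, "donor", -4), "range error")
  expect_error(percentRemaining(decay, "donor", 1200), "range error")
})

test_that("acceptor bleaching dequenches the donor above its initial level", {
  g <- genBleachTrace(E0 = 0.4, acceptorBleach = log(2) / 450,
                      donorBleachRate = 0)
  don <- percentRemaining(g$trace, "donor", 900)
  expect_gt(don, 100)
  # donor channel rises monotonically while the acceptor decays
  n <- normalizeTrace(g$trace, 1)
  expect_true(all(diff(n@donor) > 0))
  expect_true(all(diff(n@acceptor) < 0))
})

test_that("donor dequenching mirrors acceptor loss quantitatively", {
  for (E0 in c(0.2, 0.46, 0.8)) {
    g <- genBleachTrace(E0 = E0,
                        acceptorBleach = list(rates = c(0.01, 0.001),
                                              fractions = c(0.6, 0.4)),
                        donorBleachRate = 0)
    n <- normalizeTrace(g$trace, 1)
    expected <- (1 - E0 * g$truth$survival) / (1 - E0)
    expect_equal(n@donor, expected, tolerance = 1e-9)
  }
})

test_that("a 450 s half-time acceptor decay leaves 25 percent at 900 s", {
  g <- genBleachTrace(E0 = 0.3, acceptorBleach = log(2) / 450)
  expect_equal(percentRemaining(g$trace, "acceptor", 900), 25,
               tolerance = 1e-9)
  # zero bleach rates: both channels flat at 100 percent
  g0 <- genBleachTrace(E0 = 0.3, acceptorBleach = 0)
  expect_equal(percentRemaining(g0$trace, "donor", 900), 100)
  expect_equal(percentRemaining(g0$trace, "acceptor", 900), 100)
})

test_that("a flat ratio trace is a non-responder with zero amplitude", {
  tr <- IntensityTrace(seq(0, 240, 2), rep(10, 121), rep(7, 121),
                       events = c(agonist = 44, antagonist = 150))
  rr <- ratioResponse(tr)
  expect_equal(rr@amplitudePct, 0)
  expect_false(rr@responder)
})

test_that("a constructed 20 percent step responds and recovers fully", {
  t <- seq(0, 240, 2)
  ratio <- rep(1, length(t))
  ratio[t >= 44 & t < 150] <- 0.8   # 20 percent FRET-ratio drop
  donor <- rep(10, length(t))
  tr <- IntensityTrace(t, donor, ratio * donor,
                       events = c(agonist = 44, antagonist = 150))
  tr@normalized <- TRUE
  rr <- ratioResponse(tr)
  expect_equal(rr@amplitudePct, 20, tolerance = 1e-9)
  expect_equal(rr@recoveryPct, 100, tolerance = 1e-9)
  expect_true(rr@responder)
})

test_that("the responder threshold separates small responses", {
  t <- seq(0, 240, 2)
  ratio <- rep(1, length(t))
  ratio[t >= 44 & t < 150] <- 0.97   # 3 percent step
  tr <- IntensityTrace(t, rep(10, length(t)), ratio * 10,
                       events = c(agonist = 44, antagonist = 150))
  tr@normalized <- TRUE
  expect_false(ratioResponse(tr, responderThresholdPct = 5)@responder)
  expect_true(ratioResponse(tr, responderThresholdPct = 2)@responder)
})

test_that("response amplitude is invariant to overall trace scaling", {
  g <- genGpcrTrace()
  tr2 <- g$trace
  tr2@donor <- tr2@donor * 17
  tr2@acceptor <- tr2@acceptor * 17
  a1 <- ratioResponse(g$trace)@amplitudePct
  a2 <- ratioResponse(tr2)@amplitudePct
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("event annotations are validated", {
  tr <- IntensityTrace(0:10, rep(1, 11), rep(1, 11))
  expect_error(ratioResponse(tr), "event error")
  tr2 <- IntensityTrace(0:10, rep(1, 11), rep(1, 11),
                        events = c(agonist = 8, antagonist = 4))
  expect_error(ratioResponse(tr2), "event error")
})

test_that("GPCR step traces match their closed-form levels", {
  g <- genGpcrTrace(baselineE = 0.30, activatedE = 0.21,
                    transitionTauS = 0.5)
  n <- normalizeTrace(g$trace, 5)
  # donor rise factor (1 - E_act) / (1 - E_base)
  expect_equal(max(n@donor), (1 - 0.21) / (1 - 0.30), tolerance = 1e-3)
  rr <- ratioResponse(g$trace)
  ampExpected <- (1 - (0.21 / 0.79) / (0.30 / 0.70)) * 100
  expect_equal(rr@amplitudePct, ampExpected, tolerance = 0.1)
  expect_equal(rr@recoveryPct, 100, tolerance = 1)
  # equal baseline and activated levels: flat, non-responder
  flat <- genGpcrTrace(baselineE = 0.3, activatedE = 0.3)
  expect_false(ratioResponse(flat$trace)@responder)
})

test_that("traces align to the agonist event and average with confidence bands", {
  traces <- lapply(c(42, 46, 50), function(ag)
    genGpcrTrace(agonistS = ag, antagonistS = ag + 100)$trace)
  aligned <- alignTracesToAgonist(traces)
  expect_true(all(vapply(aligned,
                         function(tr) tr@events[["agonist"]] == 0, TRUE)))
  cs <- cohortSummary(lapply(aligned, normalizeTrace, 5), "ratio")
  expect_equal(nrow(cs), length(aligned[[1]]@timeS))
  expect_true(all(cs$lower <= cs$mean & cs$mean <= cs$upper))
})

test_that("relative brightness is the per-cell intensity ratio", {
  expect_equal(relativeBrightness(30, 60)$mean, 0.5)
  expect_equal(relativeBrightness(c(10, 10), c(10, 10))$mean, 1)
  expect_error(relativeBrightness(10, 0), "non-positive")

  # cohort with lognormal expression noise: CI covers the true ratio
  set.seed(7)
  expr <- rlnorm(100, meanlog = 5, sdlog = 0.5)
  noise <- function() rlnorm(100, 0, 0.05)
  rb <- relativeBrightness(0.8 * expr * noise(), expr * noise())
  expect_true(rb$ci[1] <= 0.8 && 0.8 <= rb$ci[2])
})
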