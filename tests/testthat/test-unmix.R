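# Cell spectra built directly from reference shapes, bypassing the generator,
# so the unmixing tests do not depend on the synth module.
.grid <- seq(450, 650, 1)

.shapes <- function() {
  d <- mtq2Record()
  a <- syfp2Record()
  list(
    fD = normalizeSpectrum(resampleSpectrumOnto(d@emission, .grid), "area"),
    fA = normalizeSpectrum(resampleSpectrumOnto(a@emission, .grid), "area"),
    qD = d@quantumYield, qA = a@quantumYield)
}

test_that("alignment normalizes to the acceptor-excitation peak", {
  sh <- .shapes()
  cell <- CellSpectra(
    Spectrum(.grid, 3 * intensities(sh$fD)),
    Spectrum(.grid, 2 * intensities(sh$fA) / max(intensities(sh$fA))),
    "green_yellow")   # acceptor-excitation spectrum with peak value 2
  out <- alignAndNormalize(cell)
  expect_true(out@normalized)
  expect_equal(wavelengths(out@donorExc), wavelengths(out@acceptorExc))
  expect_equal(intensities(out@donorExc), 3 * intensities(sh$fD) / 2,
               tolerance = 1e-12)
  # already-aligned grids are untouched
  expect_equal(wavelengths(out@donorExc), .grid)
})

test_that("misaligned grids interpolate back to the analytic shape", {
  sh <- .shapes()
  gridOff <- .grid[-length(.grid)] + 0.5
  cell <- CellSpectra(
    Spectrum(.grid, intensities(sh$fD)),
    resampleSpectrumOnto(Spectrum(.grid, intensities(sh$fA)), gridOff),
    "green_yellow")
  out <- alignAndNormalize(cell)
  common <- wavelengths(out@acceptorExc)
  analytic <- resampleSpectrumOnto(sh$fA, common)
  expect_equal(intensities(out@acceptorExc), intensities(analytic),
               tolerance = 5e-3)
})

test_that("zero acceptor-excitation peak is a normalization error", {
  sh <- .shapes()
  cell <- CellSpectra(Spectrum(.grid, intensities(sh$fD)),
                      Spectrum(.grid, numeric(length(.grid))),
                      "green_yellow")
  expect_error(alignAndNormalize(cell), "normalization error")
})

test_that("direct-excitation subtraction removes a constructed contribution", {
  sh <- .shapes()
  direct <- Spectrum(.grid, 0.2 * intensities(sh$fA) /
                       max(intensities(sh$fA)))
  refs <- ReferenceSet(sh$fD, sh$fA, directShape = direct,
                       qD = sh$qD, qA = sh$qA)
  donorOnly <- intensities(sh$fD)
  mixed <- Spectrum(.grid, donorOnly + intensities(direct))
  cell <- CellSpectra(mixed, Spectrum(.grid, intensities(sh$fA)),
                      "green_yellow")
  cell@normalized <- TRUE   # constructed directly on the normalized scale
  out <- subtractDirectExcitation(cell, refs)
  expect_equal(intensities(out), donorOnly, tolerance = 1e-12)

  # spectrum identical to the direct shape vanishes entirely
  cell2 <- cell
  cell2@donorExc <- direct
  expect_equal(intensities(subtractDirectExcitation(cell2, refs)),
               numeric(length(.grid)), tolerance = 1e-12)

  # no control available -> configuration error
  refs0 <- ReferenceSet(sh$fD, sh$fA, qD = sh$qD, qA = sh$qA)
  expect_error(subtractDirectExcitation(cell, refs0), "configuration error")
})

test_that("two-component unmixing recovers exact coefficients", {
  sh <- .shapes()
  refs <- ReferenceSet(sh$fD, sh$fA, qD = sh$qD, qA = sh$qA)
  mixed <- Spectrum(.grid, 0.3 * intensities(sh$fD) +
                      0.7 * intensities(sh$fA))
  um <- unmixSpectrum(mixed, refs, "green_yellow")
  # outputs are rescaled to the donor peak; coefficient ratio is preserved
  expect_equal(unname(um@coefficients["sensitized"] /
                        um@coefficients["donor"]), 0.7 / 0.3,
               tolerance = 1e-9)
  expect_equal(um@residualNorm, 0, tolerance = 1e-9)
  # component shapes proportional to the references
  expect_equal(intensities(um@FS) / intensities(um@FD),
               (0.7 / 0.3) * intensities(sh$fA) / intensities(sh$fD),
               tolerance = 1e-6)
})

test_that("pure donor input yields zero sensitized emission", {
  sh <- .shapes()
  refs <- ReferenceSet(sh$fD, sh$fA, qD = sh$qD, qA = sh$qA)
  um <- unmixSpectrum(Spectrum(.grid, intensities(sh$fD)), refs,
                      "green_yellow")
  expect_equal(max(abs(intensities(um@FS))), 0, tolerance = 1e-9)
})

test_that("donor+green regression recovers a three-component red-cell spectrum", {
  d <- mtq2Record()
  red <- scarletRecord()
  g <- egfpRecord()
  areaShape <- function(spec)
    intensities(normalizeSpectrum(resampleSpectrumOnto(spec, .grid), "area"))
  fD <- areaShape(d@emission)
  fR <- areaShape(red@emission)
  fG <- areaShape(g@emission)
  mixed <- Spectrum(.grid, 0.5 * fD + 0.2 * fG + 0.3 * fR)
  refs <- ReferenceSet(Spectrum(.grid, fD), Spectrum(.grid, fR),
                       greenRef = Spectrum(.grid, fG),
                       qD = d@quantumYield, qA = red@quantumYield)
  um <- unmixSpectrum(mixed, refs, "orange_red_with_green")
  scale <- 0.5 * max(fD)   # outputs normalized to the donor peak
  expect_equal(intensities(um@FD) * scale, 0.5 * fD, tolerance = 1e-9)
  expect_equal(intensities(um@FG) * scale, 0.2 * fG, tolerance = 1e-9)
  expect_equal(intensities(um@FS) * scale, 0.3 * fR, tolerance = 1e-9)
})

test_that("collinear references are a conditioning error", {
  sh <- .shapes()
  refs <- ReferenceSet(sh$fD, sh$fD, qD = sh$qD, qA = sh$qA)
  expect_error(unmixSpectrum(Spectrum(.grid, intensities(sh$fD)), refs,
                             "green_yellow"), "conditioning error")
})

test_that("the apparent-efficiency estimator is exact on constructed components", {
  sh <- .shapes()
  refs <- ReferenceSet(sh$fD, sh$fA, qD = sh$qD, qA = sh$qA)
  E <- 0.4
  N <- 100
  mixed <- Spectrum(.grid, N * (1 - E) * sh$qD * intensities(sh$fD) +
                      N * E * sh$qA * intensities(sh$fA))
  um <- unmixSpectrum(mixed, refs, "green_yellow")
  est <- apparentEfficiency(um, refs)
  expect_equal(est$E, E, tolerance = 1e-9)
  # wavelength-resolved efficiency is flat across the evaluation region
  expect_lt(max(abs(est$ED_lambda - E)), 1e-9)
  # weighted mean lies between the per-wavelength extremes
  expect_gte(est$E, min(est$ED_lambda))
  expect_lte(est$E, max(est$ED_lambda))
})

test_that("apparent-efficiency limits: no sensitized emission and no donor", {
  sh <- .shapes()
  refs <- ReferenceSet(sh$fD, sh$fA, qD = sh$qD, qA = sh$qA)
  um0 <- unmixSpectrum(Spectrum(.grid, intensities(sh$fD)), refs,
                       "green_yellow")
  expect_equal(apparentEfficiency(um0, refs)$E, 0, tolerance = 1e-12)
  um1 <- unmixSpectrum(Spectrum(.grid, intensities(sh$fA)), refs,
                       "green_yellow")
  expect_equal(apparentEfficiency(um1, refs)$E, 1, tolerance = 1e-12)
})

test_that("an empty flat region after floor filtering is a region error", {
  sh <- .shapes()
  refs <- ReferenceSet(sh$fD, sh$fA, qD = sh$qD, qA = sh$qA)
  um <- unmixSpectrum(Spectrum(.grid, intensities(sh$fD)), refs,
                      "green_yellow")
  expect_error(apparentEfficiency(um, refs, flatRegionNm = c(100, 110)),
               "region error")
})

test_that("the full chain returns the generator's efficiency exactly (noiseless)", {
  d <- mtq2Record()
  pairs <- list(
    list(acc = mngRecord(), class = "green_yellow", green = NULL, gf = 0),
    list(acc = scarletRecord(), class = "orange_red_with_green",
         green = egfpRecord(), gf = 0.1),
    list(acc = scarletRecord(), class = "red_no_green", green = NULL, gf = 0))
  for (p in pairs) {
    for (E in c(0.2, 0.59)) {
      g <- genCellSpectra(d, p$acc, trueE = E,
                          directExcitationFraction = 0.15,
                          greenFraction = p$gf, green = p$green,
                          acceptorClass = p$class)
      res <- spectralFretEfficiency(g$cell, g$refs)
      expect_equal(res$E, E, tolerance = 1e-6)
    }
  }
})

test_that("the recovered efficiency is invariant to overall intensity scale", {
  d <- mtq2Record()
  a <- mngRecord()
  g1 <- genCellSpectra(d, a, trueE = 0.42, donorAbundance = 100)
  g2 <- genCellSpectra(d, a, trueE = 0.42, donorAbundance = 1e6)
  e1 <- spectralFretEfficiency(g1$cell, g1$refs)$E
  e2 <- spectralFretEfficiency(g2$cell, g2$refs)$E
  expect_equal(e1, e2, tolerance = 1e-9)
})
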