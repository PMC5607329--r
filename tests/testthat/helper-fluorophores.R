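# Canonical generated fluorophores used across the suite. Peak positions and
# quantum yields follow the published scalar constants of the respective
# proteins; band shapes are the generator's skewed Gaussians.

mtq2Record <- function() {
  genSpectra("mTurquoise2", peaksNm = c(434, 474), epsilonMax = 30000,
             quantumYield = 0.93)
}

mngRecord <- function() {
  genSpectra("mNeonGreen", peaksNm = c(505, 517), epsilonMax = 116000,
             quantumYield = 0.80)
}

syfp2Record <- function() {
  genSpectra("SYFP2", peaksNm = c(515, 527), epsilonMax = 101000,
             quantumYield = 0.68)
}

scarletRecord <- function() {
  genSpectra("mScarlet-I", peaksNm = c(569, 594), widthsNm = c(25, 25),
             epsilonMax = 102000, quantumYield = 0.54)
}

egfpRecord <- function() {
  genSpectra("EGFP", peaksNm = c(488, 507), epsilonMax = 55000,
             quantumYield = 0.60)
}

# Scalar phasor with given phase/modulation, for calibration tests.
scalarPhasor <- function(dc, phase, modulation) {
  new("PhasorEstimate", dc = as.array(dc), ac = as.array(modulation * dc),
      phaseRad = as.array(phase %% (2 * pi)),
      modulation = as.array(modulation), undefined = as.array(FALSE))
}

# Independent forward model of a single-pixel homodyne sequence.
homodyneFrames <- function(dc, ac, phase, theta) {
  dc + ac * cos(theta - phase)
}
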