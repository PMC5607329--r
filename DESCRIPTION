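Package: fretchar
Title: Characterization of FRET Donor-Acceptor Pairs from Spectra, FLIM
    and Intensity Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterize Forster resonance energy transfer (FRET)
    pairs built on the cyan donor mTurquoise2. Computes overlap integrals and
    Forster radii from absorption and emission spectra, estimates phase and
    modulation lifetimes from frequency-domain FLIM phase stacks with
    reference calibration, decomposes single-cell emission spectra into donor,
    sensitized-emission, green-contaminant and direct-excitation components to
    obtain apparent FRET efficiencies, and analyses photobleaching and
    ratiometric biosensor intensity traces. A synthetic-data generator
    produces spectra, homodyne phase stacks, mixed cell spectra and two-channel
    traces with known ground truth so every stage of the pipeline can be
    validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'spectrum.R'
    'forster.R'
    'flim.R'
    'unmix.R'
    'traces.R'
    'synth.R'
    'registry.R'
    'io.R'
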