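Package: emRestore
Title: Deep-Learning Enhancement of Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for restoring and enhancing single-particle cryo-EM
    density maps. Implements MRC2014/CCP4 map input/output with axis
    canonicalization, resampling to a standard 1 Angstrom grid and
    percentile normalization; simulation of clean reference maps from
    atomic models with a per-atom Gaussian kernel scaled by atomic
    number; overlapping cubic tiling with mean-overlap reassembly; a
    3-D U-Net style transformer (efficient paired spatial/channel
    attention, residual convolution bottleneck) trained with a masked
    mean-square loss and an Adam halving schedule; sliding-window
    inference; and map-model validation via unmasked Fourier shell
    correlation and whole-box correlation. A synthetic fixture
    generator produces structure/clean-map/degraded-map triples so the
    whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
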