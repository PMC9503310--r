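Package: ringfus
Title: Simulation of Annular Phased-Array Ultrasound for Retinal Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for an annular ("racing ring") phased-array ultrasound
    transducer intended for non-invasive retinal stimulation. Builds the ring
    element layout on a spherical cap matching the eyeball curvature, computes
    continuous-wave acoustic pressure fields with a discretized
    Rayleigh-Sommerfeld forward operator, solves multi-focus excitations by
    (iteratively weighted) minimum-norm least squares, synthesizes
    two-dimensional stimulation patterns from grayscale images with a weighted
    Gerchberg-Saxton loop over angular-spectrum propagation, and provides
    frequency-selection analytics: diffraction-limited resolution, sonophore
    stimulation-efficacy scaling, power-law attenuation, and ophthalmic
    intensity/power budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, png, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
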