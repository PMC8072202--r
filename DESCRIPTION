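Package: dmdsim
Title: Coherent-Light Diffraction Simulation for Digital Micromirror Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coherent (laser) light diffracted by the tilted
    micromirror array of a digital micromirror device (DMD). Provides four
    complementary approaches: Monte-Carlo ray tracing of phase-accumulating
    rays, an analytic phase-shifting sum over per-mirror closed-form
    diffraction integrals, a fast envelope-times-grating factorization for
    uniform tilt states, and a diagonal blaze-condition planner that solves
    for incidence angles and multi-wavelength combinations compatible with
    blazed (Littrow-type) operation. Intended for designing structured
    illumination microscopy (SIM) excitation paths and other coherent DMD
    applications. Includes tilt-pattern generators, angular intensity map
    writers (32-bit TIFF, CSV, log-scaled PNG preview) and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
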