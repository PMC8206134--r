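Package: hasrc
Title: Helical Assembly Subunit Refinement and Classification for Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to separate coexisting conformations of individual
    subunits in helically symmetric cryo-EM assemblies, exercised at desk
    scale on synthetic decorated-microtubule data. Implements symmetry
    expansion of helical alignment tables, partial signal subtraction with
    re-centering on a mask's centre of mass, focused 3D classification
    without image alignment, local subunit pose refinement with priors,
    CTF simulation and per-particle defocus refinement, direct Fourier
    reconstruction, real-space helical symmetrization and gold-standard
    Fourier shell correlation. Also computes kinesin motor-domain
    conformational descriptors (nucleotide-binding-pocket C-alpha
    distances, central beta-sheet twist) from atomic models, and
    open/closed and nucleotide relative-density statistics from maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    mclust,
    yaml
Config/testthat/edition: 3
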