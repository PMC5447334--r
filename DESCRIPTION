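Package: AcousticWindow
Title: Acoustic-Window Planning for Ultrasound Acquisition from CT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Plans ultrasound probe poses that maximise expected acoustic
    transmission to a target point, using a CT volume as a tissue map. Extracts
    the body surface with outward normals, enumerates pose candidates under
    depth and coupling-angle hard constraints, estimates per-scan-line acoustic
    transmission from Hounsfield units along a curvilinear fan, and optimises
    single-view poses and multi-view shared-base-point trajectories. Includes a
    naive nearest-surface-point baseline planner, slice-based acoustic-window
    quality metrics (non-soft-tissue ratio, organ-coverage ratio), a synthetic
    torso phantom generator with rib arcs and a labelled target organ, NIfTI
    and MetaImage volume I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
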