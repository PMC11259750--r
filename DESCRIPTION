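Package: cuffarch
Title: Rotator Cuff Muscle Architecture from Diffusion Tensor Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify three-dimensional skeletal muscle architecture
    from diffusion-tensor fields and tissue label maps, aimed at the rotator
    cuff. Provides deterministic streamline tractography with anatomical
    endpoint constraints, isosurface extraction of muscle and aponeurosis
    meshes with enclosed-volume measurement, per-fascicle length and
    pennation-angle metrics, physiological cross-sectional area, geometric
    glenohumeral moment arms from sphere fits and polynomial lines of action,
    and variability statistics (coefficients of variation, absolute-agreement
    intraclass correlation, sex comparisons). A synthetic-phantom generator
    with closed-form ground truth supports end-to-end validation of every
    stage without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
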