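Package: echoreg
Title: Probabilistic Rigid Registration of Intraoperative Ultrasound to
    Preoperative MR via Hyperechogenic Structure Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid registration of reconstructed 3D intraoperative
    ultrasound volumes to preoperative T1-weighted MR volumes of the brain
    by matching hyperechogenic structures (sulci, cerebral falx, lesions).
    Structures that appear bright in B-mode ultrasound are detected in MR
    as intensity valleys with a scale-space curvature operator (MLvv) and
    combined with a lesion segmentation into a per-voxel probability map;
    the ultrasound intensities serve directly as the second probability
    map.  The rigid transform maximizing the correlation of the two maps
    is found by multiresolution Nelder-Mead simplex optimization.  The
    package also provides the associated validation machinery (landmark
    initial error, leave-one-out target registration error, warping index,
    randomized robustness studies) and a synthetic phantom generator with
    known ground-truth geometry so the whole pipeline can be exercised and
    scored without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
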