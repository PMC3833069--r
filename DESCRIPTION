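Package: gaitsim
Title: Muscle-Driven Planar Gait Simulation and Knee Load Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A sagittal-plane musculoskeletal gait analysis pipeline for
    pediatric cohorts. Scales a reduced 9 degree-of-freedom planar model
    (HAT, thighs, shanks, feet; eight Hill-type muscle groups per leg) to a
    subject's mass and height, generates dynamically consistent synthetic
    walking trials (markers, ground reaction forces, events) for obese and
    normal-weight cohorts, and runs inverse kinematics, inverse dynamics,
    static optimization of muscle redundancy, joint reaction analysis of the
    compressive tibiofemoral force, and induced acceleration analysis of
    muscle contributions to center-of-mass support and progression.
    Includes cohort statistics (group t-tests, speed versus knee-load
    regression) and readers/writers for TRC and MOT/STO motion-capture
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
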