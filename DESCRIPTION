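Package: cowgait
Title: Kinematic Gait Analysis of Walking Cattle from Body-Mounted Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the walking gait of dairy cattle from
    synchronized multi-sensor inertial measurement unit (IMU) recordings.
    Detects claw-on and claw-off events from distal-limb gyroscope and
    accelerometer signals, segments strides on the left-hind reference limb,
    reconstructs sagittal distal-limb angles with a quaternion-based
    complementary filter, estimates upper-body vertical displacement by
    cyclic double integration, computes temporal support-phase parameters
    (stance, stride, bipedal and tripedal support durations, duty factors),
    summarizes stride-normalized curves (median, median absolute deviation,
    most typical curve), and reports bootstrap and mixed-model summaries.
    Includes a synthetic quadruped-walk IMU simulator with full ground truth
    so every stage of the pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
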