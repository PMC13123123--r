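Package: planarreach
Title: Planar Robotic Upper-Limb Assessment: Simulation, Kinematic Indices, and Multivariate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative assessment of upper-limb function with a
    planar end-effector robotic device in children with unilateral cerebral
    palsy. Simulates complete assessment sessions (minimum-jerk reaching with
    an explicit impairment model, resistive path guidance, odometry/optical
    position fusion, Gaussian-copula cohort generation with clinical scores and
    Likert feasibility questionnaires), extracts the five device indices from
    raw 100 Hz position/force logs (covered area, completion time, total and
    useful work, normalized velocity, accuracy error), scores the feasibility
    questionnaires with internal consistency, and reproduces the study-style
    statistical pipeline: Shapiro-Wilk and IQR screening, MANOVA with Pillai's
    Trace and Benjamini-Hochberg follow-ups with partial eta squared, Spearman
    correlations with strength categories, and exact power/sample-size
    computations for correlation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
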