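Package: kaps
Title: Kinematic Assessment of Passive Stretch for Elbow Spasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative assessment of elbow flexor and extensor spasticity
    from robot-driven passive-stretch trials. Extracts seven kinematic
    parameters per movement direction (peak velocity, final angle, creep,
    their between-arm differences, and the between-arm catch angle) from
    1 kHz angle/velocity recordings, builds a normative model from a control
    cohort (age regression, Box-Cox transforms, outlier removal, sex
    stratification, percentile cutoffs, velocity-difference threshold),
    classifies impairment with z-scores and failure counts, and computes
    reliability statistics (ICC(2,1), Spearman correlations with Bonferroni
    control). Includes a physics-based simulator of the passive-stretch
    protocol - a second-order limb driven by a PD position controller with
    configurable spastic resistance, contracture and creep - so the whole
    pipeline can be exercised and validated without robot hardware or
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
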