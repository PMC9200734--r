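Package: echolvm
Title: Left Ventricular Mass Quantification from 2D Echocardiographic
    Measurements
Version: 0.1.0
Authors@R:
    person("Echo", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies left-ventricular mass (LVM) from already-extracted
    2D echocardiographic delineations. Implements a disc-expansion method
    that builds the epicardial end-diastolic volume by adding the mean
    short-axis wall thickness to every disc of the biplane (modified
    Simpson) endocardial volume, closing the apex with a half
    prolate-ellipsoid cap, alongside the conventional comparators: the
    Devereux cube formula, the Teichholz volume, area-length, truncated
    ellipsoid, and the fully delineated biplane shell. Ships an analytic
    left-ventricle phantom simulator with closed-form cavity and
    myocardial volumes for validation, measurement-noise models, and the
    agreement statistics used to evaluate such methods (Bland-Altman
    limits of agreement, coefficient of variation, ICC(2,1), hypertrophy
    classification against indexed-mass cutoffs, and diagnostic
    performance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
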