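Package: cardiohm
Title: Bayesian History Matching for Cohorts of Cardiac Electrophysiology Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A simulator-agnostic Bayesian history matching engine for
    calibrating cohorts of biophysical heart models. Univariate Gaussian
    process emulators (linear mean, automatic-relevance-determination
    squared-exponential kernel, optional noise) act as surrogates for one
    biomarker each; an implausibility measure iteratively shrinks the
    not-ruled-out-yet (NROY) region of a bounded parameter space over
    successive waves, with space-filling designs (Latin hypercube, Sobol'
    sequences) and a multinormal "cloud" resampler to repopulate the
    surviving region. Trained emulator banks can be reused to calibrate a
    new subject with no further simulations. A deterministic synthetic
    electrophysiology simulator and cohort generator make the full
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
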