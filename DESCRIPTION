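Package: cyclim
Title: Multipass Arrival-Time Extraction, Correction and Annotation for
    Cyclic Ion Mobility Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cyclic ion mobility mass spectrometry (cIM-MS)
    lipidomics. From a series of separation-time measurements the package
    derives zero-pass arrival times (t0) and periodic drift times (tp) of
    compounds via the linear multipass model tn = t0 + n * tp, assigns pass
    numbers through the wrap-around regime, aligns sessions and instruments
    with calibrant-based linear correction lines, reconstructs a multipass
    arrival-time database, and annotates isomeric lipids from a single
    measurement by joint m/z and corrected arrival-time search. A simulator
    of cIM-MS acquisition series provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
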