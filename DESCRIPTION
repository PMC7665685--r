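Package: ssfmonitor
Title: Analytics for Small-Scale Fisheries Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning small-scale fisheries landings surveys and
    vessel GPS tracks into catch and effort statistics. Estimates catch
    weight from fork length via length-weight allometry, applies a
    flag-and-suppress quality-control pipeline, computes fisher-hour effort
    and catch per unit effort (CPUE), derives vessel activity coefficients
    from GPS tracks, raises sampled landings to national monthly catch via
    fleet census counts, imputes gear and habitat for tracked-but-unobserved
    trips by nearest-neighbour donor assignment, and simulates a complete
    synthetic fishery with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
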