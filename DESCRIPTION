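Package: auditsim
Title: Evolutionary Simulation of Research Quality Under Random Lab Audits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based, evolutionary simulation of a "publish or perish"
    research world in which 100 competing labs trade effort against output, and
    selection on publication counts drives a competitive spiral towards the
    maximum false-positive probability. The package adds random audit
    interventions (false-positive or mistake based) with removal rules, reviewer
    noise, post-audit effort boosts that propagate through parent/child lab
    networks, and an audit cost model, so that spiral-avoidance rates, the
    percentage of papers audited, false positives per 100 papers, and audit
    costs per paper can be regenerated and explored across scenario grids.
    The research-cycle engine is implemented in C++ for speed, with a pure-R
    reference engine that consumes the random-number stream in an identical
    order for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
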