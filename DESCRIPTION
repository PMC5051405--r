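Package: eceamat
Title: Extended Cost-Effectiveness Analysis of Adolescent Maternal Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the distribution across income quintiles of adolescent
    (15-19) maternal deaths, out-of-pocket expenditure on complicated
    deliveries, and medical impoverishment (catastrophic health expenditure
    and poverty-headcount variants) in low- and middle-income countries,
    following the extended cost-effectiveness analysis (ECEA) framework.
    Income is modelled with a gamma distribution calibrated to GDP per
    capita and the Gini index. The package evaluates the counterfactual
    impact and cost of raising female education by one year, with
    probabilistic sensitivity analysis producing 95% uncertainty ranges.
    Country parameter sets for India and Niger ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
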