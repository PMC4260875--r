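Package: tiernet
Title: Tiered Diagnostic Laboratory Network Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Planning toolkit for tiered national diagnostic testing networks,
    developed around CD4 laboratory services for large HIV treatment
    programmes. Computes great-circle service precincts around testing
    laboratories, assigns referring health facilities to their nearest
    laboratory, identifies coverage gaps and over-serviced areas, classifies
    testing sites into six volume-based service tiers, proposes new
    decentralized point-of-care and community-laboratory sites by greedy
    maximal covering, and costs competing national expansion scenarios with
    exact integer-cent arithmetic. Includes a seeded synthetic network
    generator (districts, facilities, laboratories, per-sample turnaround
    times) so every stage is testable without confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
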