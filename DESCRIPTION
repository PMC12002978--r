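Package: bansim
Title: Budget-Impact Monte Carlo Model for Breath-Actuated Nebulizer Adoption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic budget-impact model estimating the national and
    per-emergency-department cost and throughput consequences of replacing
    continuous nebulizers with breath-actuated nebulizers (BAN) for asthma
    and COPD exacerbations. Ships a fully documented 22-parameter input
    table (visit volumes, diagnosis and nebulizer-use shares, admission
    rates, device prices, length-of-stay effects, unit costs) with normal,
    BetaPERT, and moment-matched lognormal uncertainty distributions; a
    seeded Monte Carlo engine with a closed-form expectation oracle;
    per-ED scaling and the published sensitivity analyses (COPD
    admission-reduction attenuation, partial adoption); synthetic parameter
    tables for testing; and report rendering plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
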