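Package: agrichain
Title: Agent-Based Simulation of Blockchain Adoption in Agricultural
    Product Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time agent-based simulator of an agricultural product
    circulation system in which a traditional chain (farmer - wholesaler -
    retailer - consumer) coexists with a blockchain-traceable chain (farmer -
    retailer, with wholesalers providing fee-for-service logistics). Farmers
    carry an honesty state that governs the probability of producing safe
    product, rises under regulatory inspection and decays otherwise; agents
    switch chains by threshold rules driven by relative profit. The package
    computes per-period, per-chain qualification rates, input-output ratios
    and circulation efficiency, and runs regulatory-intensity sweep
    experiments with common random numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
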