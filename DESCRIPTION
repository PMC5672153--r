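Package: ebpmtree
Title: Multinomial Processing Tree Analysis of Event-Based Prospective Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing event-based prospective memory (EBPM)
    performance into prospective and retrospective components with
    multinomial processing tree (MPT) models. Ships the four-tree
    color-matching EBPM model (parameters P, M, C1, C2 with g and c fixed),
    maximum-likelihood fitting by G-squared minimization with Wald or
    profile confidence intervals, joint multi-condition fits with equality
    constraints and delta-G-squared tests, Baron-Kenny three-step mediation
    with Sobel tests, and a seeded trial-level simulator for 3 x 3
    filler-by-ongoing task-duration designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
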