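Package: rumormill
Title: Clustering Near-Duplicate Social-Media Messages into Rumor Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups near-duplicate text messages reported to fact-checking
    chatbots into "rumor groups" using a token-set overlap distance,
    threshold-stopped hierarchical agglomerative clustering, and a
    classification-based speedup in which a k-nearest-neighbour classifier
    trained on a clustered sample propagates labels to the remainder.
    Includes pairwise precision/recall evaluation against a full-HAC gold
    standard, COVID-19 keyword tagging of groups, simplified-script origin
    flagging with a Yates-corrected chi-square association test, temporal
    propagation analytics (daily counts, resurfacing peaks, quoted-party
    attribution, variant timelines), and a seeded synthetic corpus
    generator with planted rumor groups for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
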