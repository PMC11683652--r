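Package: ohcdiffusion
Title: Phrase Diffusion Analysis in Threaded Online Health Communities
Version: 0.1.0
Authors@R:
    person("OHC", "Diffusion Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Reconstructs how a novel phrase (such as a health metaphor)
    spreads through a threaded online community archive that is ordered
    chronologically but carries no timestamps. Detects phrase mentions and
    their variants, classifies superusers by posting activity, builds
    per-user participation timelines, infers each adopter's exposure route
    (direct metaphor-thread co-participation, unrelated co-thread, or
    presumed lurking), assembles a rooted diffusion tree with
    self-promotion versus social spreading mechanism labels, and computes
    diffusion depth. Ships a synthetic forum generator that plants a known
    cascade (heavy-tailed user activity, a single originator, exposure-
    conditional adoption, Bernoulli lurking) so the whole inference chain
    can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
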