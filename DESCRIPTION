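Package: sibnet
Title: Singleton Attractors and Pre-Images in Strong-Inhibition Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for synchronous Boolean models of gene regulatory networks
    under the dominant-inhibition assumption, where any single active inhibitor
    switches its target off regardless of activators. Implements a
    branch-and-propagate algorithm that enumerates all singleton attractors
    (fixed points) of a signed regulatory network without scanning the full
    state space, an extension that enumerates all pre-images (predecessors) of
    an arbitrary target state, basin-of-attraction reconstruction by iterated
    pre-imaging, brute-force oracles for cross-checking, a random signed-network
    ensemble generator, and readers/writers for signed adjacency matrices and
    edge lists. Ships the classical budding-yeast cell-cycle network as a
    worked fixture and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
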