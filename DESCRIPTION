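Package: meioswitch
Title: Dynamics of Meiotic Entry and Commitment in Fission Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Ste11-Mei2-Pat1 regulatory network that controls
    the transition from mitosis to meiosis in Schizosaccharomyces pombe,
    both as a stand-alone subsystem driven by the nutrient inputs Tor2 and
    PKA and integrated with a compact fission-yeast cell-cycle model with
    division events. Provides nutrient-shift protocols (starvation,
    return-to-growth), an in-silico genotype screen that maps mutant strains
    to parameter overrides and classifies mating/meiosis phenotypes, and a
    one-parameter bifurcation toolkit (multi-start equilibrium finding,
    pseudo-arclength continuation, saddle-node and Hopf detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
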