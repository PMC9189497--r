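Package: aodsim
Title: Forward-Time Simulation of Supergene Degeneration and Associative
    Overdominance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a supergene polymorphism
    created by introgression of a chromosomal inversion between two diverged
    populations. Models multiplicative selection on recessive or partially
    recessive deleterious mutations, crossover suppression in inversion
    heterokaryotypes with gene flux by gene conversion, divergence burn-ins,
    single-migrant admixture and the subsequent fate of the polymorphism
    (loss, fixation, viable polymorphism, half-lethal or balanced-lethal
    system). Includes the associated statistics: associative overdominance
    following Ohta, segregation-load decomposition into drift and mutational
    components, symmetry of homokaryotype loads and outcome classification,
    together with deterministic fixture populations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
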