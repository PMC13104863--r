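Package: eusim
Title: Selection on Vitality and Longevity Under Eusocial Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulators for studying how reproductive structure
    shapes selection on the two components of Gompertz-Makeham mortality:
    baseline hazard (vitality) and the exponential rate of hazard increase
    with age (longevity). Provides a deterministic age-structured two-allele
    competition model with a survivorship-based fitness difference, fitness
    nullclines and carrying-capacity matching; a colony-site competition ODE
    with competitive-exclusion steady states; a diploid agent-based
    simulator of allele competition under single-queen (linear) versus
    all-female (exponential) reproduction; colony-level metapopulation
    simulators in ant and mole-rat styles; and a queen-effects invasion
    model that measures fixation bias of invading alleles on demographically
    matched populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
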