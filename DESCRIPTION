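Package: bwcrn
Title: Hidden Markov Model Learning by Mass-Action Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Baum-Welch reaction network: a chemical reaction
    network whose deterministic mass-action dynamics learn the parameters of a
    hidden Markov model (HMM). Provides the classical Baum-Welch (EM) machinery
    (forward/backward recursions, E- and M-steps, multi-sequence fitting with
    initial-distribution updates), an explicit constructor for the catalytic
    mono-molecular network that mirrors each Baum-Welch quantity as a chemical
    species, three execution semantics for the network (sequential subnetwork
    equilibration, inference/learning module alternation, and the fully coupled
    autonomous ODE), and validation experiments that check the fixed-point
    equivalence of the discrete and continuous dynamics, including the
    occasionally dishonest casino example. Networks can be exported as SBML or
    a plain-text reaction format; results are returned as tidy tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
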