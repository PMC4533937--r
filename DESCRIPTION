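Package: biorient
Title: Discrete-Time Markov Chain Model of Kinetochore-Microtubule
    Attachment and Chromosome Bi-Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and stochastic analyses of a discrete-time Markov chain
    model of kinetochore-microtubule attachment and detachment during
    mitosis and meiosis I. Enumerates the attachment state space of a
    kinetochore pair, classifies states into the five canonical attachment
    classes (free, monotelic, syntelic, merotelic, amphitelic), and builds
    the sparse one-step transition kernel with tension- and
    geometry-dependent scaling of transitions out of the amphitelic and
    monotelic classes. Provides exact transient propagation, mean first
    passage times to bi-orientation via absorbing-chain linear solves,
    stationary distributions, expected bi-orientation attempt counts,
    kinetochore-microtubule occupancy densities, multi-chromosome synchrony
    curves and half-lives, closed-form stationary occupancy formulas, and a
    seeded Monte Carlo trajectory simulator that serves as an independent
    cross-validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
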