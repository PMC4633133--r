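Package: kalmantd
Title: Unified Bayesian and Temporal-Difference Models of Associative Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates classical (Pavlovian) conditioning with four related
    learning rules: Rescorla-Wagner, the Kalman filter over a linear-Gaussian
    dynamical system on cue weights, temporal-difference (TD) learning with a
    complete serial compound stimulus representation, and Kalman TD, which
    applies the Kalman filter to discounted temporal derivatives of the
    stimulus features so that long-run value is estimated with full posterior
    uncertainty.  Includes a compact textual notation for experimental designs
    ("A->+ / AB->-; A->-"), a catalog of classic conditioning paradigms
    (latent inhibition, blocking, overshadowing, overexpectation, conditioned
    inhibition, second-order conditioning and serial-compound designs) with
    their expected response orderings, and tools to run, tabulate and plot
    simulated test responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
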