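Package: cavgate
Title: Gating Analysis of T-Type Calcium Channel Variants and Thalamic
    Neuron Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biophysical analysis pipeline for low-voltage-activated
    (Cav3.2/T-type) calcium channel variants characterised by whole-cell
    voltage clamp. Implements Boltzmann and exponential forward models of
    activation, steady-state inactivation and recovery from inactivation;
    synthesis of voltage-clamp sweep families under standard activation,
    inactivation and double-pulse recovery protocols (with linear leak,
    Gaussian noise, Bessel filtering and P/4 subtraction); peak extraction
    and bounded nonlinear least-squares fitting of the gating equations;
    window-current overlap analysis; variant-versus-wild-type summary
    statistics with Kruskal-Wallis/Dunn testing; and a three-compartment
    conductance-based model of a reticular thalamic neuron in which a
    fraction of the T-type conductance carries variant kinetics, used to
    quantify rebound-burst and tonic excitability (rheobase, firing
    frequency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
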