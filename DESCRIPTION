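Package: ocsnn
Title: Olivocerebellar Spiking Neural Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and simulation of a two-microcomplex olivocerebellar
    spiking neural network. Builds a geometric scaffold of mossy fibers,
    granular- and molecular-layer neurons, Purkinje cells, deep cerebellar
    nuclei and inferior olive with convergence/divergence-constrained
    connectivity; simulates extended generalized leaky integrate-and-fire
    (EGLIF) or plain LIF point neurons coupled by alpha-shaped
    conductance-based synapses; drives the network with an eyeblink
    conditioning style stimulation protocol (baseline Poisson mossy-fiber
    noise, a conditioned-stimulus mossy-fiber train, an unconditioned-stimulus
    climbing-fiber burst); and analyses the spike output (peristimulus time
    histograms, Gaussian-kernel instantaneous rates, response speed,
    eyeblink decoding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
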