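Package: mzn
Title: Cerebellar Microzone Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Seeded, layered stochastic simulation of the cerebellar
    microzone network computation. Synthesizes mossy fibre input rates per
    granular-layer rank, emulates terminal branching and clustering so that
    each field receives a replacement-like random sample of rank rates,
    recodes input through a calibrated Golgi-glomerulus inhibition chain
    into a sparse parallel-fibre code, and propagates it through the
    molecular layer (binomial stellate contact law, Purkinje dendritic
    compartments, somatic integration) onto a deep-nuclear output group.
    Includes the phase-sensitivity experiment for a sinusoidally driven
    locomotor network, cross-layer summary statistics (density regulation,
    range contraction, mean conservation, linearity), and a closed-form
    amplitude-attenuation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
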