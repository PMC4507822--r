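Package: lciphys
Title: Firing Regularity, Synaptic-Current, and Stereology Analysis for
    Striatal Cholinergic Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for slice electrophysiology of striatal
    large cholinergic interneurons: interspike-interval statistics and
    binned spike-train autocorrelograms with a three-way regularity
    classification, template-based detection of spontaneous postsynaptic
    currents with frequency, amplitude-bin and interevent-interval
    summaries and tetrodotoxin percent-reduction, evoked-response
    measurement (earliest peak, charge, decay, paired-pulse ratio,
    input-output), passive membrane properties from voltage steps,
    Cavalieri volume and Abercrombie-corrected neuron density from serial
    sections, and the group-comparison statistics used on those outputs.
    Includes a seed-reproducible synthetic-data generator (gamma-renewal
    and bursting spike trains, noisy current traces with
    double-exponential synaptic events, RC step responses, sectioned
    sphere phantoms) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
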