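Package: meapipe
Title: Multiwell Microelectrode Array Spike, Burst and Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end analysis pipeline for multiwell microelectrode
    array (MEA) recordings of in vitro neuronal networks. Reads and writes a
    plate-recording HDF5 dialect (/Data/<well>/<electrode> voltage traces plus
    /DataInfo metadata), detects extracellular spikes with amplitude
    thresholding at 4.5 times a robust noise estimate combined with a
    stationary-wavelet-transform Teager energy operator (SWTTEO) false-positive
    cancellation stage, detects bursts with a logISI inter-spike-interval
    histogram method, quantifies pairwise network synchronization with the
    spike time tiling coefficient (STTC) and with correlated spectral entropy
    (CorSE), and classifies wells with a 7-feature z-scored principal component
    analysis. A ground-truthed synthetic plate generator emulates the
    low-amplitude activity of human pluripotent stem cell derived and rat
    cortical networks so that every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rhdf5,
    signal,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
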