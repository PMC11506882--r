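Package: cstgat
Title: Causal Spatio-Temporal Graph Attention Networks for Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects epileptic seizures in multichannel intracranial EEG by
    combining directed causal connectivity graphs with a spatio-temporal
    neural classifier. Channel-to-channel information flow is estimated with
    a plug-in transfer entropy estimator (with Granger causality, mutual
    information and absolute Pearson correlation as alternative graph
    builders), the resulting directed graph drives a multi-head graph
    attention encoder, temporal structure is captured by a bidirectional
    LSTM, and windows are classified with a softmax head. Includes a vector
    autoregressive simulator with known directed coupling for validating
    connectivity recovery and end-to-end training, sliding-window
    preprocessing with Butterworth band-pass filtering, confusion-matrix
    metrics, event-wise experiment splitting, and an ablation harness over
    graph builders, model components and attention head counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
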