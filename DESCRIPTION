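Package: seizgraph
Title: Graph-Based Seizure Detection from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects epileptic seizures in multichannel scalp EEG by
    converting overlapping signal windows into feature vectors
    (statistical, spectral and Daubechies-wavelet descriptors), linking
    windows whose scaled feature vectors lie within a Euclidean distance
    threshold into an undirected graph, and classifying nodes as ictal or
    interictal with a graph convolutional network topped by either an
    LSTM sequence head or a balanced random forest.  Includes a synthetic
    spike-and-wave EEG generator, an EDF reader/writer with plain-text
    seizure annotations, SMOTE and KNNOR minority oversampling, and
    whole-recording inference that merges overlapping window predictions
    into per-second seizure probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    randomForest,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr
Config/testthat/edition: 3
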