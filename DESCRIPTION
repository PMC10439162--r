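Package: epistates
Title: Model-Driven Classification of Epileptic Brain States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised classification of epileptic brain states
    (interictal, preonset, onset, ictal) in single-channel
    electrophysiological recordings. A Wendling neural mass simulator
    generates labeled prototypical activity for each state; five-second
    segments are summarized by eleven signal features, projected into a
    four-component principal-component space, and classified by the
    nearest labeled k-means centroid. Centroids are labeled by Voronoi
    voting of simulated segments, so no expert labels are required to
    build a classifier. Classification performance is scored by per-type
    sensitivity and positive predictive value and tested for significance
    against Markov-chain surrogate label sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
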