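Package: dqcsort
Title: Knowledge-Independent Tumor Sorting by Dynamic Quantum Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised sorting of bulk RNA-seq expression profiles without
    using sample labels. Implements Dynamic Quantum Clustering (DQC), which
    evolves each sample as a Gaussian wave packet under a Hamiltonian whose
    potential is a proxy for the data density, together with SVD eigenvector
    feature selection with iterative biomarker-layer removal, a t-SNE /
    HDBSCAN / consensus-clustering stage with cluster attribute enrichment,
    hypergeometric term over-representation against user-supplied GMT
    annotation sets, and the random-transcript-subset "background
    classification potential" experiment. Ships a synthetic gene expression
    matrix generator with planted class structure and ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), limma, mclust, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
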