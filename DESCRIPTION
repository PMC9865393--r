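Package: selfgen
Title: Sequence-to-Sequence Generative Design of Drug-Like Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generative design of small drug-like molecules around known
    actives. Molecules are encoded as SELFIES-derived one-hot character
    sequences and autoencoded with a recurrent (LSTM) encoder-decoder;
    new candidates are sampled by perturbing the latent states of seed
    actives with amplitude-scaled noise, decoded back to SMILES, and
    passed through a drug-likeness filter cascade (QED, Lipinski's rule
    of 5, a Bernoulli fragment synthesizability score) with min-max
    normalised composite ranking. Includes Tanimoto fingerprint novelty
    audits, batch docking orchestration with a deterministic mock
    backend and AutoDock Vina log parsing, and a synthetic-corpus
    generator so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse
SystemRequirements: Python (>= 3.8) with the RDKit package on PATH as
    'python' (configurable via option 'selfgen.python' or the
    SELFGEN_PYTHON environment variable).
Config/testthat/edition: 3
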