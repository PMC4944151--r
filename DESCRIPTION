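Package: puckerfit
Title: Conformer Populations of Iduronate Rings from NMR J-Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deconvolutes the ring-pucker equilibrium of iduronate residues
    (IdoA/IdoA2S) in heparan sulphate oligosaccharides from measured vicinal
    1H-1H coupling constants. Ensemble-averaged couplings are modelled as a
    population-weighted mixture of per-conformer reference couplings for the
    1C4 chair, 2SO skew-boat and 4C1 chair, and the populations are recovered
    by residual-sum-of-squares minimisation on the probability simplex (exact
    constrained least squares and an exhaustive grid search). Also included:
    Cremer-Pople puckering analysis and conformer classification for
    six-membered rings, an idealised ring builder with ring protons,
    Karplus-type back-calculation of couplings from H-C-C-H torsions,
    r^-6-averaged NOE H2-H5/H4-H5 ratio prediction, geometric hydrogen-bond
    detection, and a seeded Markov-chain generator of synthetic ring-flip
    ensembles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
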