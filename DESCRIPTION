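Package: pdgain
Title: Point Divergence Gain Analysis of Image Sequences
Version: 0.1.0
Authors@R: person("Jan", "Novak", email = "jan.novak@example.org",
    role = c("aut", "cre"))
Description: Exact computation of the Point Divergence Gain (PDG), a
    Renyi-entropy difference caused by exchanging a single occurrence
    between two bins of a discrete frequency histogram, together with its
    macroscopic companions: the Point Divergence Gain Entropy (PDGE) and
    the Point Divergence Gain Entropy Density (PDGED) of a pair of
    grayscale images.  Includes generators for discretized Cauchy, Gauss,
    Levy and Rayleigh test histograms, per-pixel PDG maps and alpha
    spectra for frame sequences, spectrum-based multifractality and focus
    inspection, k-means++ clustering of image series by [PDGE, PDGED]
    feature vectors, value-threshold segmentation masks, a Least
    Information Loss bit-depth converter, plain TIFF/PGM/CSV stack input
    and output, a synthetic fixture generator, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
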