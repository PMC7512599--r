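# pdgain — Point Divergence Gain analysis of image sequences

`pdgain` quantifies the information carried by *individual pixel changes*
between consecutive frames of a grayscale image series (video, microscopy
z-stack, simulation output). It is aimed at bio-image analysts who need a
model-free measure of frame-to-frame change for focus detection, z-stack
clustering, change-map segmentation and multifractality inspection.

## The statistic

For a frame's intensity histogram $P = \{n_j/n\}$ with Rényi entropy
$H_\alpha(P) = \frac{1}{1-\alpha}\log_2\sum_j p_j^\alpha$, the **point
divergence gain** of exchanging one occurrence of intensity $l$ for
intensity $m$ is

$$\Omega_\alpha(l\to m) = H_\alpha(P^{(l\to m)}) - H_\alpha(P)
= \frac{1}{1-\alpha}\log_2\!\Big(\tfrac{(n_l-1)^\alpha - n_l^\alpha +
(n_m+1)^\alpha - n_m^\alpha}{C_\alpha} + 1\Big),
\qquad C_\alpha = \sum_j n_j^\alpha .$$

Applying this per pixel to a frame pair (remove $a_i$, insert $b_i$)
yields a change map; summing $|\Omega|$ over all pixels gives the **PDGE**
$I_\alpha$ (absolute information change) and over the distinct realized
transitions the **PDGED** $P_\alpha \le I_\alpha$ (rare-phenomenon
sensitive). Spectra of $I_\alpha, P_\alpha$ over a grid of $\alpha$
fingerprint each frame pair; stacking them as feature vectors
$[I_\alpha, P_\alpha]$ lets k-means++ group a series into regimes (e.g.
in-focus vs out-of-focus planes).

## Worked example

```r
library(pdgain)

# a single exchange: histogram (3, 1), move the rare point's partner
h <- count_histogram(c(3, 1), labels = c("bg", "spot"))
pdg(h, "bg", "spot", alpha = 2)
#> [1] 0.3219281            # bits: frequent -> rare is a positive gain

# spectra of a translating 12px square on a 64x64 background
ms <- synth_sequence("moving_square", frames = 4, seed = 1)
pdg_spectra(ms, alphas = c(0.5, 0.99, 2))
#>  pair_index alpha I_alpha  P_alpha
#>           1  0.50 0.06237 0.002599
#>           1  0.99 0.05630 0.002346
#>           1  2.00 0.03372 0.001405
#>           2  0.50 0.06237 0.002599
#>  ...
```

Every pair shows the same $I_\alpha$ (0.062 bits at $\alpha=0.5$): the
square realizes identical transitions each step. $P_\alpha$ is 24x
smaller — each of the two off-diagonal transitions is counted once
instead of per-pixel.

Focus detection on the synthetic defocus stack (21 frames, sharpest at
frame 11):

```r
fs <- synth_sequence("focus_stack", seed = 1)
s <- pdg_spectra(fs, alphas = 0.99)
s$pair_index[which.max(s$I_alpha)]
#> [1] 11                   # the pair involving the focal frame
```

A command-line front end mirrors the R API:

```sh
pdg synth --kind moving_square --frames 10 --out stack.tif
pdg spectra --input stack.tif --alphas default13 --out spectra.csv
pdg cluster --spectra spectra.csv --k 2 --seed 42 --out labels.csv
pdg segment --pair a.pgm,b.pgm --alpha 4 --rule zero --out mask.pgm
```

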