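# antl — adaptive neighborhood triplet loss for binary segmentation

`antl` implements a boundary-aware auxiliary loss for two-class per-pixel
image segmentation, aimed at the setting where a network segments a single
object (a lesion in a dermoscopy image, a cell, an organ slice) from
background and the errors concentrate in an ambiguous band around the object
boundary. It is written for people developing or studying segmentation
losses: the full mining pipeline is exposed as composable R functions, every
stage is testable against brute-force oracles, and no GPU, network weights
or external dataset is needed — a synthetic generator reproduces the
statistical structure the loss exploits.

## The loss

Let `P^o(m, n)` be the softmax probability that pixel `(m, n)` belongs to
the object, and `y(m, n) ∈ {0, 1}` its ground-truth label. Within each
labeled region the pipeline mines, per class:

1. **Anchors** — the `k` best-predicted pixels of the class: the `k`
   largest own-class probabilities `P^class` restricted to the class
   support (`M_good`).
2. **Hard pixels** — `k` pixels whose own-class probability falls strictly
   inside an adaptive search interval, initially `(0.5, 0.55)`: nearly
   misclassified pixels. After any round with fewer than `k` candidates the
   interval widens by 0.05 — the upper bound rises, or the lower bound
   falls when *every* pixel of the class is mispredicted (`P^class < 0.5`).
   Surplus candidates are down-selected uniformly at random (`M_bad`).
3. **Neighborhoods** — each hard pixel is replaced by the union of layers
   `1..L` of its 8-connected, same-label neighborhood, deduplicated and
   clipped to the image (`N_bad`). These neighborhoods, not the hard pixels
   themselves, enter the triplet.

For anchor class `c1` with opposite class `c2`, with `A`, `P`, `N` the
means over anchors, same-class neighborhoods, and other-class neighborhoods
— all valued on the **object channel** — the per-direction term is

```
l_antl^c1 = [ (A − P)² − (A − N)² + Δ ]₊
```

with margin `Δ = 1`: for a perfect prediction the object channel is 1 on
object pixels and 0 on background pixels, so `(A − P)² − (A − N)² = −1` in
both anchor directions and the term vanishes. The composite objective adds
mean binary cross-entropy:

```
L = α (l_antl^o + l_antl^b) + L_ce
```

with `α = 0.015` by default (0.04 suits noisier data).

## Worked example

```r
library(antl)

mask  <- make_mask(blob_spec(width = 64, height = 64, radius_range = c(10, 18), seed = 7))
probs <- make_prediction(mask, corruption_spec(interior_confidence = 0.9, boundary_band = 4,
                                               boundary_noise = 0.08, flip_fraction = 0.02, seed = 3))
breakdown <- antl_loss(probs, mask, antl_config(k = 10, delta = 1, alpha = 0.015, rng_seed = 1))
breakdown
#> ANTL loss breakdown
#>   l_antl (object anchors):     0.746288
#>   l_antl (background anchors): 0.742921
#>   cross-entropy:               0.191944
#>   total:                       0.214282
attr(breakdown, "counts")
#> $k_object: 10   $k_background: 10   $p_object: 46   $q_background: 66
```

The mask is a blob covering about a quarter of a 64×64 grid; the prediction
is confident (0.9) deep inside each region, decays toward 0.5 inside a
4-pixel band around the boundary (with noise), and has 2% of pixels grossly
flipped. Both triplet terms sit near 0.74: the hard-pixel neighborhoods
(46 object and 66 background pixels here) are ambiguous, so their means are
pulled toward 0.5 and the anchor–negative separation buys back only a
quarter of the margin. On the ideal prediction the same call returns both
ANTL terms exactly 0 and `total = 1e-07` (the clipped-log cross-entropy
floor):

```r
antl_loss(perfect_prediction(mask), mask)
#>   l_antl (object anchors):     0
#>   l_antl (background anchors): 0
#>   total:                       1e-07
```

`gradient_check()` verifies the analytic gradient against central finite
differences (selections frozen), and `logistic_demo()` / `run_demo()` train
a tiny logistic pixel model with and without the ANTL terms on synthetic
blobs and compare held-out Jaccard indices.

## Command line

A thin wrapper is installed at `inst/scripts/antl`:

```sh
antl synth --out-dir fixtures --n 2 --seed 5
antl loss   --mask fixtures/mask_001.png --probs fixtures/probs_001.npy --k 10 --alpha 0.015
antl select --mask fixtures/mask_001.png --probs fixtures/probs_001.npy \
            --output sel.tsv --overlay overlay.png
antl demo --pairs 5 --seed 1
antl gradcheck --mask fixtures/mask_001.png --probs fixtures/probs_001.npy
```

Masks are single-channel PNG/TIFF (0 background, 1 or 255 object);
probability maps are NPY arrays of shape `(2, h, w)` or `(h, w)`;
selections export as TSV; losses and reports as JSON. A YAML config file
(`--config`) can hold any `antl_config()` field; flags take precedence.

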