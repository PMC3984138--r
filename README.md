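# ppmassoc

Object-based association analysis for two-channel fluorescence
microscopy via point-pattern matching.

## The problem

In live-cell two-channel imaging the channels are exposed sequentially.
Vesicles and other labeled structures move between the two exposures,
and the optical paths can leave a small misalignment between channels.
Pixelwise colocalization estimates (Pearson correlation, Manders
coefficients, mask overlap) require signal to occupy the same pixels
and therefore collapse under even a few pixels of displacement — yet
two structures a couple of pixels apart may be genuinely *associated*:
traveling together, docking, or about to fuse.

`ppmassoc` quantifies association instead of strict colocalization.
Objects are detected in each channel and reduced to centroid point
sets; the two point sets are then matched under a translation, so that
a global channel shift is compensated and each object may pair with a
counterpart anywhere within a chosen search radius.

## The method

Let `P` (model) and `Q` (scene) be the centroid sets of the two
channels, and let `T` be the class of translations. For a candidate
translation `t` derived from a point pair (`t = q_j − p_i`), a
bipartite graph is built with an edge `(i, j)` whenever `q_j` is among
the `k` nearest neighbors of `p_i + t` and `‖p_i + t − q_j‖ ≤ δ` (the
*matching distance*). A maximum-cardinality matching `M` of this graph
is computed with the Hopcroft–Karp algorithm, and accepted only if

* **ratio**: `|M| ≥ α · min(|P|, |Q|)` (the *matching ratio* α),
* **bias**: `‖mean residual vector‖ / δ ≤ β_max` — residuals that all
  point one way indicate a systematically wrong alignment, while
  honest noise averages out near zero,
* **magnitude**: `‖t‖` does not exceed the allowed channel shift.

The best accepted matching over all candidate translations (largest,
then least biased, then smallest shift) yields the association
estimate: the matched fraction of each channel's objects,
`|M| / |P|` and `|M| / |Q|`, or 0 when no acceptable matching exists.
A translation-only biunique ICP registration (`icp_register()`) and
the pixelwise estimators (`coloc_estimates()`) are included as
baselines, together with a controlled scene simulator that plants
exact association levels with full ground-truth correspondence.

## Worked example

Simulate a high-association scene (ground truth: 83 shared objects of
111 in channel 1 and 97 in channel 2, i.e. association 0.7477 /
0.8557), displace channel 2 by 2 px and jitter every object by
σ = 0.5 px, then run the full pipeline:

```r
library(ppmassoc)

scene <- generate_scene(sim_params(shift_magnitude = 2,
                                   jitter_sigma = 0.5, seed = 11))
d1 <- detect_spots(scene$images$ch1, detection_params(threshold = 20))
d2 <- detect_spots(scene$images$ch2, detection_params(threshold = 20))
res <- association(d1$centroids, d2$centroids,
                   ppm_params(delta = 4, max_translation = 3))
res
#> <association: ch1 0.7523 (109 obj), ch2 0.8723 (94 obj), 82 pairs>
res$matching
#> <matching: 82 pairs, t = (1.874, -0.178), bias = 0.0309, accepted>

cl <- coloc_estimates(scene$images$ch1, scene$images$ch2,
                      d1$mask, d2$mask)
#> pearson -0.1590  M1 0.2590  M2 0.2453  overlap (0.3818, 0.4357)
```

The matcher recovers the planted shift (truth: (1.998, −0.087)) and
estimates association 0.75 / 0.87 against the planted 0.7477 / 0.8557,
while the pixelwise estimates collapse: Pearson is slightly negative
and barely 40 % of mask pixels still overlap. That contrast — object
association surviving displacements that destroy pixel colocalization
— is what the package is for.

A command-line wrapper with subcommands `simulate`, `detect`, `match`,
`coloc`, `benchmark` and `delay` is installed at
`system.file("scripts", "assoc.R", package = "ppmassoc")`, e.g.

```sh
Rscript assoc.R match --ch1 a.csv --ch2 b.csv --delta 4 --alpha 0.1 \
    --max-bias 0.2 --k 10 --max-shift 3 --out result.json
```

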