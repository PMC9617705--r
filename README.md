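# SPFKMC

**Superpixel and fused K-means clustering segmentation of interstitial
lung disease (ILD) patterns in 2-D lung CT.**

ILD produces characteristic HRCT texture patterns — ground glass,
fibrosis, consolidation, micronodules, emphysema — whose segmentation is
the first quantitative step toward pattern classification and disease
staging. Plain intensity clustering fails here in two well-known ways: it
ignores spatial context, and an object whose densities span more than one
intensity band ends up *split across clusters*, so no single cluster
contains it. This package implements a hybrid pipeline addressing both,
for image-analysis researchers and method developers working on lung CT:

1. **Superpixel presegmentation** — watershed flooding of a multi-scale
   morphological gradient reconstruction (MMGR):
   `M(f) = max over r = r1..r2 of closing-by-reconstruction(grad f, B_r)`,
   which removes spurious regional minima while preserving contours;
   each watershed region is flattened to its mean.
2. **K-means in CIE Lab** over the flattened pixels, minimizing
   `J = sum_j sum_{x in C_j} ||x - c_j||^2` (Lloyd iterations with
   deterministic multi-restart).
3. **Wavelet fusion of the selected clusters** — two-level Daubechies-4
   decomposition of the one or two cluster images carrying the object,
   coefficient-wise pixel-level-maxima (or mean) combination, inverse
   transform, binarization at half the fused maximum.
4. **Morphological cleanup** (opening, boundary extraction, color
   overlay) and an optional cross-correlation template classifier.
5. **Evaluation** — pixel confusion counts with
   `accuracy = (TP+TN)/total`, `JSI = TP/(TP+FP+FN)`,
   `DSC = 2TP/(2TP+FP+FN) = 2·JSI/(1+JSI)` — against fuzzy C-means and
   plain K-means baselines.

A synthetic phantom generator provides 240 x 320 lung-slice look-alikes
for all five ILD patterns with exact ground-truth masks, plus a
"split-cluster" phantom that reproduces the multi-cluster-belonging
failure mode. PNG/JPEG and uncompressed DICOM input are supported.

## Worked example

The defining experiment: a multifocal lesion whose dim (0.50) and bright
(0.90) components fall into different K-means clusters. The single best
cluster recovers half the object; fusing the two object-bearing clusters
recovers it all.

```r
library(SPFKMC)

sp  <- splitClusterPhantom(seed = 3)          # image + truth masks
cfg <- pipelineConfig(k = 4L)                 # bg, lung, dim, bright

res <- runSPFKMC(sp$image, cfg, clusterSelector = function(cs)
  chooseLesionClusters(cs, "bright", sp$lungMask, 2))
res$clusters
#> ClusterSet: k = 4, n = 76800 points, J = 1150.72
#>   cluster sizes: 24506, 2026, 2033, 48235
res$mask
#> BinaryMask 240 x 320, 4059 foreground pixel(s) (5.3%)

jF <- jaccardIndex(confusionCounts(res$mask, sp$lesionMask))

rb <- runBaseline(sp$image, "kmeans", cfg, clusterSelector = function(cs)
  chooseLesionClusters(cs, "bright", sp$lungMask, 1))
jB <- jaccardIndex(confusionCounts(rb$mask, sp$lesionMask))
sprintf("fused JSI %.3f | single-cluster baseline JSI %.3f", jF, jB)
#> "fused JSI 0.998 | single-cluster baseline JSI 0.500"
```

The two clusters of ~2000 pixels are the lesion components; the baseline's
0.500 is the bright component alone, and fusion lifts the overlap to
0.998. On single-density phantoms (`generatePhantom(phantomSpec("consolidation"))`
etc.) all methods score near 1; the fusion advantage appears exactly when
an object spans clusters.

A command-line front end wraps the same calls:

```sh
inst/cli/spfkmc phantom --category fibrosis --seed 1 --out ph/
inst/cli/spfkmc run ph/phantom.png --truth ph/lesion_mask.png \
    --clusters auto --k 3 --out seg/
inst/cli/spfkmc evaluate ph/phantom.png --truth ph/lesion_mask.png \
    --methods fcm,kmeans,spfkmc --out eval/
```

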