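# cfuCounter

Robust counting of cell colonies and other circular objects (seeds,
pollen, nuclei) in digital plate images, for microbiologists and cell
biologists who count colony-forming units (CFU) from photographs or
webcam captures.

## The method

Single-threshold segmentation mistakes dish rims, bubbles, cracks and
dust for colonies, because at *some* binarisation threshold part of an
artefact looks circular. cfuCounter instead sweeps essentially every
threshold *t* of a contrast-enhanced grey image and accumulates a
per-pixel **score map**

&nbsp;&nbsp;&nbsp;&nbsp;S(p) = #{ t : p belongs to a component at threshold t that passes the morphological particle filter },

where the particle filter screens each connected component on its
equivalent radius √(A/π), aspect ratio, and hollowness (enclosed-hole
area / area). Colonies are circular at every threshold below their
contrast and accumulate many votes; artefacts are circular only by
accident and stay near zero. The score map is cut at a user threshold
(default 12 votes) and each surviving component is classified as a single
object, multiple merged objects, or invalid, from its circularity
4πA/P², convexity A/A<sub>hull</sub>, aspect ratio and hollowness.
Merged components are split by a chamfer distance transform (5×5
neighbourhood, step weights a = 1, b = 1.4, c = 2.1969) and a
marker-constrained watershed in which a region seeded at a distance peak
*v* (the presumptive radius) may grow downhill-or-flat only, never beyond
1.3·πv² pixels, and never farther than 1.5·v from its marker; every
fragment is re-validated by the particle filter. An optional colour
filter fits a normal model to the relative colour intensities of unsplit
objects and flags outliers (e.g. contaminant species). The Petri dish is
located automatically by a Hough circle transform and used as region of
interest (−25 px margin by default), so the analysis follows the dish
when plates are repositioned.

A synthetic plate generator with exact ground truth (colonies, fused
pairs/triples, dish rim, bubbles, cracks, dust) backs the entire test
suite; no external images are needed.

## Worked example

```r
library(cfuCounter)

sc <- renderScene(randomPlateSpec(60, nBubbles = 3, seed = 7))
cs <- countColonies(sc$image, imageName = "demo_plate")
cs
#> ColonySet 'demo_plate': 60 objects, ROI auto_petri (250287 px)

head(records(cs), 3)
#>       x      y median_r median_g median_b area perimeter cluster_size excluded reason
#> 1 341.5  99.94    78.32    73.33    52.79   83     30.97            1    FALSE
#> 2 352.4 121.70    69.98    64.63    47.71   86     32.14            1    FALSE
#> 3 176.2 121.90    76.73    71.30    51.52   72     28.73            1    FALSE
```

The plate truly contains 60 colonies; the three bubbles contribute
nothing. `ColonySet` reports one row per accepted object: centre (0-based
pixel coordinates, x = column), corrected median colour intensities
(medians of the background-subtracted channels over the object's pixels),
area, perimeter, the number of colonies that shared its original merged
cluster, and the colour-filter exclusion flag. `runBatch()` processes a
list of image files and `writeOutputs()` writes the two CSV formats — a
per-image summary (`image,count,mask_surface`) and the per-colony
detailed table.

Command-line wrappers live in `inst/scripts/`:

```sh
Rscript inst/scripts/cfu-synth.R --colonies 200 --seed 5 --out plates/
Rscript inst/scripts/cfu-count.R plates/plate.png --auto-petri \
    --threshold 12 --out-summary s.csv --out-detailed d.csv
```

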