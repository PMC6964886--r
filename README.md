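# PeelStack

Surface-guided layer extraction and quantification for confocal Z-stacks
of plant tissue, with the standard phenotype formulas used alongside such
imaging.

## The problem

Confocal stacks of leaves are acquired through a curved outer surface:
the abaxial epidermis sits at a different z depth at every (x, y)
position, and the mesophyll lies a few micrometres deeper still. A fixed
z slice — or a whole-stack projection — therefore mixes tissues, so a
reporter expressed in both layers cannot be attributed to either.
PeelStack is for microscopists who need to answer "is this signal
epidermal or mesophyll?" from a two-channel stack in which one channel is
a plasma-membrane (or other surface) marker.

## The method

1. **Surface segmentation.** In the marker channel, after mild 3-D
   Gaussian pre-smoothing, each (y, x) column is scanned from the
   objective-near slice downward; the surface height *h(y, x)* is the
   first z at which intensity stays at or above a global threshold
   (fixed, or Otsu by default) for `minRun` consecutive slices. Columns
   with no crossing are filled from their nearest valid neighbour, and
   the height map is regularized by a median filter plus Gaussian
   smoothing, giving a smooth, gap-free contoured surface.
2. **Peeling.** A tissue layer is the half-open interval
   [*h* + *offset*, *h* + *offset* + *depth*) below the surface,
   in slices or micrometres. Integer slices are selected by
   ceil(lower) ≤ z < ceil(upper), so adjacent layers — epidermis at
   offset 0, mesophyll a few slices deeper — tile each column with no
   voxel counted twice.
3. **Rendering and quantification.** Peeled layers are rendered as Z-sum
   (or maximum) projections and summarized per channel as voxel count,
   total and mean intensity. Sum projections conserve the masked voxel
   total exactly.

Phenotype helpers implement the standard closed forms: stomatal index
SI = 100 · stomata / (stomata + epidermal cells); stomatal density
SD = stomata / mm²; relative expression by the ΔΔCt method,
2^−((Ct_target − Ct_ref)_condition − (Ct_target − Ct_ref)_calibrator);
and dual-luciferase normalization firefly / Renilla.

A ground-truthed phantom generator (`simulateStack()`) emulates the
two-tissue geometry — smooth surface, bright epidermal shell, deeper
mesophyll, noise — so every stage is testable without real acquisitions.

## Worked example

```r
library(PeelStack)

spec <- phantomSpec(surfaceModel = "flat", baseDepth = 5,
                    shape = c(25L, 128L, 128L), seed = 7)
sim <- simulateStack(spec)          # reporter means: 80 (epi), 40 (meso)
hm  <- extractSurface(sim$stack)    # detect -> fill gaps -> regularize

epi <- makeLayerMask(sim$stack, hm, PeelSpec(offset = 0, depth = 4))
mes <- makeLayerMask(sim$stack, hm, PeelSpec(offset = 6, depth = 8))
rbind(cbind(layer = "epidermis", quantifyLayer(sim$stack, epi, 2)),
      cbind(layer = "mesophyll", quantifyLayer(sim$stack, mes, 2)))
#>       layer channel channel_name voxel_count total_intensity mean_intensity
#> 1 epidermis       2     reporter       65536         5243404        80.0080
#> 2 mesophyll       2     reporter      131072         5242020        39.9934
```

The recovered layer means (80.01, 39.99) match the generating reporter
means (80, 40) to within the noise of the phantom: the peel separated
the two tissues cleanly. Count records work the same way:

```r
df <- simulateCounts(5, siTrue = 20, cellsPerRoi = 200, seed = 7)
stomatalIndex(df$stomata, df$epidermal_cells)
#> [1] 21.0 19.0 19.5 20.0 21.0
stomatalDensity(df$stomata, df$roi_area_mm2)   # 400 um x 400 um ROI
#> [1] 262.50 237.50 243.75 250.00 262.50
```

The same pipeline is scriptable from a shell via the installed launcher:

```sh
PEELSTACK=$(Rscript -e 'cat(system.file("scripts", "peelstack", package = "PeelStack"))')
Rscript "$PEELSTACK" simulate --out-prefix phantom --seed 7
Rscript "$PEELSTACK" pipeline --input phantom_stack.tif --out-prefix run \
    --epidermis-depth 4 --mesophyll-offset 6 --mesophyll-depth 8
# -> run_surface.tif, run_{epidermis,mesophyll}.tif + _sum.tif,
#    run_quantify.csv, run.runrecord.json
```

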