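# mmtrack

Automated analysis of mother-machine microscopy time-lapses in R.

The mother machine traps a single "mother" bacterium at the dead end of
each of thousands of microfluidic channels while daughters are pushed out
the open end, making it the workhorse device for single-cell physiology:
growth rate, division timing, gene expression, antibiotic response,
persistence. The images it produces — thousands of frames of brightfield
or phase-contrast data, often with one or more fluorescence planes per
time point — are the bottleneck. `mmtrack` turns a folder of such frames
into a lineage-resolved table of per-cell measurements with no manual
drawing and no fluorescent tag required for detection.

## What the pipeline does

1. **Modality classification.** The uncorrected intensity-histogram
   skewness `G1 = m3 / m2^(3/2)` separates the two transmitted-light
   modalities: positive skew (dark field, sparse bright structures) is
   phase contrast, negative skew is brightfield.
2. **Channel detection.** Channel walls are enhanced with a multi-scale
   Frangi ridge filter (brightfield) or Sobel gradient (phase), binarised
   with Li's minimum cross-entropy threshold, and the wall outlines are
   closed, filled and subtracted to give channel interiors. Interiors are
   filtered by axis length (100–400 px by default) and width, the
   channel pitch is estimated, missing channels are interpolated on the
   pitch grid, and the average channel shape is stamped into each
   interpolated or badly-eaten position. Everything length-like scales
   with a single `scale_factor` for other magnifications. Works on
   tilted devices; frames with fewer than three detected channels are
   skipped with a warning.
3. **Bacteria segmentation.** Per channel: invert, subtract a
   rolling-ball background, filter with a scale-normalised
   Laplacian-of-Gaussian stack, binarise at one frame-level Li threshold
   (so empty channels stay empty), split touching cells with a
   marker-controlled watershed, then refine with two robust stages —
   merging regions whose interface shows no dim gap, and splitting
   regions where skeleton width *and* intensity drop below
   median − k·MAD cuts together.
4. **Tracking.** The global frame shift comes from FFT cross-correlation;
   channels link by mutual nearest neighbours and keep stable ids.
   Bacteria within each channel are tracked by scoring every
   order-preserving combination of {persist, divide, lyse, enter} events,
   each cell contributing area-change × centroid-displacement × event-prior
   probabilities; the most probable combination relabels the cells, with
   division children and new cells assigned fresh lineage ids.
5. **Quantification.** Per cell and frame: length and width
   (second-moment ellipse axes), area, and per fluorophore the mean
   intensity minus the background measured in the empty parts of the same
   channel, written as CSV.

A synthetic time-lapse generator with complete ground truth
(`mm_generate_series()`) and the standard evaluation metrics (precision /
recall / Jaccard, detection efficiency and accuracy, tracking efficiency)
make the whole chain testable without external data.

## Worked example

Simulate a four-frame brightfield series (8 channels, one fluorescence
plane, one division scheduled in channel 2 at frame 3) and analyse it:

```r
library(mmtrack)

spec <- mm_fixture_spec(n_frames = 4, seed = 11, n_fluo = 1,
                        division_schedule = data.frame(channel = 2, frame = 3))
series <- mm_generate_series(spec)
series
#> mm_fixture_series: 4 frames of 230x400 px, 8 channels, brightfield, 18 cell tracks

result <- mm_analyze(series)
result
#> mm_result: brightfield, 4/4 frame(s) analysed, 18 track(s), 66 measurement row(s)

head(result$measurements[, c("frame_index", "channel_id", "global_id",
                             "parent_id", "event", "length_px", "area_px",
                             "fluo1_mean")], 8)
#>   frame_index channel_id global_id parent_id     event length_px area_px fluo1_mean
#> 1           1          1         1        NA       new  29.39253     174   77.95781
#> 2           2          1         1        NA no-change  31.10866     184   78.10900
#> 3           3          1         1        NA no-change  33.02387     198   77.35480
#> 4           4          1         1        NA no-change  35.51758     203   76.14626
#> 5           1          1         2        NA       new  19.64516     114  122.61680
#> 6           2          1         2        NA no-change  21.76552     136  122.24873
#> 7           3          1         2        NA no-change  23.71174     149  122.49543
#> 8           4          1         2        NA no-change  26.06988     161  119.80454
```

Each row is one bacterium at one time point. `global_id` is the stable
lineage id: cell 1 grows from 174 to 203 px² over four frames while its
background-subtracted GFP-like signal stays near its programmed level
(~78 a.u. over a background of 10). The scheduled division appears as two
rows with `event = "division"` sharing a `parent_id`; a lysing cell's last
row carries `fate = "lysis"`. `mm_export_csv(result, "area01.csv")`
writes the fixed-schema CSV.

Real data goes through the same interface: name the files
`<area>_YYMMDD_HHMMSS.tiff` (e.g. `Area01_171016_123301.tiff`), then

```sh
Rscript inst/scripts/analyze.R /path/to/folder --n-fluo 1 --output results/
```

indexes the folder by area, analyses each area's time series and writes
one CSV per area. `inst/scripts/make_fixtures.R` writes a synthetic
series as protocol-named TIFFs with ground-truth labels, and
`inst/scripts/evaluate.R` scores a pipeline run against that truth.

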