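# deckpipe

Video-based counting and landmarking of crabs and lobsters from deck
cameras on fishing vessels.

## The problem

Crab and lobster stocks are largely data-poor: size and catch-composition
data are expensive to collect with onboard observers or port sampling.
Electronic monitoring offers a cheap alternative — a camera over the
sorting area records fishers presenting each animal — but raw footage
must be turned into *one record per animal* (species, representative
frames, body landmarks) on low-power onboard hardware, where even
"lightweight" deep models barely fit. The central difficulty is
temporal: a cheap per-frame presence classifier emits a volatile
confidence stream, and a naive frame-by-frame count would measure the
same animal many times.

`deckpipe` implements the full offline pipeline for this setting, for
fisheries scientists and computer-vision engineers who need a testable,
dependency-light reference:

1. **Scheduling** — a GPS rule decides when the device records
   (fishing: speed < 4 knots) and when it processes (travelling or
   docked: speed ≥ 4 knots, or within a port geofence).
2. **Temporal segmentation** — the per-frame confidence signal
   `S` is smoothed with a rectangular (box) window,

   `f(n) = (1/m) Σ_{i = n-⌊m/2⌋}^{n+⌈m/2⌉-1} S_i`,

   with out-of-range indices taken as zero, then hard-thresholded;
   two smooth→step passes (window 20 / threshold 0.01, then window 10 /
   threshold 0.5) turn the stream into maximal runs of 1s — "contigs",
   one per presented animal.
3. **Frame selection** — a small per-view CNN scores every in-contig
   frame for "representativeness" (centrality, scale, blur, occlusion);
   the per-contig, per-view argmax is shortlisted
   (5 contigs × 2 views = 10 frames).
4. **Detection and cropping** — a pluggable object detector localises
   the animal on the *unresized* selected frame; a dataset-wide
   fixed-size window (mean detected box dimensions, even-rounded) is
   cropped by pure translation. Nothing on the measurement path is ever
   resampled.
5. **Keypoints** — a small CNN regresses the 7 named landmarks
   (`crab_left`, `crab_right`, `left_eye`, `right_eye`, `carapace_end`,
   `tail_end`, `last_segment`) in crop pixels; accuracy is summarised
   as Mean Euclidean Error (px) and as a percentage of the mean
   ground-truth box diagonal.

A seeded synthetic deck-video generator (elongated two-tone blobs with
known pose, view texture, boxes, keypoints and quality labels) provides
full ground truth, so every stage — including training both reference
CNNs — runs and is tested entirely offline. See the methods vignette
(`vignettes/deckpipe-methods.Rmd`) for model details and design choices.

## Worked example

```r
library(deckpipe)

sched <- random_event_schedule(5, min_len = 50, max_len = 90,
                               min_gap = 60, max_gap = 100, seed = 2)
vid <- generate_video(sched, signal_noise_model(jitter_sd = 0, seed = 2),
                      image_size = c(128, 72), seed = 2)
rep <- run_pipeline(vid, pipeline_config(classifier = "intensity", seed = 2))
rep
#> <pipeline_report> 803 frames -> 5 contigs -> 5 records
rep$records[, c("contig_id", "class_label", "selected_top",
                "selected_underside")]
#>   contig_id class_label selected_top selected_underside
#> 1         0        crab          101                102
#> 2         1        crab          244                245
#> 3         2     lobster          391                392
#> 4         3     lobster          522                523
#> 5         4     lobster          661                662
profile_run(rep)
#>        stage frames seconds       fps
#> 1 classifier    803   0.006 133833.33
#> 2   selector    425   0.009  47222.22
#> 3   detector      5   0.001   5000.00
#> 4  keypoints      5   0.001   5000.00
evaluate_contigs(rep$contigs, sched)$success_rate
#> [1] 1
```

Five presentation events become exactly five contigs (a 100% success
rate: each contig encompasses exactly one animal), two shortlisted
frames per contig (top and underside views), one species call per
record, and a 7-landmark keypoint set per detected animal, e.g.

```r
round(unclass(rep$records$keypoints[[1]]), 1)
#>                 x    y
#> crab_left    -4.1 13.6
#> crab_right   21.5 13.0
#> left_eye      5.2 -1.0
#> right_eye    11.6 -1.1
#> carapace_end  9.1 29.3
#> tail_end      9.3 37.3
#> last_segment  9.2 33.3
```

(coordinates in crop pixels; `crab_left`/`crab_right` span the carapace
width used to size crabs). The per-stage frame counts show the design
point: the cheap classifier touches all 803 frames, the scorer only the
425 in-contig frames, and the expensive detector and keypoint models
exactly once per animal.

## Command line

```sh
Rscript inst/cli/deckpipe.R simulate --events 5 --seed 2 --out video_dir
Rscript inst/cli/deckpipe.R segment --in video_dir/signal.csv --out contigs.csv
Rscript inst/cli/deckpipe.R run --video video_dir --out pipeline_out
Rscript inst/cli/deckpipe.R evaluate --contigs contigs.csv \
    --schedule video_dir/schedule.csv --frames 803
```

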