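---
title: "Counting broomrape tubercles by calibrated colour thresholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting broomrape tubercles by calibrated colour thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizocount)
```

## The measurement problem

Sunflower broomrape (*Orobanche cumana*) is an obligate root parasite whose
infection severity is scored, three to four weeks after inoculation, by
counting the orange storage organs — tubercles — it forms on the host root
system. Rhizotron culture makes the roots visible against white glass-fibre
paper, so an imaged root system contains essentially three colour
populations: near-white paper, near-white roots, and orange tubercles.
`rhizocount` turns that colour contrast into an automatic count: it is the
kind of measurement a phenotyping platform needs when a resistance screen
produces hundreds of images per experiment and manual counting (roughly a
minute per image) becomes the bottleneck.

## The pipeline

Counting one image is a fixed five-step chain, exposed both as individual
functions and as `count_tubercles()`:

1. **Scale calibration** (`calibrate_scale`). A ruler imaged beside the
   rhizotron gives pixels-per-millimetre; with the reference camera geometry
   1100 px correspond to 50 mm, i.e. 22 px/mm. All downstream areas are in
   mm² so results do not depend on image resolution.
2. **Crop** (`crop_image`). An axis-aligned region of interest restricts
   analysis to the inoculated zone and removes the most common false-positive
   sources (rockwool at the bottom, stem base at the top).
3. **HSB threshold** (`rgb_to_hsb`, `threshold_hsb`). Pixels are converted to
   8-bit hue/saturation/brightness and kept when all three channels fall
   inclusively inside a band. The default orange-tubercle band is
   H 0–55, S 102–255, B 95–255: white paper and roots fail the saturation
   gate, green or grey debris fails the hue gate.
4. **Hole filling** (`fill_holes`). Specular highlights inside a tubercle
   punch holes in the binary mask; any background region not 4-connected to
   the image border is filled so a tubercle is measured at its full area.
5. **Particle analysis** (`find_particles`). 8-connected components are
   measured (pixel area, area in mm², binary centre of mass, bounding box)
   and filtered to the inclusive size band 0.05–20 mm². Components below the
   floor are sensor noise; above the ceiling they are stem fragments or
   merged debris.

A second colour band (e.g. a brown, low-brightness band) can be added to the
configuration to count necrotic tubercles — the post-haustorial resistance
phenotype — as a separate class; the default configuration counts only the
orange class.

```{r single-image}
cfg <- pipeline_config(
  calibration = scale_calibration(22),
  bands = list(tubercle = hsb_range(0, 55, 102, 255, 95, 255)),
  size = size_range(0.05, 20))
scene <- generate_rhizotron_image(
  scene_params(canvas_px = c(600, 440), n_tubercles = 10,
               radius_range_mm = c(0.3, 1.2), seed = 1), "demo")
particles <- count_tubercles(scene$image, cfg, image_id = "demo")
attr(particles, "counts")
head(as.data.frame(particles)[, 1:6])
```

### Numerical conventions

Published macro parameters pin the band and size values, but several
numerical details are conventions of this implementation:

* **Byte mapping.** Hue in degrees maps to bytes by `round(deg * 255/360)`;
  saturation and brightness fractions by `round(frac * 255)`. Band endpoints
  are inclusive. No attempt is made at bit parity with any particular
  desktop tool build; a ±1 difference at a band edge is possible against
  other converters and is irrelevant at the published band widths.
* **Connectivity.** Foreground is 8-connected and background 4-connected —
  the standard dual pairing. Diagonally touching blobs therefore merge,
  which is exactly the behaviour that makes very close tubercles count as
  one particle.
* **Order of operations.** Holes are filled *before* the size filter, so a
  ring-shaped detection is judged by its filled area.
* **Size bounds** are inclusive at both ends: a particle of exactly 0.05 or
  20 mm² is kept.
* **Hue wraparound** is supported (`h_min > h_max` passes through the
  255→0 seam) so red-centred bands remain expressible, although the default
  band does not wrap. Achromatic pixels take hue 0.
* **Coordinates.** Pixels are 0-based with the origin at the top-left
  corner; centroids are unweighted (binary) centres of mass, reported in mm
  relative to the crop origin and additionally in original-image pixels.
  The centre of mass is binary rather than intensity-weighted because the
  count, not the photometry, is the measurand.
* **Particle ids** follow raster order of each component's first pixel, so
  numbering is deterministic across runs and platforms.
* **Degenerate inputs.** An empty mask yields an empty particle table;
  recall/precision with empty denominators are reported as `NaN`, never as
  zero-divides; a constant count vector yields `NA` correlation.

## Batch processing and manual correction

`process_directory()` is the unattended workflow: images are processed in
lexicographic order under one configuration, each yielding a particle CSV,
and a summary table (`image_id, tubercle_count, necrotic_count, corrected`)
is written last. Unreadable files are logged and skipped rather than
aborting a run. Floating-point CSV values are rounded to 6 decimals so
repeated runs are byte-identical.

`apply_corrections()` mirrors semiautomatic counting: delete points remove
at most one particle each (bounding-box containment first, else nearest
centroid within 2 mm — the resolution of a click falling between two close
particles is a convention of this package), and add points append
`manual_added` particles that carry a count but no measured area, because a
manual addition is a count correction, not a segmentation edit.

## Evaluation against reference annotations

`match_particles()` performs one-to-one greedy matching by ascending
centroid distance, accepting pairs within a tolerance (default 2 mm, about
one tubercle radius at 22 px/mm); ties break on the lower automatic id,
then lower truth id, keeping results deterministic. Greedy matching rather
than optimal assignment is deliberate: it is transparent, O(n² log n), and
at the densities involved (≤ ~100 objects per image with centimetre-scale
spacing) it differs from the optimal matching only in contrived
configurations. Matched pairs are true positives; unmatched reference
objects false negatives; unmatched detections false positives. How a human
decides that a manual mark and an automatic particle are "the same
tubercle" is inherently visual, so the distance rule is a stand-in and is
labelled as such in every report.

`agreement_stats()` computes the two count-level figures used to summarise
manual-versus-automatic agreement: the Pearson product-moment correlation
of per-image counts and the least-squares trend line through the origin,
$b = \sum x_i y_i / \sum x_i^2$ with the reference count as $x$.
`evaluate_experiment()` (and `run_benchmark()`) aggregate per-image matching
into mean ± sample-sd recall and precision, with the number of images over
which each statistic is defined reported alongside — zero-truth images have
undefined recall and are excluded from that average but kept in the pooled
count correlation.

## The synthetic rhizotron generator

No raw rhizotron images are distributed, so verification rests on a seeded
generator (`generate_rhizotron_image()`) that emulates the imaging
conditions and, crucially, the four documented failure modes of
colour-threshold counting:

* **pale tubercles**: saturation drawn in 30–95, below the band's 102 floor
  — missed for the documented reason (colour, not geometry);
* **necrotic tubercles**: brightness 30–90, below the 95 floor, hue 8–30 —
  invisible to the default band but countable by a second brown band;
* **touching clusters**: pairs placed at 0.8× the sum of radii so their
  masks merge into a single 8-connected particle;
* **distractors**: in-band blobs in a rockwool strip along the bottom plus
  an optional stem-base blob — rendered but absent from the ground truth,
  so they surface as false positives.

Orange tubercles draw hue in 5–40, saturation 150–255 and brightness
110–240 — strictly inside the band. Because the colour model and the band
are consistent by construction, a clean scene (all confound fractions zero,
no distractors) must be recovered with recall = precision = 1, and the test
suite asserts exactly that; conversely each confound perturbs exactly one
error channel, which the property tests check monotonically.

Rendering choices that matter numerically: tubercles are ellipses of equal
area to a nominal radius (aspect 0.8–1), drawn with a ~1 px anti-aliasing
ramp centred on the outline so the thresholded area tracks πr² within a
fraction of a pixel — without this, the smallest (0.15 mm) tubercles would
drift below the 0.05 mm² floor and the largest (2.5 mm) above the 20 mm²
ceiling through edge effects alone. Necrotic tubercles are drawn hard-edged:
an anti-aliased rim blended against the bright background would pass
through the band (saturation rising, brightness falling through the gate
window) and create a detectable ring artefact that real necrotic tubercles
do not have. The default canvas is 2634 × 1824 px at 22 px/mm — the
reference crop geometry — so pipeline configurations transfer between real
and synthetic images unchanged.

The generator's realism is deliberately limited: no photorealistic texture,
no root-architecture biology, no lighting gradients, no necrosis dynamics,
no camera optics. Passing the synthetic benchmarks therefore shows that the
measurement chain is correct and robust to the *modelled* confounds; it
does not certify performance on real images, whose colour distributions
must still be checked when fixing a band for a new experiment.

`generate_experiment()` scales this to designs with per-scenario count
distributions: susceptible lines draw counts from a truncated normal
(mean 45, sd 6 by default, matching reported infestation of a susceptible
genotype), an intermediate scenario from mean 15 ± 5, tolerant lines
uniformly from 0–4, and resistant lines are exactly zero. One master seed
feeds a stream from which two sub-seeds per image (count draw, scene
rendering) are taken up front, so extending a design never changes earlier
images.

## Benchmarks and problem sizes

Two standing benchmarks, used by both the test suite and
`scripts/acceptance.R`, emulate the two published agreement analyses:

* **Single-line benchmark** (`design_single_line()`): 19 full-resolution
  images of one susceptible line, true counts uniform in 10–80, confounds
  pale 5%, clusters 8%, two rockwool distractors per image. Reported:
  count correlation, mean recall, mean precision (2 mm tolerance). The
  published values these must meet as lower bounds are r = 0.83,
  88% and 83%.
* **Genotype panel** (`design_genotype_panel()`): four scenarios × five
  rhizotrons (susceptible, intermediate, tolerant, resistant) with the same
  confounds, including genuinely empty images. Reported: pooled count
  correlation, which must reach the published 0.94. The resistant images
  reproduce a known behaviour of threshold counting: with nothing real to
  find, every distractor detection is a false positive, which is exactly
  why per-genotype correlations were lowest for resistant material.

Unit tests run on ~600 × 440 px canvases with 6–10 tubercles for speed;
the acceptance tests and script run the full 2634 × 1824 geometry (about
seven seconds per image), which keeps the complete verification run in the
minutes range on one CPU.

## Known limitations

* The band is global per run; staining, lighting drift or camera changes
  require re-deriving it on a few images, exactly as in interactive use.
* Merged clusters are counted as one particle by design; separating them
  would need shape analysis or learning-based methods, both out of scope.
* Manual additions carry no area, so area statistics exclude corrected
  particles.
* The matching tolerance (2 mm) is a convention; reported agreement
  percentages move with it, which is why every report embeds the rule used.
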