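# fiberseg

Quantitative histology of skeletal-muscle cross-sections from
immunofluorescent images, as a scriptable R package with a command-line
interface. It addresses the routine but laborious measurements of muscle
physiology and muscular-dystrophy research — fiber size distributions,
fiber-type proportions, centrally nucleated fiber (CNF) prevalence, and
capillary density — on sections where a membrane stain (laminin) outlines
each fiber, DAPI marks nuclei, and further channels carry a fiber-type
(e.g. slow myosin heavy chain) or object (e.g. PECAM) stain.

## Method

All analyses rest on one segmentation of the fiber outlines. Let *I* be
the outline channel (8-bit). Shallow regional minima — noise basins that
make the watershed over-segment — are removed by **h-minima suppression**:
every regional minimum whose depth relative to its lowest surrounding
saddle is below *h* (default *h* = 5) is filled to its overflow level,
while deeper minima are kept untouched. The **watershed transform** (Meyer
flooding, 8-connectivity) of the smoothed image then assigns every pixel a
fiber label or 0 on a ridge line. Non-fibers are removed by four rules in
fixed order: edge contact, area outside [100, 5000] µm² (area =
pixel count × `pixel_size`², default 0.645 µm/px), **eccentricity**
> 0.95 (second-moment ellipse: 0 = circle, 1 = line), and **convexity**
(solidity, region area / pixel-corner convex-hull area) < 0.8, which
rejects stellate interstitial space. Interactive editing is replaced by
files: separation polylines (JSON) cut merged fibers; removal lists delete
labelled objects.

Per fiber, the package reports centroid, cross-sectional area (CSA), and
the **minimum and maximum Feret diameters** with the minimal-caliper
direction, computed by rotating calipers on the pixel-corner convex hull
(the minimum Feret diameter is the standard section-angle-robust fiber
size measure). Fiber typing thresholds the per-fiber mean stain intensity,
initialized by **Otsu's method** and adjustable; CNFs are called when
thresholded nuclear staining of at least 5 µm² lies deeper than 10 µm from
the fiber border (exact Euclidean distance transform); the object counter
reports count, areas and centroids of 8-connected thresholded components.
A ground-truthed synthetic section generator (Lloyd-relaxed Voronoi fibers
with membrane band, type fill, nuclei and capillary-like dots) makes every
stage testable without slide images.

## Worked example

```r
library(fiberseg)

spec <- section_spec(size = 512, n_fibers = 60, noise_sd = 0,
                     n_objects = 20, seed = 42)
sec <- generate_section(spec)
#> <synthetic_section> 512 x 512 px, 60 fibers (33 interior), 20 objects, seed 42

params <- default_params()             # published defaults (Table-style)
mask <- initial_segmentation(sec$image, params)
filt <- filter_fibers(mask, params)
#> <fiber_filter> 60 objects in, 33 fibers kept
#> rejected
#> edge
#>   27

props <- fiber_properties(filt$mask, params$pixel_size)
summarize_fibers(props)["mean", c("min_feret", "area_um2")]
#>      min_feret area_um2
#> mean  43.33082 1779.402

classify_fiber_types(filt$mask, get_channel(sec$image, "type"),
                     params$pixel_size)
#> <typing_result> 33 fibers, threshold 10.5 (Otsu), 30.3% positive

cnf_analysis(sec$image, filt$mask, params)
#> <cnf_result> 33 fibers, 30.3% CNF (nuclear threshold 8.5)

count_objects(get_channel(sec$object_image, "object"),
              params$object_smoothing, params$pixel_size)
#> <object_table> 20 objects, threshold 5.5
```

All 27 rejected objects are edge-clipped partial fibers; the 33 kept
fibers average 1779 µm² CSA and 43.3 µm minimum Feret diameter. The Otsu
threshold (10.5) separates the 10 type-positive fibers (30.3 %) the
generator planted; CNF calls (30.3 %) and the object count (20) also match
the ground truth exactly.

The same pipeline from the shell:

```sh
exec/fiberseg synth --seed 42 --size 512 --n-fibers 60 --outdir out
exec/fiberseg all --image out/synthetic.png --outdir out --with-type --with-cnf
```

which writes `*_Mask.tif`, `*_Props.csv`, `*_FiberType.csv`, `*_CNF.csv`
and a `fiberseg_run.log` recording every parameter and every threshold
actually used (re-run with `--threshold` to adjust).

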