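# endodomain

Quantification of protein microdomains on the limiting membrane of large
endosomes, as imaged in *C. elegans* coelomocytes — scavenger cells whose
unusually large (1–5 µm) endosomes make it possible to resolve segregated
coat-protein patches (recycling microdomains marked by RME-8/SNX-1,
degradative microdomains marked by ESCRT-0/HRS) by ordinary fluorescence
microscopy. The package is aimed at cell biologists who need reproducible,
scriptable versions of the measurements usually done by hand in
acquisition software, plus a ground-truthed synthetic-image generator to
validate every measurement by parameter recovery.

## What it computes

Let `I(x)` be a channel's intensity and `T` a threshold (user-supplied, or
Otsu's maximum between-class-variance threshold by default; "above
threshold" is strict `>` everywhere).

- **Microdomain spread** — a circumferential line scan samples `I` by
  bilinear interpolation at the nominal radius of an endosome ring;
  `spread = #{samples: I > T} / n_samples`, averaged over ≥3 endosomes per
  cell. This is the fraction of the endosome circumference the microdomain
  occupies.
- **Membrane/cytoplasm ratio** — `mean(per-disc mean I over 3 on-endosome
  discs) / mean(same over 3 off-endosome discs)`, with 3-µm-diameter
  measurement discs; reported linear and log2.
- **Interior/peripheral ratio** — the cell disc is split into two
  equal-area regions (interior disc of radius `R/√2`, peripheral annulus);
  `log2( Σ I[I>T] interior / Σ I[I>T] peripheral )`. On this scale 0 means
  equal intensity, +1 a two-fold interior excess, −1 a two-fold peripheral
  excess.
- **Thresholded Pearson colocalization** — Pearson `r` between two
  channels over pixels above threshold in either channel (union rule;
  intersection/all available).
- **FRAP** — double normalization
  `F(t) = [(B(t)−bg)/(R(t)−bg)] / prebleach mean`, then least squares for
  `F(t) = F₀ + (plateau−F₀)(1−e^(−t/τ))` with `F₀` fixed to the first
  post-bleach value; reports mobile fraction `(plateau−F₀)/(1−F₀)` and τ.
- **Fiber length** — per connected component: Zhang–Suen skeleton, path
  length as the minimum-spanning-tree sum of inter-pixel steps (1 px
  orthogonal, √2 diagonal) × pixel size.
- **Cell area** — thresholded-mask pixel count × pixel size².
- **IWN homolog curation** — scans protein sequences for the four-residue
  IWN repeat `[ILV] W ζ ζ` (ζ = hydrophilic: S,T,N,Q,D,E,K,R,H), filters
  BLAST hit tables at coverage > 40 % and e-value < 1e-3 (both strict),
  and calls a hit a homolog candidate iff it passes the filter and carries
  ≥ 3 repeats.

The `synthetic_data` functions generate disc-shaped coelomocyte scenes
(cytoplasm, dark nucleus, peripheral endosome rings carrying angular
microdomain arcs of known coverage), FRAP series with known mobile
fraction and τ, planted-motif FASTA fixtures, and hit tables with a known
pass count — so every metric above is tested by recovering the parameters
that generated the image.

## Worked example

```r
library(endodomain)

sp <- scene_spec(
  image_shape = c(256L, 256L), pixel_size_um = 0.1,
  cell_radius_um = 12, nucleus_radius_um = 3,
  cytoplasm_intensity = 100, background_intensity = 10,
  noise_sd = 15, seed = 42L,
  endosomes = list(
    endosome_spec(60, 127.5, radius_um = 1.5, ring_width_um = 0.4,
                  ring_intensity = 150, arc_center_deg = 0,
                  arc_coverage = 0.3, arc_intensity = 400),
    endosome_spec(160, 60, radius_um = 1.2, ring_width_um = 0.4,
                  ring_intensity = 150, arc_center_deg = 120,
                  arc_coverage = 0.3, arc_intensity = 400),
    endosome_spec(170, 180, radius_um = 1.8, ring_width_um = 0.4,
                  ring_intensity = 150, arc_center_deg = 250,
                  arc_coverage = 0.3, arc_intensity = 400)))
scene <- generate_coelomocyte(sp)
img <- scene$channels[[1]]

profs <- lapply(scene$truth$endosome_rois,
                function(r) circle_profile(img, r))
microdomain_spread(profs, threshold = 275)
#> <spread_result> fraction above threshold 0.2971 (threshold 275 AU, 3 endosomes)

discs <- place_measurement_discs(img, scene$truth$cell,
                                 scene$truth$endosome_rois, seed = 42L)
membrane_cytoplasm_ratio(img, discs$on_discs, discs$off_discs)
#> <ratio_result> ratio 1.284 (log2 0.3609), num 128.3, den 99.93, n = 6

interior_peripheral_ratio(img, scene$truth$cell, threshold = 125)
#> <ratio_result> ratio 2.011 (log2 1.008), num 3.441e+05, den 1.711e+05, n = 2

fit <- fit_recovery(normalize_frap(extract_frap_curve(generate_frap_series(
  frap_spec(mobile_fraction = 0.7, tau_s = 10, noise_sd = 2, seed = 42L)))))
fit
#> <frap_fit> mobile fraction 0.7001, tau 10.01 s, SSE 3.23e-05

scan_iwn("MSLWDNAAIWTTQQVWSEK")
#>   position window
#> 1        3   LWDN
#> 2        9   IWTT
#> 3       15   VWSE
```

Reading the output: the measured spread 0.297 recovers the generated arc
coverage 0.3 to within angular pixelation; the membrane/cytoplasm ratio
1.28 reflects the on-disc mix of bright ring and cytoplasm pixels against
pure cytoplasm (99.9 ≈ 100 AU, the generated level); all three endosomes
sit in the interior equal-area region, giving a two-fold interior excess
(log2 ≈ +1); the FRAP fit recovers the generated mobile fraction 0.7 and
τ = 10 s from a noisy series; the scanner reports all three IWN windows.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/endodomain.R", package="endodomain"))')
Rscript $CLI simulate cell --config scene.yaml --seed 1 --out run1
Rscript $CLI measure spread --image run1/scene.txtimg --rois run1/rois.csv \
        --config measure.yaml --out spread.csv
Rscript $CLI iwn scan --fasta proteins.fasta --out iwn_hits.tsv
```

Images travel in a lossless plain-text format (`.txtimg`); ROIs and
results as CSV; sequences as FASTA; hit tables as TSV; configuration as
YAML or JSON.

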