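# phasorflim

Phasor and lifetime analysis of NAD(P)H fluorescence lifetime imaging
(FLIM) in R.

Metabolic imaging reads the balance between free and enzyme-bound NAD(P)H
from the coenzyme's autofluorescence decay: the free form lives
~0.4 ns, the enzyme-bound form ~3.4 ns. `phasorflim` is for microscopists
and image analysts working with time-correlated single photon counting
(TCSPC) FLIM data who want both standard quantification routes in one
tested toolbox:

* **Time-domain fitting** — per-pixel single/double-exponential
  Levenberg–Marquardt fits of the photon histogram after 3×3 spatial
  binning and 20 000-photon gating, with nested F-test model selection
  and the amplitude-weighted mean lifetime
  τ<sub>m</sub> = (A₁τ₁ + A₂τ₂)/(A₁ + A₂).
* **Phasor analysis** — the model-free transform
  g = ∫F cos(ωt)dt / ∫F dt, s = ∫F sin(ωt)dt / ∫F dt at
  ω = 2π·100 MHz over one excitation period, instrument-response
  correction by complex division with an IRF phasor referenced from the
  brightest pixel, and projection of each pixel onto the free↔bound axis
  to obtain the bound NAD(P)H fraction
  f = A₂τ₂/(A₁τ₁ + A₂τ₂) ∈ [0, 1].
* **Compartment analysis** — background thresholding (Otsu or manual),
  nuclear ROI rasterization with the cytoplasm as secondary object,
  photobleaching correction b = mean frame intensity / first frame,
  normalization to same-replicate vehicle controls, and the
  concentration proxy intensity/τ<sub>m</sub>.
* **Experiment statistics** — interaction-gated factorial ANOVA (type II,
  or type III under sum-to-zero contrasts when interactions are
  significant) and Tukey-adjusted pairwise comparisons over
  field-of-view summaries.
* **A synthetic TCSPC simulator** with exact photon conservation and
  known ground truth, so every stage is validated without external data.

## Worked example

Simulate a field whose cytoplasm is an equal-amplitude free/bound mixture
(true bound fraction 3.4/3.8 ≈ 0.895) and whose nucleus is pure free
NAD(P)H, with 5% per-frame photobleaching, then run the full analysis
against the ground-truth masks:

```r
library(phasorflim)

meta <- acquisition_meta(n_bins = 256)   # 256 bins over one 10-ns period
phantom <- field_phantom(shape = c(48L, 48L),
                         photons_per_pixel = c(cytoplasm = 3000, nucleus = 2400),
                         n_frames = 3L, bleach_rate = 0.05,
                         meta = meta, seed = 42)
sim <- simulate_field(phantom)
res <- run_field(sim$cube, sim$truth,
                 run_config(fit = TRUE, max_fit_pixels = 200))
res$summary[, c("compartment", "mean_lifetime", "bound_fraction",
                "raw_intensity", "corrected_intensity", "n_pixels")]
#>   compartment mean_lifetime bound_fraction raw_intensity corrected_intensity
#> 1     nucleus        0.6867        0.08222          2277                2393
#> 2   cytoplasm        1.8150        0.88080          2853                2998
#> 3  whole-cell        1.5837        0.73107          2745                2885
#>   n_pixels
#> 1      240
#> 2   1040
#> 3   1280
res$bleach$factor                      # 0.952: ~5% bleaching, corrected above
res$f_populations$mean_bound_fraction  # 0.895: Gaussian-population image mean
```

The cytoplasmic bound fraction lands on the mixture truth (0.88 pixelwise,
0.895 from the Gaussian-population fit of the histogram), the nucleus sits
near zero, and the cytoplasmic mean lifetime approaches the
amplitude-weighted truth of 1.9 ns. The nuclear τ<sub>m</sub> (0.69 ns)
exceeds the pure-free 0.4 ns because 3×3 binning mixes in perinuclear
cytoplasmic photons — the same blur real data shows.

The phasor-axis calibration itself:

```r
cfg <- transform_config(1e8, meta)
ax <- phasor_axis(tau_free = 0.4, tau_bound = 3.4, cfg)
ax$p1   # g = 0.9406, s = 0.2364  (pure free NADH)
ax$p2   # g = 0.1797, s = 0.3840  (pure bound NADH)
ax$L    # 0.7750 — matches the closed-form axis length
```

A full synthetic treatment experiment (2 cell lines × HER2 inhibition ×
3 metabolic treatments, with rotenone/FCCP/AG825 preset effect
directions) runs with `run_demo_experiment(seed = 42)` and returns field
summaries, the gated ANOVA, Tukey pairs, and sign checks of every preset
effect.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/flim.R simulate --phantom phantom.json --out field/
Rscript inst/cli/flim.R summarize --cube field/cube.tif --mask field/truth_masks.tif --out results.csv
Rscript inst/cli/flim.R demo --seed 42 --out demo/
```

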