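# nvjquant

Quantification of inducible enzyme partitioning and retention at the yeast
nucleus-vacuole junction (NVJ).

When yeast face acute glucose restriction, GFP-tagged HMG-CoA reductase
concentrates in the arc of the nuclear envelope (NE) that contacts the
vacuole. `nvjquant` provides the measurement pipeline for this behaviour,
for microscopists and modellers who need reproducible, testable versions of
what is usually done by hand in Fiji and Prism:

* **Partitioning index** — background-subtract an image by a Gaussian-blur
  duplicate (sigma 5 px), take 5-px-wide line scans across the NE at the
  NVJ and at the antipodal crossing, and form the ratio of the areas under
  the two profiles,
  `ratio = AUC_NVJ / AUC_opposite`;
  cells with `ratio > 2.0` (strictly) are classed as NVJ-partitioned, and
  fields are summarized as percent partitioned.
* **FRAP / FLIP analysis** — double normalization of recovery curves
  `I_norm(t) = (I_wc,pre / I_wc(t)) * (I_frap(t) / I_frap,pre)`, full
  normalization pinning the pre-bleach frame to 1 and the bleach frame to
  0, FLIP normalization `I_FLIP(t) = I_NVJ(t) / I_NVJ,pre`, and one-phase
  exponential fits giving halftimes `t_1/2 = ln 2 / k`.
* **Synthetic ground truth** — a two-channel 16-bit cell renderer (NE ring
  with a known NVJ enrichment, vacuole channel, PSF, Poisson + read noise)
  and a reaction-diffusion-binding simulator of fluorophore kinetics on
  the NE ring driven by the published FRAP (25 s, 500 ms frames) and FLIP
  (50 cycles / 300 s) schedules, so every statistic can be validated
  against known enrichments and rate constants.
* **Growth resumption** — empirical resumption-probability curves after
  glucose replenishment and a hand-implemented two-sample
  Kolmogorov-Smirnov test (direct ECDF walk, asymptotic p-value).

## Worked example

Render a cell with a known 15-fold NVJ enrichment and recover it blind
from the pixels:

```r
library(nvjquant)

spec <- cell_spec(nucleus_center = c(3.2, 3.2),
                  vacuole_center = c(5.5, 3.2),
                  enrichment_factor = 15)
img <- render_cell(spec, imaging_config(rng_seed = 7))
img
#> synthetic_image: 64 x 64 px (0.1 um/px), 1 cell(s)

quantify_field(img)
#>   cell_id  auc_nvj auc_opposite    ratio partitioned
#> 1       1 5581.228     345.6234 16.14829        TRUE
```

The measured ratio (16.1) recovers the true enrichment within about 10%;
the cell is correctly classed as partitioned (`ratio > 2.0`). The same
pipeline applied to a uniform ring returns a ratio of 1 and no call.

Selective retention shows up in simulated FLIP experiments: with NVJ
binding (`k_on = 0.1`/s, `k_off = 0.007`/s, implying ~15-fold steady-state
enrichment) the fitted NVJ halftime exceeds 100 s, while without binding
the same ROI empties in tens of seconds:

```r
demo <- calibrate_demo()
demo$halftime_retained
#> [1] 212.8   # seconds
demo$halftime_free
#> [1] 29.6    # seconds
```

Resumption-time tables are compared with the built-in KS test:

```r
res <- compare_resumption(records, c("wt", "nvj1d"))
res$D; res$p
#> [1] 0.633
#> [1] 2.03e-11
```

A thin command-line wrapper over the same functions is included at
`inst/cli/nvjquant.R` with subcommands `simulate-image`, `quantify`,
`simulate-bleach`, `fit` and `resume`.

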