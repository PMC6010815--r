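# isobarrier

Quantifies reproductive isolation (RI) between two co-occurring flower
colour forms from field and experimental data, for pollination
biologists and speciation researchers working on barrier strength. It
was built for studies of the classic design: flowering phenology
surveys, pollinator foraging observations, reciprocal hand-pollination
(self / intraform / interform / control), and floral reflectance
spectra.

Core quantities, per maternal direction:

- **Phenological RI** — `RI = 1 − S/(S+U)` from shared (`S`) and
  unshared (`U`) flowering time, with inclusive day counting.
- **Per-barrier RI** — `RI = 1 − 2H/(H+C)` from conspecific (`C`) vs
  heterospecific (`H`) success: pollinator transitions, pollen tubes
  entering the ovary, fruit set, large-embryo rates. Bounded in
  [−1, 1]; negative values mean heterospecific advantage. Directional
  **asymmetry** is the absolute RI difference between crossing
  directions.
- **Sequential composition** — barriers in life-history order compose
  into total RI via
  `RI_total = 1 − 2·S·Πh / (S·Πh + 1)` with `h = H/C` per stage, plus
  telescoping absolute contributions `AC_i = RI[1,i] − RI[1,i−1]` and
  relative contributions `RC_i = AC_i / RI_total`.
- **Floral constancy** — Gegear's `CI = (c − e)/((c + e) − 2ce)` with
  `e = p² + (1−p)²` per forager, from plant-to-plant transition
  sequences.
- **Bee colour vision** — colour-hexagon loci of reflectance spectra
  (quantum catches, von Kries background adaptation, excitations
  `E = P/(P+1)`), chromatic distances in hexagon units against a
  0.1-unit just-noticeable-difference threshold.

A synthetic-data generator (`simulation_config()`, `simulate_study()`)
produces complete studies with the statistical structure the analysis
assumes, so everything is testable end to end without field data.

## Worked example

The package ships a published-summary fixture (flowering dates,
pollinator transition counts, crossing summary statistics encoded as
ordinary input files). Running the pipeline on it:

```r
library(isobarrier)
cfg <- system.file("extdata", "paper_fixture", "config.yaml",
                   package = "isobarrier")
res <- run_pipeline(cfg, out_dir = tempfile())
res$barrier_table[, c("barrier", "maternal_form", "ri", "asymmetry")]
#> # A tibble: 10 × 4
#>    barrier     maternal_form      ri asymmetry
#>    <chr>       <chr>           <dbl>     <dbl>
#>  1 phenology   white          0.146     0.0371
#>  2 phenology   pink           0.109     0.0371
#>  3 pollinator  white          0.897     0.374
#>  4 pollinator  pink           0.524     0.374
#>  5 pollen_tube white         -0.0274    0.120
#>  6 pollen_tube pink           0.0924    0.120
#>  7 fruit       white          0.39      0.33
#>  8 fruit       pink           0.0600    0.33
#>  9 seed        white          0.228     0.212
#> 10 seed        pink           0.0165    0.212
res$summary$total_ri_2dp
#> $white
#> [1] 0.97
#> $pink
#> [1] 0.67
```

Reading: the two forms co-flower broadly (phenological RI 0.15/0.11),
pollinators move between forms rarely (RI 0.52 toward pink), pollen
tubes barely discriminate (−0.03: interform tubes slightly *outperform*
intraform ones into white pistils), and fruit/seed stages add moderate
isolation into white. Composed in sequence, isolation toward the white
form is nearly complete (0.97) but much weaker toward pink (0.67); the
pollinator stage contributes the most (absolute contribution 0.77 in
the white direction):

```r
ct <- res$cascade_table
ct[ct$maternal_form == "white", c("barrier", "cumulative_ri", "abs_contrib")]
#> # A tibble: 5 × 3
#>   barrier     cumulative_ri abs_contrib
#>   <chr>               <dbl>       <dbl>
#> 1 phenology           0.146     0.146
#> 2 pollinator          0.912     0.766
#> 3 pollen_tube         0.907    -0.00473
#> 4 fruit               0.958     0.0511
#> 5 seed                0.973     0.0154
```

A fully synthetic study, end to end:

```r
paths <- simulate_study(simulation_config(seed = 1), "study_in")
res <- run_pipeline(list(flowering = paths$flowering,
                         foraging = paths$foraging,
                         crossings = paths$crossings,
                         spectra = paths$spectra,
                         bootstrap = list(B = 2000, seed = 1)),
                    out_dir = "study_out")
```

There is also a thin CLI: `exec/isobarrier simulate|run --config <yaml>
--seed <int> --out <dir>`.

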