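# glossim

A deterministic lattice simulator of tsetse-fly (*Glossina*) movement and
host/bait finding. A cohort of hungry flies diffuses over a grid of
10 m × 10 m vegetation cells, feeds on mapped hosts, artificial baits and
a background of wild hosts, and either feeds, dies, or starves by the end
of its six-day hunger cycle. The package reproduces the published
behaviour of this model class: how habitat geometry (blocks, narrow
bands, bushes) attenuates displacement, how host odour extends a bait's
reach, why hosts aggregated in groups are much harder for flies to find,
and how starvation risk depends on fly mobility and host density.

## The model in brief

* **Movement.** Each step, a fraction `h/4` of a cell's flies attempts a
  move to each orthogonal neighbour (`1 − h` stay). `h = 0.7858` is
  calibrated so the orthogonal lattice walk reproduces the classical
  random-walk mean displacement for 10 m steps over one day (196 steps).
  The map is bordered by mirror-image maps, so edge outflux re-enters.
* **Vegetation.** Cells are good (entry probability 1.0), poor (0.1) or
  no-go (0). A move into a worse cell succeeds with probability
  destination/source; failures return home. At equilibrium, fly density
  is proportional to entry probability (10:1 good:poor).
* **Hunger cycle.** Spontaneous activity rises through the cycle
  (150, 300, 600, 1200, 2400, 1350 steps on days 1–6; 6000 per cycle),
  in alternating 25-step host-searching and general blocks. Background
  mortality is 3 %/day; flies meet wild hosts with per-step probability
  0.00125 × f(day), where the probing response f rises 0.1 → 0.6 over
  the cycle. Flies still unfed at the end of day 6 starve.
* **Baits.** A bait's visual footprint is a block of cells matched to
  host mass (6 m × (m/50 kg)^⅓ radius); its odour plume is a downwind
  triangle with a 26° half-angle and range 90 m × √(m/470 kg). Flies in
  footprint cells during host-searching steps are recruited; a fraction
  f feeds (or is caught), the rest mill about and are re-released
  nearby at the end of the block.

## Worked example

```r
library(glossim)

# movement calibration: the matching step probability and the two
# displacement formulations it reconciles
match_h(10, 196)                        # 0.785767
orthogonal_mean_displacement(10, 196)   # 124.1009 m (h = 1 lattice walk)
classical_mean_displacement(10, 196)    # 124.0718 m (x * sqrt(pi n) / 2)

# habitat attenuates displacement: 1000 steps in a 50 m band vs a
# 200 m block (both flanked by no-go vegetation)
displacement_after(make_band(5), 1000)$mean_displacement_m            # 158.12
displacement_after(make_block(20, outside = "nogo"), 1000)$mean_displacement_m  # 76.655

# starvation on wild hosts only: 2.69 % of a cohort starves per cycle
100 * starved_fraction_wild_only()      # 2.6915

# geometry of bait encounter: at 100 baits per km^2 of good habitat a
# fly is ~40 m from the nearest bait in a block but ~250 m in a 10 m
# band (distances measured through traversable habitat)
nearest_bait_distance(make_block(200), density = 100)                 # 38.531
nearest_bait_distance(make_band(1, serpentine = TRUE), density = 100) # 249.988
```

Higher-level experiment drivers reproduce the published analyses:
`odor_efficacy_experiment()` (six-day crossover catches with and without
odour), `feeding_success()` (cumulative feeding on mapped hosts placed
singly or in groups), `starvation_table()` (starvation probability by
host density, habitat, day and fly mobility) and `target_efficacy()`
(kill rates of insecticide-treated targets).

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "glossim", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`tests/testthat/test-acceptance.R` asserts each published quantity at its
stated tolerance; `scripts/acceptance.R` recomputes every headline number
from scratch and writes them as JSON. The model is fully deterministic —
the seed only feeds the stochastic test oracles. The methods vignette
(`vignettes/glossim-methods.Rmd`) documents the update order, the
calibrations, the habitat conventions, and the few published numbers the
model cannot reconcile (with the analysis of why).

A command-line interface for the main workflows is installed at
`system.file("cli", "glossim.R", package = "glossim")`.
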