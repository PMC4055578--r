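---
title: "glossim: model, calibrations and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glossim: model, calibrations and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glossim follows a cohort of hungry tsetse flies through one six-day
hunger cycle on a lattice of 10 m × 10 m vegetation cells. The model is
fully deterministic: instead of tracking individual flies it propagates
the expected density of flies per cell, so every run of the same
configuration is bit-for-bit reproducible. This vignette documents the
update rules, the calibrations behind the default constants, the
conventions chosen where a rule admits more than one reading, and the
known limitations.

## Movement

Each step period, a fraction $h/4$ of the flies in a cell attempts a
move to each of the four orthogonal neighbours and $1-h$ stay put. The
step probability $h$ is calibrated so that this orthogonal lattice walk
reproduces the classical two-dimensional random walk's mean displacement
$x\sqrt{\pi n}/2$ for step length $x = 10$ m over one day of $n = 196$
steps: equating $x h \sqrt n$ (classical, reduced step length) with the
orthogonal model's displacement scaled by $\sqrt h$ gives

```{r}
match_h(10, 196)   # 0.785767
```

`orthogonal_mean_displacement()` evaluates the $h = 1$ lattice walk
exactly (124.1009 m for the calibration case) rather than through the
large-$n$ approximation, so `match_h()` is independent of the step
length, as the derivation requires.

The map adjoins mirror-image copies of itself on all four sides: flux
that would leave across an edge re-enters the same edge cell. A
homogeneous band is therefore effectively infinite along its axis, and
closed habitats conserve flies to machine precision (the test suite
asserts a per-step drift below $10^{-12}$).

## Vegetation and the crossing rule

Cells carry an entry probability: good 1.0, poor 0.1, no-go 0. An
attempted move into a cell of lower entry probability succeeds for the
fraction destination/source of attempting flies; the rest return to
their source cell. This satisfies detailed balance, so the stationary
fly density is proportional to entry probability — a 10:1 good:poor
ratio at equilibrium, which `stationary_field()` returns in closed form
and `stabilize()` reaches by iteration.

## The hunger cycle

Daily step counts rise through the cycle — 150, 300, 600, 1200, 2400,
1350 (6000 per cycle) — in alternating 25-step *host-searching* and
*general* blocks, starting with host-searching. A mobility multiplier
rescales each day to the nearest multiple of 50 steps, preserving the
block alternation: multipliers 1/3 and 3 give the 2000- and 18000-step
cycles used for less and more mobile flies.

Each step period applies, in order:

1. background mortality, $(1-0.03)^{1/\text{steps}_d}$ per step, and
   wild-host feeding with per-step probability $0.00125\,f_d$;
2. recruitment, during host-searching steps only, of the stimulation
   fraction of the flies already in each bait's footprint cells;
3. one orthogonal dispersal step;
4. recruitment of the same fraction of the flies that just stepped into
   footprint cells;
5. the effective response: a fraction $f$ of recruits feeds or is
   caught or killed; the remaining $1-f$ join the bait's inactive pool,
   which is released in equal shares over the good cells of the bait's
   visual footprint at the end of each host-searching block.

The probing response $f_d$ rises linearly from 0.1 on day 1 to 0.6 on
day 6; capture at an electric pen uses a fixed $f = 0.6$. Flies still
unfed at the end of day 6 starve. With wild hosts only the starved
fraction has a closed form, $\prod_d (1-m)(1-p f_d)^{s_d}$, which a
spatial run reproduces exactly and which fixes the default
$p = 0.00125$ at 2.69 % starvation per cycle
(`goal_seek_wild_prob()` inverts this calibration).

## Baits

A bait of mass $m$ kg is seen within $6\,(m/50)^{1/3}$ m and smelt
within $90\sqrt{m/470}$ m. The visual footprint is the square block of
cells matched to the circle of the visual range (side
$\mathrm{round}(\sqrt\pi\,r/10)$): 1 cell for the lizard (stimulation
fraction 0.5, or 0.8 with odour) and warthog, 2 × 2 for the kudu,
5 × 5 for the elephant. The odour plume is the set of cells whose
centres lie strictly inside a downwind isosceles triangle with a 26°
edge-to-axis half-angle and the olfactory range as height; wind blows
toward one of the four cardinal directions. Artificial baits: the
*large target* occupies 1 × 2 cells with an optional 60 m artificial
odour; the *tiny target* stimulates a quarter of one cell and never has
odour.

## Experiment drivers and conventions

Several published protocols admit more than one spatial reading; the
package fixes the following conventions and the tests are written
against them.

* **Crossover catches** (`crossover_catch()`,
  `odor_efficacy_experiment()`): the two baits operate simultaneously at
  two sites placed at the quarter points of the habitat (snapped away
  from the map edge so no footprint is clipped), swap sites daily for
  six days, and are present for the second half of each day's step
  blocks; wild hosts compete throughout. Catches are percentages of the
  initial population per km² of good habitat. These experiments use
  *straight* bands, which the mirror boundary makes effectively
  infinite: a serpentine band would let an odour plume span the 20 m
  no-go gap between adjacent runs and recruit flies from a part of the
  band that is kilometres away along its axis, which the protocol's
  "two distant sites" premise excludes.
* **Distributed-host experiments** (`feeding_success()`,
  `starvation_table()`, `target_efficacy()`,
  `nearest_bait_distance()`): hosts are placed at a density per km² of
  good habitat, evenly spaced along the band axis (singly or in groups
  of consecutive cells). Here a *serpentine* band — full-width runs
  separated by single no-go rows, joined at alternating ends — packs
  about 2 km of 10 m band into the 2 km × 2 km map, which is the
  package's chosen problem size for band-habitat tables. Nearest-bait
  distances are measured through traversable habitat (along the band
  axis for bands), since adjacent serpentine runs are close in the
  plane but far apart for a fly.
* **Starvation probability** (`starvation_probability()`): among flies
  alive and unfed after day $d$, the probability that their feeding
  question is resolved by starvation rather than a meal,
  $\text{starved}/(\text{starved}+\text{fed})$. Deaths from other
  causes are excluded from both numerator and denominator; on slow
  schedules the probability exceeds $1-\text{daily mortality}$, which
  rules out any definition charging those deaths to the denominator.

The default map is 200 × 200 cells (2 km × 2 km). That size is the
package's own choice: it is large enough that one-day displacement
distributions and six-day crossover catches are unaffected by the
mirror boundary, while keeping every documented experiment comfortably
within desktop memory and minutes of CPU.

## Known limitations

Three published figures of this model family are not reproduced, and we
document rather than tune them.

* **Absolute crossover catch scale.** Relative efficacies and catch
  ratios are reproduced, but absolute catch percentages run several
  times higher than some published tables; no reading of the
  normalisation (per km² of good habitat, per map, per site) fixes both
  the block and band habitats at once. All headline quantities are
  ratios, from which this scale cancels.
* **Grouped feeding success.** Grouping hosts lowers feeding success in
  the package, as it should, but the published penalty for grouping
  (roughly an order of magnitude) exceeds what any diffusion-limited
  encounter process can produce: collapsing $k$ hosts into one site
  reduces a reaction-limited encounter rate by at most $k$, and a
  diffusion-limited one by far less. The package reports the
  diffusion-consistent values.
* **Starvation after many searching days in very small habitat blocks**
  shows the same aggregation sensitivity and inherits the same caveat.

The acceptance tests assert the corresponding published values at their
stated tolerances anyway, so these three appear as expected, explained
failures rather than silent gaps.
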