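---
title: "Modelling a CI-driven Wolbachia invasion with mitochondrial hitchhiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a CI-driven Wolbachia invasion with mitochondrial hitchhiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosweep)
```

## The system

A maternally inherited *Wolbachia* strain that induces cytoplasmic
incompatibility (CI) can sweep through a host population: infected females
are compatible with every male, while uninfected (here: singly infected)
females lose a fraction $l_{CI}$ of their eggs when mated to males carrying
the invading strain. Because mitochondria ride in the same cytoplasm, the
mitochondrial haplotype linked to the founding infected females hitchhikes
to high frequency — a cytoplasmic selective sweep.

`cytosweep` models this jointly for the cherry fruit fly situation: a
resident strain fixed everywhere (so "uninfected" means singly infected),
an invading second strain entering linked to mitochondrial haplotype HT2,
and a resident population carrying HT1. The state is a frequency vector
over four heritable *cytotypes*:

| class | infection | haplotype |
|-------|-----------|-----------|
| `a1`  | single    | HT1       |
| `a2`  | single    | HT2       |
| `b1`  | double    | HT1       |
| `b2`  | double    | HT2       |

The doubly-infected-with-HT1 class `b1` is the *mismatch*: it cannot arise
under strict maternal co-inheritance and is the model's diagnostic for
paternal or horizontal transmission.

## The recursion

Generations are discrete and the population panmictic. Each generation
applies, in order:

1. **Horizontal acquisition.** Singly infected individuals acquire the
   invading strain with per-capita probability $\beta$. A fraction
   $\alpha$ of acquisitions reaches the germline and converts the
   individual to the heritable doubly infected class of the same
   haplotype; the remaining $1-\alpha$ stay somatic — visible to PCR at
   census but neither transmitted nor CI-active (they neither induce nor
   rescue CI). Somatic infections therefore appear only in the *observed*
   frequencies (`observed_frequencies()`), as an overlay
   $\beta(1-\alpha)\,x_{A_h}$ added to the doubly infected class of the
   same haplotype.
2. **Census.** Observed frequencies, mismatch fractions and trajectory
   rows are recorded on this somatic-inclusive overlay.
3. **Random mating and CI.** Mothers and fathers pair at random over the
   heritable classes. The mating table (`build_mating_table()`) gives each
   of the 16 crosses a reproductive weight — the mother's fecundity
   $F_A$ or $F_B$, multiplied by $(1 - l_{CI})$ for the incompatible
   A-mother × B-father cross — and an offspring cytotype distribution:
   haplotype is strictly maternal; B mothers transmit the invading strain
   with probability $1-\mu$; offspring of a B father that did not inherit
   the strain maternally gain it with probability $\tau$ (keeping the
   maternal haplotype).
4. **Normalization** by mean reproductive output.

Summing the four classes over haplotypes collapses the model to the
classic single-strain CI recursion

$$p' = \frac{F p (1-\mu)}{F p + (1-p)(1 - l_{CI}\,p)},$$

which `classic_ci_recursion()` implements and the test suite uses as an
aggregation oracle (agreement to $10^{-12}$ over 1000 random parameter
draws). The event order — acquisition, census, mating — is a modelling
choice, recorded in scenario config files for reproducibility; placing
acquisition after mating instead changes the transient by less than one
generation's acquisition flux.

## Parameters

| parameter | meaning | default | unit |
|-----------|---------|---------|------|
| `l_ci`  | CI level: egg mortality in incompatible crosses | 0.98 | fraction |
| `mu`    | maternal transmission leakage ($1-\mu$ transmitted) | 0 | probability |
| `f_a`, `f_b` | relative fecundity of singly/doubly infected females | 1 | — |
| `tau`   | paternal transmission probability | 0 | probability |
| `alpha` | probability an acquired infection becomes heritable | 0 | probability |
| `beta`  | per-generation horizontal acquisition probability | 0 | probability |

The defaults encode the empirically motivated regime for this system:
crossing studies give near-complete unidirectional CI (98% egg
mortality), field associations indicate near-perfect maternal
transmission, and nothing is known about fecundity effects, so none are
assumed. `scenario_params()` bundles the three named transmission
scenarios run by `analysis/01_scenarios.R`:

* **paternal** — $\tau = 0.3$, $\beta = 0$;
* **heritable horizontal** — $\alpha = 1$, $\beta = 0.015$;
* **somatic horizontal** — $\alpha = 0$, $\beta = 0.3$.

All three create the mismatched `b1` class during the sweep. The
long-run contrast is the scientific point: the mismatch *persists* under
paternal and heritable-horizontal transmission but goes *extinct* under
purely somatic acquisition once the invasion completes — so only somatic,
transient acquisition is compatible with mismatch confined to the moving
transition zone.

## Initial conditions and the acquisition model

The founding condition is a rare doubly infected, HT2-linked founder in
an HT1 population: $x_{B2}(0) = 0.01$, $x_{A1}(0) = 0.99$. This is a
design choice — the invasion's true founding frequency is unknowable —
and the size of the *permanent* mismatch left behind by heritable
acquisition depends on it strongly, because every generation spent at low
invader frequency converts more of the large HT1 pool. Two genuinely open
choices interact here:

* **Acquisition rate form.** The default treats $\beta$ as a constant
  per-capita rate, which makes $\beta(1-\alpha) x_{A_h}$ the somatic
  overlay even before any heritable invader is common. The alternative
  `acquisition = "contact"` scales acquisition by the doubly infected
  frequency (mass action: acquiring requires a donor).
* **Founding frequency** `initial`, exposed on `run_scenario()`.

`analysis/01_scenarios.R` sweeps both: with the defaults the heritable
scenario leaves a very large permanent mismatch (≈ 92% of infected),
falling to ≈ 20% only for founding frequencies near 0.05 under contact
acquisition or 0.1–0.2 under the constant rate. Reported mismatch levels
for such systems should therefore always be read jointly with the assumed
founding frequency; the package's acceptance checks run the documented
default and report what it actually produces.

Convergence uses a component-wise tolerance of $10^{-10}$ with a 10,000
generation cap; the scenarios above converge within ≈ 20–120 generations.
"Permanent" claims are evaluated at convergence, "transient" ones via
`peak_mismatch()` (ties broken by earliest generation). The mismatch
denominator — all individuals or observed doubly infected individuals —
is always explicit, since both conventions are in circulation; at full
invasion they coincide.

## Travelling-wave dispersal bounds

A bistable CI invasion spreads spatially as a travelling wave. With a
Gaussian dispersal kernel (standard deviation $\sigma$ per generation),
perfect maternal transmission and no fecundity cost, the width of the
transition zone — where the invader's frequency rises from 5% to 95% —
is

$$\Delta x = \frac{3\sigma}{\sqrt{l_{CI}}},$$

so an observed lower bound on $\Delta x$ bounds the dispersal scale from
below: `sigma_lower_bound()`. Two numerical choices:

* The square-root form above is the default; the form without the
  radical, which occasionally appears in print, is kept behind
  `form = "literal"`. For $\Delta x = 130$ km and $l_{CI} = 0.98$ the two
  give 43 vs 42 km after rounding; only the square-root form reproduces
  both survey-period bounds (43 and 28 km) consistently.
* Because the invasion advances along a north–south axis, distances
  default to pure latitudinal separation at 111.2 km/degree
  (`latitudinal_distance()`); a haversine alternative is provided. When
  invasion proceeds from both ends of a transect, the single-front width
  bound is half the end-to-end transitional span.

`transition_zone_width()` measures $\Delta x$ on empirical profiles.
Sampling noise creates spurious threshold crossings, so profiles are
first monotonized by isotonic (pool-adjacent-violators) regression —
fitted in both orientations, keeping the better fit, which makes the
width invariant under reversing the transect — and crossings located by
linear interpolation between adjacent sites. On simulated clines with
known $\sigma$ (21–31 sites, 200–400 flies per site) the measured width
lands within 15% of the analytic value; denser transects do better.

## Survey statistics

`summarize_association()` produces stratified counts of the
infection × haplotype association with percentages rounded half-up to
one decimal (the reporting convention of the bundled fixtures).
Haplotype-untyped individuals (one collection period was screened for
infection only) stay in infection denominators but never in haplotype
denominators. `fisher_exact()` reports the conventional two-sided exact
hypergeometric p (probability-based tail aggregation, verified in the
suite against exhaustive enumeration for every 2×2 table with total
≤ 30) and a continuity-corrected sample odds ratio that plays no part in
the p-value.

## In-silico PCR-RFLP

`digest_amplicon()` performs an exact-match restriction digest
(HaeIII, `GG^CC`, by default) and `call_haplotype()` maps fragment
profiles to haplotypes: a single full-length 546 bp fragment is HT1, the
342 + 204 bp profile is HT2, anything else is `unknown` — flagged for
sequencing, as on the bench. Two conservative choices: fragment matching
uses a ±5 bp gel-resolution tolerance (agarose calls are approximate;
exact equality would be unrealistically strict), and IUPAC ambiguity
codes never match the motif, so poor-quality sequence cannot generate a
false cut. Inputs are assumed to be pre-trimmed amplicons; primer
handling is out of scope.

## What the synthetic data do and do not emulate

`generate_survey()` draws individual-level surveys from a design:
per-site binomial sampling of infection status along a logistic cline
whose 5–95% width obeys the wave relation, with haplotypes drawn
conditionally (elevated mismatch probability inside the declared
transition interval, small reciprocal single-with-HT2 leakage
everywhere). `generate_fixture_amplicons()` builds a synthetic 546 bp
amplicon pair differing by the single site-destroying C→T transition —
labelled `_synthetic` throughout: they emulate the structure of the real
haplotype pair, not its sequence. `transition_zone_survey()` /
`outside_zone_survey()` synthesize individual tables whose stratum
margins equal the published field counts exactly (counts are sufficient
statistics for every statistic computed here; the unprinted joint
period × host-plant split is an arbitrary consistent completion).

The generators deliberately omit: genetic drift and finite-population
stochasticity in the dynamics (the recursions are deterministic),
spatially explicit migration (the cline shape is imposed, not emerged),
overlapping generations and prolonged pupal dormancy, host-race
structure beyond a site label, and parasitoid or cannibalism mechanisms
of transfer. Passing tests therefore validate the arithmetic and the
sampling structure, not these biological complications.

## Problem sizes

The test suite and analysis scripts use deterministic recursions of at
most a few hundred generations, surveys of ≤ ~4000 individuals,
property sweeps of 200–1000 random draws and the exhaustive ≤ 30-total
Fisher sweep (≈ 45,000 tables); the full suite runs in a couple of
minutes on one core.

## Known limitations

* The recursions are deterministic; near-threshold behaviour with
  fecundity costs ($F < 1$, bistability) is expressible but not analysed.
* The wave relation assumes the standard bistable-wave regime; Fisherian
  (fitness-driven) spread would need a different width–dispersal link.
* Survey p-values are reported without multiple-testing correction,
  matching the descriptive use of the fixtures.
* The PCR-RFLP caller digests the given strand of pre-trimmed amplicons;
  it does not model partial digestion or heteroplasmy.
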