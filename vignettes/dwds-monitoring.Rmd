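---
title: "Absolute microbiome monitoring of a drinking-water distribution system: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute microbiome monitoring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Relative 16S rRNA gene amplicon profiles cannot distinguish a bloom of one
taxon from a collapse of the others, and they offer no principled way to
remove reagent contamination. `micmon` implements the two ideas that fix
both problems at once:

1. **Internal-calibrator (IC) quantification.** A known quantity of foreign
   genomic DNA — `ic_copies` 16S gene copies per reaction — is spiked into
   every sequencing replicate. Under clonal (micelle-style) amplification
   there is no template competition, so read counts are proportional to
   template molecules and the absolute abundance of OTU $o$ in a replicate
   is

   $$\widehat{c}_o \;=\; \frac{r_o}{r_\mathrm{IC}} \times
     n_\mathrm{IC} \times s,$$

   where $r_o$ and $r_\mathrm{IC}$ are reads, $n_\mathrm{IC}$ is the
   spiked copy number and $s$ (`volume_scale`) converts per-reaction copies
   to copies per 100 µL of source water. The limit of detection of the
   replicate is the copies-equivalent of a single read,
   $\mathrm{LOD} = n_\mathrm{IC}\, s / r_\mathrm{IC}$. A replicate whose
   calibrator received no reads is *invalid* — quantification is undefined
   there and the package never imputes it.

2. **Negative-extraction-control (NEC) subtraction.** Because sample and
   NEC copies are on the same absolute scale, the contamination that
   reagents contribute to every extract can be estimated from NECs
   (calibrated per replicate, averaged per OTU) and subtracted from every
   sample of the same extraction batch (one batch = one month here).

Triplicates are merged by the mean (median available via
`calibration_config(merge = "median")`; with three points the two differ
little and the mean preserves totals), with a consensus rule: an OTU must
be nonzero in at least two valid replicates or it is reset to zero.

## Subtraction near the noise floor

The textbook rule $\max(0, \text{sample} - \text{NEC mean})$ has a blind
spot: for an OTU present *only* in the reagents, sample and NEC carry the
same expected signal, so the residual is symmetric counting noise around
zero and stays positive in roughly half of all replicates at any
sequencing depth. `decontaminate()` therefore applies a one-sided
detection test wherever the NEC contamination $c$ is positive: the
post-subtraction excess must exceed

$$z \sqrt{c \cdot \mathrm{LOD} + \mathrm{LOD}^2},$$

the Poisson standard error of a signal at the contamination level
expressed in copies ($z = 3$ by default, `decontam_z`), or it is censored
to exactly zero. OTUs with no NEC signal are never censored, so genuine
community members are untouched; an OTU whose true abundance is within
counting noise of its reagent background is — correctly — reported as
undetectable. With `lod = 0` (the default argument) the function reduces
to the plain clipped subtraction.

## The dynamics analyses

All downstream analyses run on the decontaminated absolute profiles:

* **Location medians and dominance.** Per OTU and location, the median of
  copies/100 µL across months; an OTU is *dominant* at a location when its
  median relative abundance strictly exceeds 5%. Strictness matters only
  at the boundary and is our convention.
* **Consecutive-location fold changes.** Downstream over upstream median
  after adding a shared pseudo-floor of half the smallest positive
  replicate LOD (so zero medians stay finite and the log-ratio is
  antisymmetric); changes strictly beyond 2-fold in either direction are
  flagged significant, the threshold below which technical variation
  cannot be excluded.
* **Spearman trends.** The package ships its own Spearman engine
  (`spearman_trend()`): mid-ranks, the Pearson formula on ranks, an exact
  two-sided permutation p-value for $n \le 9$ (all $n!$ permutations
  enumerated) and the $t$ approximation with $n-2$ degrees of freedom
  otherwise. A zero-variance margin is reported as undefined, never as 0.
  By default trends pool all samples with location as the ordinal variable
  ($n = 30$ in the default design) for power; per-month trends are
  available via `otu_trends(per_month = TRUE)`.
* **Anomaly scan.** For each month and consecutive location pair, the
  fraction of detected OTUs whose within-month fold reaches 2 is compared
  against 30%; a flag requires *direction reversal* — the pair's
  cross-month median fold must be below 1, i.e. widespread increases at a
  step of the system where biomass normally drops. This formalises the
  kind of single-month event a utility would want to catch: many taxa
  rising at the disinfection step.

## What the simulator emulates

`simulate_truth()` generates a six-location (A–F), five-month, triplicate
campaign with known ground truth:

* **Composition.** 144 water-community OTUs (plus the calibrator row and
  five contamination-only OTUs): three *front-dominant* OTUs engineered to
  dominate the head of the system (base shares 23%, 12.7%, 7%), three
  *back-dominant* OTUs that dominate its end, and a heavy-tailed lognormal
  background pool (fixed 14% total share, `sdlog` 3.6, per-OTU cap 1.8%
  maintained by water-filling). The tail is chosen so that roughly half
  the OTU inventory sits below the detection limit of a 25 000-read
  replicate, reproducing the familiar gap between a system-wide OTU
  inventory (~144) and per-sample richness (~69).
* **Spatial structure.** Disinfection kill-off divides every OTU's copies
  by `killoff_factor` (default 10) between A and B; back-dominant OTUs are
  reduced only by its fourth root — without this, regrowth could never
  carry the end-of-system dominants above their location-A level — and
  regrow by `regrowth_factor` (default 8) towards C, background OTUs by
  its square root. After C, profiles are stable apart from gentle
  class-specific drifts expressed through the same factors
  (`killoff_factor^-0.05` and `regrowth_factor^0.05` per step), so the
  degenerate configuration `killoff_factor = regrowth_factor = 1` yields
  exactly location-flat profiles and every consecutive step from C stays
  within 2-fold.
* **Season.** A cosine water-temperature curve (July ≈ 19.7 °C to
  November ≈ 9.9 °C) scales the log spatial profile, so trends weaken as
  the water cools; a seasonal factor (amplitude 0.3) and a lognormal
  per-(OTU, month) effect (CV 0.3) shared across locations modulate the
  bases. Keeping the month effect shared across locations is what makes
  the spatial structure deterministic given the month — replicate-level
  variation comes entirely from read sampling.
* **Anomaly.** In month 3, location B, one back-dominant OTU is boosted
  138-fold relative to location A and `round(0.30 × 144)` = 43 community
  OTUs in total are boosted at least 2.2-fold. Boosted OTUs are
  taken from the most abundant background taxa: a measured increase
  presupposes a detectable OTU, and boosting the undetectable half of the
  tail would produce an anomaly no method could see.
* **Reads.** Each replicate draws `read_depth` reads multinomially over
  template molecules: each OTU's copies plus the shared contamination
  load, plus `ic_copies` calibrator copies. NECs contain only
  contamination and calibrator. There is no amplification-efficiency bias
  term — the premise of clonal amplification is its absence — and no
  sequence-level error model, chimeras, or OTU-clustering noise.

Defaults the underlying study design does not pin down are declared
assumptions: `ic_copies = 10 000` per reaction (the same order as a qPCR
standard curve), `read_depth = 25 000` per replicate, total copies at
location A log-uniform in $[10^5, 10^6]$ per 100 µL, five contamination
OTUs at 200 copies/100 µL, `volume_scale = 1`.

Because contamination is modelled as a *fixed* per-extract load shared by
samples and NECs — the assumption implicit in NEC subtraction — passing
the decontamination tests says nothing about contamination that varies
between extracts (batch effects, cross-contamination), which this design
cannot remove. Similarly, multinomial sampling understates the
overdispersion of real library preparation, so real-data copy estimates
will be noisier than the simulation suggests.

## Companion series and concordance

`simulate_companion_series()` produces flow-cytometry and qPCR totals as
the true total copies times a method offset (defaults 4.9 and 1.3) times
unit-mean lognormal noise (CV 0.3). `fold_difference()` reports the
≥1-oriented per-sample fold $\max(a,b)/\min(a,b)$ — mean, SD, and the
directional fraction separately (so "higher in 29 of 30 samples" stays
visible) — and `trend_agreement()` gives per-month Spearman correlations
between methods across locations. The dispersion is reported as an SD and
labelled as such.

## Numerical conventions and degenerate inputs

* Ratios at zero medians: pseudo-floor `min positive LOD / 2`, shared by
  numerator and denominator (configurable).
* Boundary semantics are strict: exactly 5% is not dominant, exactly
  2-fold is not significant. The anomaly scan's two fractions use `>=`.
* Exact-permutation p-values compare $|r_s|$ with a $10^{-12}$ slack so
  ties in the permutation distribution are counted, not lost to rounding.
* A sample with fewer than two calibrator-valid replicates is refused as
  unquantifiable; a month without an NEC stops `quantify_dataset()` with
  an actionable message.
* All randomness flows from configuration seeds through one internal
  helper that restores the caller's RNG state, so identical
  configurations are byte-identical, including across the
  simulate/analyse boundary.

## Problem sizes used in the shipped checks

The test-suite recovery checks run the full default design (6 × 5 × 3
replicates, 150 OTU rows) over 100 simulated campaigns, calibration
recovery over 200 campaigns of a two-month design at $10^5$ reads per
replicate, and the Spearman oracle over 1 000 random series; the analysis
drivers under `analysis/` run one default campaign end to end. These sizes
keep every property estimate's Monte-Carlo error well below the margins
being asserted.

## Known limitations

* OTU identity is positional (`otu_001` …); taxonomy is upstream and out
  of scope.
* The simulator's spatial profiles are deterministic per class given the
  month; real systems mix classes and add location-level stochasticity.
* The anomaly definition requires direction reversal at a biomass-losing
  step; a system-wide bloom that also lifts the cross-month median above 1
  would not be flagged by this rule.
* qPCR and FCM series are consumed as numeric totals; their laboratory
  error structure is reduced to a single lognormal CV.
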