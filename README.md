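# micmon

Absolute quantification and dynamics analysis for longitudinal
drinking-water microbiome monitoring.

Water utilities that sequence 16S rRNA gene amplicons from a distribution
system get *relative* OTU profiles, which cannot tell a bloom of one taxon
from a die-off of the rest and are silently distorted by reagent
contamination. `micmon` implements the quantitative monitoring workflow
that fixes both:

* **Internal-calibrator quantification** — a known spike of foreign
  genomic DNA (`ic_copies` 16S copies per reaction) converts each
  replicate's read counts into absolute gene copies per 100 µL:
  `copies_o = reads_o / reads_IC × ic_copies × volume_scale`, with the
  limit of detection `ic_copies × volume_scale / reads_IC`.
* **NEC decontamination** — negative extraction controls, processed in
  triplicate like every sample, are calibrated on the same absolute scale
  and their mean contamination is subtracted per extraction batch, with a
  one-sided counting-noise censor so reagent-only OTUs go to exactly zero.
* **Triplicate consensus** — an OTU must be nonzero in ≥2 valid replicates;
  replicates without calibrator reads are invalid, never imputed.
* **Dynamics** — per-location medians over months, dominance (>5% median
  relative abundance), consecutive-location fold changes with a 2-fold
  significance rule, per-OTU Spearman trends (exact permutation p-values
  for n ≤ 9), and a scan for single-month community-wide anomalies.
* **Concordance** — fold-difference statistics (mean, SD, directional
  fraction) and per-month Spearman agreement between the pipeline's 16S
  totals and companion flow-cytometry / qPCR series.
* **A synthetic-data module** — six locations × five months × triplicates
  with engineered disinfection kill-off, regrowth, seasonal weakening,
  reagent contamination, a single-month anomaly, and multinomial read
  sampling over template molecules including the spiked calibrator — so
  every stage is testable against known ground truth.

## Worked example

The `analysis/` directory holds the four-stage workflow; each stage reads
the previous stage's tables from `results/`:

```sh
Rscript analysis/01_simulate.R 1     # seed 1
Rscript analysis/02_quantify.R
Rscript analysis/03_dynamics.R
Rscript analysis/04_concordance.R
```

which prints (seed 1):

```
simulated 30 samples + 5 NECs (seed 1)
true total copies/100 uL at location A, month 1: 219862
kill-off A->B (month 1): 7.5-fold
water temperature range: 9.9 - 19.7 degC

quantified 30 samples
median observed richness: 78 OTUs/sample (range 48-89)
total copies span 29687 - 1295714 copies/100 uL
NEC contamination subtracted per month: 1, 2, 3, 4, 5

dominant OTUs (>5% at some location): otu_001, ..., otu_006
83 OTUs change significantly (>2-fold) across A->B; 83 of them decrease
anomaly: month 3, step A->B: 41/83 detected OTUs at least doubled
  against the usual direction

FCM intact cells sit 4.5-fold (SD 1.1) above the 16S totals, higher in 30/30 samples
qPCR agrees with the pipeline within 1.4-fold (SD 0.3)
median per-month Spearman between methods: 0.77
```

Reading the output: the six OTUs engineered to dominate the head and tail
of the system are exactly the six flagged by the >5% rule; the
disinfection step (A→B) removes most taxa significantly; in month 3 the
scan flags the injected anomaly — roughly half the detected community at
least doubling at a step where biomass otherwise drops — and the
companion-method comparisons recover the configured 4.9× (cell counts vs
gene copies) and 1.3× (qPCR vs sequencing) offsets within sampling noise.

The same analysis is available in-memory:

```r
library(micmon)
run <- run_pipeline(sim_config(seed = 1))
print(run)
run$dominance      # per (OTU, location) medians, shares, dominance flags
run$fold_changes   # consecutive-location ratios with the 2-fold rule
run$trends         # pooled Spearman trend per OTU
run$anomalies$anomalies
```

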