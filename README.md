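# sipgrad

Analysis of DNA stable-isotope probing (SIP) experiments with
¹³C-labelled substrates.

In a DNA-SIP experiment, an environmental microbial community is incubated
with a ¹³C-labelled substrate (here: one-carbon compounds such as methanol
or methylamine). Organisms that assimilate the substrate build ¹³C into
their DNA, raising its buoyant density; CsCl density-gradient
ultracentrifugation then separates labelled ("heavy") from unlabelled
("light") DNA across ordered gradient fractions, and sequencing of
representative heavy (H) and light (L) fractions — alongside the
unincubated *in-situ* community — identifies the active
substrate-incorporating populations. `sipgrad` implements the quantitative
chain around that experiment for microbial ecologists running or
validating SIP studies:

* **Isotope mass balance** — δ¹³C of particulate organic carbon (POC)
  versus VPDB (`R_ref = 0.0112372`) to atom ratio,
  `R = (δ/1000 + 1)·R_ref`; ¹³C mass `m(¹³C) = 13·m_POC·R/(13R + 12)`;
  blank-corrected assimilation rate `(m_sample − m_blank)/t` and the
  percentage of ¹³C in the POC pool.
* **Gradient fraction analysis** — DNA-concentration peak detection,
  ¹³C-vs-¹²C profile separation, heavy/light group assignment,
  representative H/L fraction selection, and the incubation-time decision
  rule (greatest eligible H–L community dissimilarity, earliest on ties).
* **Community statistics** — equal-depth rarefaction, Bray-Curtis
  dissimilarity, Shannon diversity, group-average (UPGMA) dendrograms,
  NMDS ordination (Kruskal stress-1), and ANOSIM with exact enumeration
  for small designs.
* **Ecotype classification** — after a >1 % abundance screen, OTUs are
  called type I (rapid/dominant incorporation: heavy-enriched ≥3-fold),
  type II (slow/minor incorporation: present in H at L-like abundance) or
  type III (no incorporation: lowest in H), with cross-feeding caveats on
  late type II calls.
* **In-silico T-RFLP** — terminal restriction fragment lengths under a
  MspI + RsaI double digest.
* **A seeded forward simulator** of the whole experiment — GC-dependent
  buoyant density, two-band partial labelling, 12-fraction gradients over
  1.687–1.770 g/mL, multinomial read sampling, and a δ¹³C-POC time series
  that is the exact inverse of the mass-balance equations — providing
  planted ground truth for every downstream stage.

See `vignettes/sip-gradient-methods.Rmd` for the models, parameter
choices, and limitations.

## Worked example

Simulate an incubation with a planted total assimilation rate of
25 µg ¹³C L⁻¹ d⁻¹ and recover it through the mass-balance chain:

```r
library(sipgrad)

meas <- simulate_poc_timeseries(incubation_scenario(
  substrate = "MOH", planted_rates = 25, timepoints = c(1, 4),
  m_poc0 = 600, natural_delta = -22))
assimilation_report(meas)
#>     sample substrate time_days assimilation_rate_ug_l_d percent_13c
#> 1 site1_5m       MOH         1                       25       3.997
#> 2 site1_5m       MOH         4                       25      14.242
```

The recovered rate equals the planted 25 µg ¹³C L⁻¹ d⁻¹ at both
timepoints; `percent_13c` is the share of the POC pool that is
blank-corrected ¹³C (4.0 % after one day, 14.2 % after four).

Run the full pipeline on a synthetic experiment (100 taxa, 5 planted rapid
and 10 slow incorporators, gradients at days 1, 2 and 4):

```r
res <- run_pipeline("out_sip", seed = 1)
res$decision
#> <timepoint_decision> chose t = 4 d (H-L dissimilarity 0.9466, 1 of 3 timepoints eligible)
#>  t hl_dissimilarity peaks_distinguishable  anosim_r anosim_p eligible
#>  1               NA                 FALSE 0.7351852    0.001    FALSE
#>  2               NA                 FALSE 0.7537037    0.003    FALSE
#>  4           0.9466                  TRUE 0.7444444    0.003     TRUE
res$selection[c("h_fraction", "l_fraction")]   # representative fractions 4 and 10
res$ecotype
#> <ecotype_report> 34 abundant OTUs at depth 20000 (66 filtered): I=13 II=0 III=21 unclassified=0
res$recovery$sensitivity_I                      # 1: all planted rapid taxa called type I
```

At days 1 and 2 the ¹³C and ¹²C DNA profiles are not yet distinguishable,
so day 4 is chosen; the representative H fraction (4) sits at the labelled
DNA peak and the classifier recovers every planted rapid incorporator with
no false incorporation calls. `out_sip/` receives the fraction table,
OTU tables, assimilation report, selection report, NMDS coordinates,
dendrogram (newick), ecotype calls and a manifest with the derived seeds
and file digests that make the run reproducible bit-for-bit.

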