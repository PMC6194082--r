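---
title: "Methods: DNA-SIP gradient analysis, isotope mass balance, and ecotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-SIP gradient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipgrad)
```

# The experiment this package analyses

DNA stable-isotope probing (SIP) identifies which members of a microbial
community assimilate a supplied substrate. Seawater (or any environmental
sample) is incubated with a ^13^C-labelled one-carbon substrate such as
methanol or methylamine; organisms that incorporate the substrate replicate
their DNA with heavy carbon. Ultracentrifugation in a CsCl gradient
separates DNA by buoyant density, the gradient is divided into ordered
fractions (numbered heavy-first), and sequencing of a representative heavy
(H) and light (L) fraction — plus the unincubated *in-situ* community —
reveals which taxa moved into the heavy DNA pool.

`sipgrad` implements the quantitative steps of that workflow: the carbon
isotope mass balance, the gradient fraction analysis, the incubation-time
decision, the community statistics, and the classification of OTUs into
three ecological response types. A seeded forward simulator generates whole
synthetic experiments with planted ground truth, so every stage can be
validated by parameter recovery.

# Isotope mass balance

delta-13C of particulate organic carbon (POC), measured against the VPDB
standard (atom ratio $R_{ref} = 0.0112372$), converts to the sample atom
ratio

$$R = \left(\frac{\delta^{13}\mathrm{C}}{1000} + 1\right) R_{ref},$$

and the ^13^C mass in a POC pool of mass $m_{POC}$ (µg C L^-1^) is the
exact isotopic mass fraction

$$m(^{13}C) = \frac{13\, m_{POC}\, R}{13R + 12}.$$

The microbial assimilation rate is the blank-corrected difference
$(m_{sample}(^{13}C) - m_{blank}(^{13}C))/t$ (µg ^13^C L^-1^ d^-1^), where
the blank is the parallel incubation with the ^12^C form of the same
substrate, and the percentage of ^13^C in the POC pool shares the same
numerator divided by $m_{POC}$. Two conventions worth noting:

* $R_{ref}$ is often verbally described as an "atomic percent", but it
  enters the algebra as the ^13^C/^12^C *atom ratio*; 0.0112372 is the VPDB
  ratio and that is how the package uses it throughout.
* Negative blank-corrected rates (blank exceeding the labelled sample) are
  measurement noise; they are returned with a warning rather than clamped
  at zero so that noise behaviour remains inspectable.
* Rates are cumulative over the elapsed incubation time $t$: the chain uses
  the total elapsed days, not interval differences between consecutive
  sampling days. With measurements at several timepoints this yields one
  cumulative rate per timepoint.

## The forward model and what "planted rate" means

`simulate_poc_timeseries()` is the exact algebraic inverse of this chain.
A planted rate is defined as the *blank-corrected excess* ^13^C
assimilation rate: both treatments assimilate the same total carbon
$c(t) = \rho t / (w_{sub} - w_{nat})$, where $w_{sub}$ and $w_{nat}$ are
the ^13^C mass fractions of the substrate (99 atom% ^13^C by default) and
of natural-abundance carbon. The labelled treatment's assimilated carbon
carries $w_{sub}$, the blank's carries $w_{nat}$. Consequences: the
blank's delta-13C stays exactly at the natural background (unlabelled
substrate adds natural-abundance carbon), POC mass is identical across
treatments, and the analysis chain recovers $\rho$ exactly — the
gross-assimilation alternative would leave a systematic offset of about
1.2 % (the natural ^13^C content of the assimilated carbon), which is the
quantity the blank correction is designed to remove. delta-13C values are
emitted through atom-count bookkeeping ($n_{13} = m_{13}/13$,
$n_{12} = (m_{POC}-m_{13})/12$, $R = n_{13}/n_{12}$), so inversion is exact
to machine precision.

# The gradient simulator

`simulate_gradient()` uses the standard linear buoyant-density model

$$\rho = 1.660 + 0.098\,\mathrm{GC} + x_{label}\cdot 0.036 \;\;
  \mathrm{g\,mL^{-1}},$$

with the full-label shift of 0.036 g mL^-1^ scaled by the substrate's
^13^C atom fraction (0.99). All coefficients are `gradient_config()`
fields, not constants in code. Each taxon's DNA is a mixture of two
Gaussian bands (sd `band_sigma` = 0.005 g mL^-1^): an unlabelled band and a
fully labelled band, weighted by the taxon's labelled DNA fraction
$1 - e^{-t/\tau}$. The two-band mixture — rather than a single band
drifting continuously — reproduces the bimodal "one to two peaks"
DNA distributions characteristic of partially labelled SIP gradients.

The default gradient divides 1.687–1.770 g mL^-1^ into 12 equal intervals
whose midpoints are the fraction densities, fraction 1 heaviest. Band mass
per fraction is the Gaussian integral over the fraction's interval,
evaluated from whichever distribution tail is numerically accurate so that
far-off bands keep a tiny nonzero weight instead of underflowing to zero.
Measured DNA concentrations receive multiplicative lognormal noise with
unit mean and cv 0.05, a typical fluorometric quantification error.
Sequencing of a fraction is a multinomial draw proportional to per-taxon
DNA mass — no PCR bias, chimera, copy-number or sequencing-error model.

## The synthetic community

`make_community()` draws relative abundances from a lognormal
(sdlog = 1.5), the long-tailed rank-abundance shape typical of
bacterioplankton, and GC content from a normal (mean 0.5, sd 0.05)
truncated to [0.35, 0.65], the bulk of marine bacterial genomic GC.
Planted rapid incorporators (ecological type I) are drawn from the
20th–50th abundance percentile, reflecting that rapid C~1~-incorporators
tend to be rare *in situ*; slow incorporators are drawn at random from the
rest. Labelling time constants default to $\tau = 0.5$ d (rapid; >50 %
labelled within a day) and $\tau = 3$ d (slow; >50 % only by day 4), with
growth at 1 and 0.5 doublings d^-1^ respectively. Non-incorporators
neither label nor grow; the supplemented mineral medium could in reality
stimulate some of them, but no quantitative basis exists for
parameterising that, so their `growth_rate` is exposed per taxon and
defaults to 0. Blank (^12^C) incubations keep the same growth but zero
labelling, since the unlabelled substrate is consumed all the same.

What passing recovery tests therefore show is that the analysis chain is
correct *under* these idealisations — clean multinomial sampling, Gaussian
bands, no cross-feeding, no compositional artefacts of PCR. They do not
show robustness to real-data features the simulator deliberately omits.

# Gradient fraction analysis

`detect_peaks()` makes the visual peak-reading of gradient profiles
deterministic: a peak is a fraction exceeding both neighbouring usable
fractions with topographic prominence at least 0.1 of the profile maximum;
plateaus count once at their heaviest fraction; edge fractions are never
peaks. Failed fractions (where fingerprinting failed but DNA was still
quantified) are excluded by default and included (`include_failed = TRUE`)
when locating concentration peaks for representative-fraction selection;
if a selected fraction is failed, the nearest non-failed fraction in the
same group substitutes, ties resolving to the heavier fraction.

`peak_separation()` calls the ^13^C and ^12^C profiles distinguishable
when the DNA-weighted mean density shift reaches 0.010 g mL^-1^ *or* the
heavy-half DNA share grows by 0.15. No numeric criterion exists in the
field for "clearly distinguished" peaks; both thresholds are explicit
configuration with these defaults as the package's own operational choice
(the shift threshold is about two fraction widths of weighted-mean
movement; the share gain catches strongly bimodal cases with small mean
shift).

Heavy/light group assignment takes any two-group labelling of the
fractions and orients it by mean density. The pipeline produces that
labelling from the community structure itself — Bray-Curtis dissimilarity
between fraction communities, UPGMA, two-group cut — which mirrors how H
and L groups are delimited from fingerprint data. On simulated gradients
with realistic GC spread the heavy-to-light transition can be gradual
enough that this unconstrained cut strands the labelled DNA peak in the
"light" cluster; when that happens the pipeline falls back to
`valley_groups()`: split the fraction series at the DNA-concentration
trough between the two main bands, the classical way a practitioner
delimits the H and L regions on the concentration profile.

`select_timepoint()` encodes the incubation-time rule: a timepoint is
eligible when its ^13^C/^12^C peaks are distinguishable, a representative
H/L pair exists, and (when a replicated design allows ANOSIM) the
heavy-light community difference is significant at $\alpha = 0.05$; among
eligible timepoints the greatest H-L dissimilarity wins, ties going to the
earliest time, which minimises cross-feeding and bottle effects. The
ANOSIM screen is optional because single unreplicated gradients cannot
support a permutation test.

# Community statistics

Bray-Curtis dissimilarities are computed on relative abundances (raw-count
mode available), Shannon diversity in natural log, and rarefaction is
sampling without replacement to an exactly equal depth — all delegated to
vegan. Diversity is computed after subsampling by default. NMDS uses
monotone regression with the primary treatment of ties and 20 random
restarts (vegan's monoMDS); because the package makes no claim of numeric
agreement with any particular legacy ordination tool, NMDS quality is
asserted through stress properties, not coordinates. UPGMA clustering
sorts labels lexicographically before linkage so merge ties resolve
deterministically; dendrograms export as newick via ape.

ANOSIM is implemented in the package rather than delegated: the
permutation p-value uses the $+1/+1$ convention (the observed labelling
counts as one permutation), and designs with $n \le 8$ can be enumerated
exhaustively, giving exact p-values that the random-permutation mode and
an independent enumeration oracle are tested against. The R statistic is
cross-checked against vegan's implementation in the test suite.

# Ecotype classification

OTUs are screened to those whose relative abundance strictly exceeds 1 %
in at least one of the H, L or *in-situ* libraries (per-library reading of
the screen, all three libraries rarefied to a common depth first). The
three response types are then called in rule order:

* **I — rapid/dominant incorporation**: $h / \max(l, i, \varepsilon) \ge F$,
  heavy enrichment beyond fold threshold $F = 3$;
* **III — no incorporation**: $h < l$ and $h < i$, strictly lowest in the
  heavy library (ties fall through rather than forcing a III call);
* **II — slow/minor incorporation**: present in H above 0.1 % at an
  abundance within a factor $F$ of L;
* otherwise unclassified.

$F = 3$ and the 0.1 % presence floor are the package's quantitative
rendering of the qualitative notions "enriched", "similar" and "lowest";
both live in `ecotype_config()`. The ordering makes the rules mutually
exclusive and exhaustive, and raising $h$ alone can never demote a type I
call (property-tested). Type II calls on incubations longer than two days
are flagged with a cross-feeding caveat: secondary consumers of
incorporator metabolites or biomass acquire label late and masquerade as
slow incorporators; the package warns rather than models this. Taxonomy
strings, when supplied, aggregate the calls into clade-style summaries
with per-role median abundances; dataset-specific clades are groupings of
the three underlying types, so the classifier works at the type level and
leaves clade definitions to the data.

A caveat the simulator exposed: because a sequencing library normalises
away absolute DNA mass, "sequencing" a heavy fraction that contains
essentially no DNA yields a library of Gaussian-tail DNA dominated by the
highest-GC taxa, which would be falsely called type I. The chain avoids
this by construction — a representative H fraction is only ever selected
at an actual DNA concentration peak — but it is the reason
`ecotype_report()` should not be fed arbitrary fraction pairs.

# Numerical and design choices

* Fraction numbering is heavy-first everywhere; I/O re-sorts (with a
  warning) rather than erroring on ascending input.
* Peak prominence 0.1 x max; plateau ties to the heavier fraction.
* The degenerate case of two fraction groups with exactly equal mean
  density is an error, not an arbitrary orientation.
* Every stochastic stage takes a seed derived deterministically from the
  master seed (`derive_seed()`, kept within 32-bit range); a pipeline run
  is reproducible bit-for-bit from its manifest.
* T-RF lengths are 1-based, include the labelled 5' primer base, and use a
  double digest (MspI `C^CGG`, RsaI `GT^AC`) in which the shortest
  fragment wins; no +-1 nt bin merging is applied.
* Validation runs use communities of 100 taxa (5 rapid, 10 slow), 12
  fractions, 5 x 10^3^ reads per fraction and 2 x 10^4^ reads per H/L/in-situ
  library, 20 seeds for end-to-end recovery and 200 replicates for the
  ANOSIM null calibration — sizes chosen so the full suite re-runs in
  minutes on a laptop while keeping Monte-Carlo error well inside the
  asserted margins.

# Known limitations

* Detection of rapid incorporators is bounded by the abundance screen, not
  only by the classifier: a planted rapid taxon rare enough to stay below
  1 % even in the heavy library is reported as filtered/unclassified. In
  simulated recovery runs essentially all type I misses are of this kind,
  concentrated at early timepoints where slow incorporators and unlabelled
  spill-over still dominate the heavy fraction.
* No quantitative SIP (qSIP-style per-taxon atom-fraction-excess
  estimation); the classifier is categorical.
* The buoyant-density model is linear in GC and label; real gradients show
  tube-to-tube offsets and compression that the simulator does not emulate.
* No model of PCR amplification bias, rRNA operon copy number, chimeras or
  sequencing error; recovery results are upper bounds on real performance.
* Cross-feeding and bottle effects are reported as caveats, not modelled.
* The incubation-time rule compares a small set of discrete timepoints; it
  does not interpolate an optimal continuous time.
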