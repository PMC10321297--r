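---
title: "Methods: allele-dose onset analysis for recessive WFS1 registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-dose onset analysis for recessive WFS1 registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfsdose)
```

## The analysis model

`wfsdose` treats a Wolfram syndrome registry as a cross-sectional sample of
biallelic *WFS1* patients, each contributing two protein-level variant
descriptors and per-manifestation ages of onset (years, possibly absent).
The scientific question is ordinal, not parametric: does onset occur
*earlier* as the genotype carries more severe alleles? Accordingly the
pipeline never fits an onset distribution; it compares groups with rank
statistics.

Three classification layers define the groups:

* **Broad class.** A parsed variant is NSFS if its kind is nonsense or
  frameshift (predicted truncating), and in-frame if it is missense or an
  in-frame insertion/deletion/delins (reading frame preserved). Everything
  else — start-loss, stop-loss, synonymous, unparseable text — is OTHER.
  The two-bin scheme has no defensible place for such alleles, so patients
  carrying one are excluded from dose analyses (with a machine-readable
  reason) rather than silently guessed into a bin.
* **NSFS dose** is the count of NSFS alleles (0/1/2). Homozygotes are
  written as the same descriptor twice and both alleles count: the dose is
  an allele count, not a distinct-variant count.
* **TM dose** is the count of in-frame alleles whose affected residue
  interval overlaps a transmembrane range. It is defined only for
  genotypes with at least one in-frame allele, giving the two analysed
  subsets: two-in-frame patients (TM dose 0/1/2) and one-in-frame patients
  (TM dose 0/1).

Eligibility is per manifestation: a patient enters the DM analysis iff both
alleles are present and classifiable *and* a numerical DM onset is
recorded. A record with onset "childhood" is kept but contributes nothing
to that manifestation.

## Interval semantics for transmembrane calls

The domain table is a set of ordered, non-overlapping, 1-based closed
residue intervals. A missense variant affects its single substituted
residue. For multi-residue in-frame variants the membership question is
genuinely open — annotation schemes are written for point substitutions —
and we chose **overlap, not containment**: a deletion counts as
transmembrane if *any* deleted residue is membrane-spanning. Removing even
one residue of a membrane helix plausibly disrupts it, so overlap is the
conservative generalisation. A pure insertion has no reference residue of
its own and is attributed to its two flanking residues; a duplication is
treated as an insertion after the last duplicated residue. These choices
are property-tested against a per-residue brute-force membership scan.

The package ships only a clearly labelled *synthetic* domain table on a
fictitious 890-residue protein (nine 21-residue helices). Real analyses
must supply a snapshot of the wolframin annotation; the loader refuses
tables without a provenance line precisely because transmembrane
coordinates drift across annotation releases, which shifts TM-dose group
membership.

## Rank-sum testing and multiplicity

`wilcoxon_rank_sum()` is two-sided throughout (direction is read off the
medians afterwards; a one-sided test would presuppose the dose effect it is
meant to establish). Two regimes:

* **Exact enumeration.** For untied samples the null distribution of the
  rank sum `W` is uniform over the `choose(n, n_x)` assignments of ranks to
  the first sample. The p-value is `P(|W − E W| ≥ |w_obs − E W|)` by
  complete enumeration, which equals classic tail-doubling for this
  symmetric distribution. `auto` mode enumerates when the pooled sample has
  no ties and `n ≤ 20` (at most 184,756 splits); `exact` mode additionally
  refuses enumeration above 5·10⁶ splits. Tied data cannot be enumerated
  uniformly, so exact requests on tied data fall back to the approximation
  with a logged note.
* **Normal approximation.** Mid-ranks with the standard tie-corrected
  variance; no continuity correction by default (configurable, and recorded
  in the comparison's settings so runs are reproducible). If every pooled
  observation is identical the statistic is degenerate and p = 1 with a
  warning.

Bonferroni adjustment multiplies each raw p by the number of pairwise tests
*within one manifestation × one grouping* (m = 3 for three dose groups,
m = 1 for a sex comparison) and caps at 1. The family is deliberately not
extended across manifestations: each manifestation's comparison is reported
as its own self-contained family, matching how pairwise brackets are
annotated per panel in onset figures. Both raw and adjusted p-values are
always reported.

Group summaries follow box-plot conventions: median and quartiles, whiskers
clamped to the most extreme observations within 1.5×IQR fences, points
beyond as outliers. Quartile interpolation defaults to linear interpolation
between order statistics (R's `quantile` type 7) and is configurable
(`lower` = type 1, `midpoint` = type 2) because published quartiles with
four decimals imply *some* interpolating convention without naming it;
matching printed tables from real data may require trying the alternatives.

## The synthetic registry

`generate_cohort()` emulates the *structure* of a pooled rare-disease
registry, not Wolfram biology:

* **Onset ages** are log-normal, truncated at zero by construction —
  onset-age box plots are right-skewed with late-onset outliers, which a
  normal model would miss. The real distributional family is unknown; every
  generator claim is about the generator only.
* **Dose effects** move the log-normal median: a patient's expected median
  is `baseline − d_NSFS·nsfs_shift − d_TM·tm_shift − male·male_dm_shift`
  (the last term for DM only), floored at 0.5 y, with ages drawn around it
  (`shift_mode = "multiplicative"`; an additive variant subtracts shifts
  from sampled ages and truncates at 0).
* **Defaults as study conditions.** 350 patients; NSFS allele frequency
  0.55; TM fraction 0.5; baseline medians 8/12/13/14 y with log-SD
  0.45/0.35/0.30/0.40 for DM/OA/DI/HL; `nsfs_shift = 1.5` y/allele (a
  3-year two-allele gap, the size of the published DM contrast),
  `tm_shift = 2.0` y/allele (the published two-in-frame DM contrast spans
  ~5 y over two alleles), `male_dm_shift = 1.5` y; missingness
  0.06/0.11/0.56/0.43 so eligible sample sizes land near the published
  ~325/307/149/195 per manifestation; 4% of rows lack one allele
  descriptor. These were chosen once as the emulated conditions and are not
  tuning knobs.
* **What it does not emulate:** allele-frequency spectra of real *WFS1*
  catalogues, correlation between manifestations within a patient beyond
  shared dose, consanguinity structure (homozygosity is a flat 15% within
  the 0/2-dose classes), ascertainment bias of literature case reports, or
  measurement error in recalled onset ages. Passing tests therefore
  validate the machinery and its calibration, not any claim about real
  registries.

Note that under the *default* parameters the marginal NSFS contrast is
partially confounded by the TM effect (zero-NSFS patients carry two
in-frame alleles, some transmembrane — as in real cohorts, where the two
severity axes coexist). Calibration and power runs therefore isolate one
effect at a time: the null study sets all shifts to zero, and the NSFS
power study sets `tm_shift = 0` so the simulated NSFS2-vs-NSFS0 median gap
is exactly 3 years.

## Validation problem sizes

The shipped validation suite runs at desk scale: exhaustive
enumeration-vs-oracle agreement for all two-sample splits with total
n ≤ 10; 1,000 null replicates at n = 50/group for type-I error of the
adjusted NSFS2-vs-NSFS0 test; 200 replicates at n = 100/group for power and
median-gap recovery under the 3-year gap; 1,200 synthetic patients for
classification ground-truth recovery; 1,000 random variant/table pairs for
the transmembrane overlap oracle. Monte-Carlo checks use fixed seeds and
binomial-error tolerances.

## Known limitations

* The parser covers protein-level (p.) descriptors only; cDNA descriptors
  are rejected with a pointer to the reason, and splice or regulatory
  variants cannot be expressed at the protein level at all — cohorts
  containing them lose those patients to the OTHER bin.
* No survival machinery: patients who have not yet developed a
  manifestation are simply absent from that analysis, so late-onset
  censoring biases medians downward in young cohorts. A time-to-event
  treatment is out of scope.
* No covariate adjustment; sex is handled only by stratification.
* Registry rows are assumed to be distinct patients; cross-source
  deduplication must happen upstream.
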