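# wfsdose

Allele-dose genotype–phenotype analysis for Wolfram syndrome patient
registries.

Wolfram syndrome is an autosomal-recessive disorder caused by biallelic
variants in *WFS1*, which encodes wolframin, a polytopic ER membrane
glycoprotein. Its cardinal manifestations — diabetes mellitus (DM), optic
atrophy (OA), diabetes insipidus (DI) and sensorineural hearing loss (HL) —
appear at ages that vary widely between patients, and part of that
variability tracks the *severity of the genotype*. `wfsdose` implements the
registry analysis that quantifies this:

1. **Allele classification.** Each protein-level variant descriptor
   (`p.Arg558Cys`, `p.Trp613*`, `p.Val412Serfs*29`, …) is parsed and binned
   as **NSFS** (nonsense/frameshift, predicted truncating) or **in-frame**
   (missense, in-frame insertion/deletion). A patient's *NSFS dose* is the
   number of NSFS alleles, 0/1/2.
2. **Transmembrane annotation.** In-frame variants are classified as
   transmembrane (TM) or not by closed-interval overlap of their affected
   residue interval with a transmembrane-domain table; the *TM dose* counts
   TM in-frame alleles.
3. **Dose–onset statistics.** For each manifestation, age of onset is
   compared across dose groups (and between sexes) with two-sided Wilcoxon
   rank-sum tests — exact by complete enumeration of rank assignments for
   small untied samples, tie-corrected normal approximation otherwise —
   with Bonferroni adjustment over the pairwise family:
   `p_adj = min(1, m · p_raw)`, `m` = number of pairwise tests in the
   comparison. Group summaries use box-plot conventions (median, quartiles,
   whiskers at 1.5×IQR, outliers beyond).
4. **Synthetic registry.** A seeded generator emits registries with the same
   schema and statistical structure (log-normal onsets, per-allele dose
   shifts, a male DM shift, missingness) plus a ground-truth table, so the
   entire pipeline is testable and power-calibrated without patient data.

The bundled transmembrane table (`inst/extdata/wfs1_tm_domains_synthetic.tsv`)
is a clearly labelled synthetic stand-in on a fictitious protein; to analyse
real data, supply your own snapshot of the wolframin annotation (the loader
requires a provenance line recording its source).

## Worked example

```r
library(wfsdose)

# simulate a registry of 350 patients and analyse it end to end
sim <- generate_cohort(sim_params(seed = 42))
dir <- tempfile(); write_cohort(sim, dir)

report <- run_analysis(run_config(
  registry_path     = file.path(dir, "registry.tsv"),
  domain_table_path = file.path(dir, "domains.tsv"),
  output_dir        = file.path(dir, "report")))
print(report)
#> <wfs_report>
#> cohort onset summaries:
#>  manifestation   n median lower_quartile upper_quartile
#>             DM 310  4.335          3.145           6.25
#>             OA 301  9.400          7.130          12.15
#>             DI 144 10.480          8.158          12.47
#>             HL 183 11.780          9.155          14.70
#> eligible n: DM=310  OA=301  DI=144  HL=183
#> 10 file(s) written to ...

# the DM TM-dose comparison among patients with two in-frame alleles
print(report$comparisons$DM$tm_two_inframe)
#> <group_comparison> DM by tm_two_inframe
#>  manifestation group  n median lower_quartile upper_quartile
#>             DM  NTM0 18  8.465          5.480        12.2475
#>             DM  NTM1 33  4.720          3.430         6.9200
#>             DM  NTM2 16  3.265          2.785         5.1950
#> pairwise Wilcoxon rank-sum (Bonferroni m = 3 ):
#>  group_a group_b   U     p_raw     p_adj
#>     NTM0    NTM1 470 0.0006499 0.0019500
#>     NTM0    NTM2 250 0.0002548 0.0007645
#>     NTM1    NTM2 353 0.0577500 0.1733000
```

Among the 67 eligible DM patients carrying two in-frame alleles, diabetes
emerges earliest with two transmembrane variants (median 3.3 y), later with
one (4.7 y) and latest with none (8.5 y); both comparisons against the
zero-TM group survive Bonferroni adjustment. The report directory contains the
group and pairwise tables as TSV, optional box-plot PNGs, and a JSON run
manifest with input checksums and every excluded patient with its reason
(`missing_allele`, `unparseable_allele`, `missing_onset`).

A thin command-line front end with `simulate`/`classify`/`annotate`/
`analyze`/`power` subcommands is installed at
`system.file("cli", "wfsdose.R", package = "wfsdose")`.

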