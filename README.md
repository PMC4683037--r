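# germir

Small RNA annotation, miRNA hairpin discovery and target analysis for
germinating seed embryos.

germir is an R package for analyzing small RNA sequencing libraries from
time courses of seed germination (e.g. embryos at 0, 12 and 24 hours
after imbibition). It is aimed at plant small-RNA researchers who want a
transparent, fully testable implementation of the classical
miRNA-discovery pipeline: every stage runs offline, and a synthetic data
generator with complete ground-truth bookkeeping lets each stage be
validated without any external download.

## What it computes

**Classification.** Collapsed 18–30 nt reads are mapped to the genome by
exact matching on both strands and assigned one category with precedence
known_miRNA > rRNA > tRNA > snoRNA > snRNA > other. Known-miRNA matching
is Hamming distance ≤ 2 at equal length; structural RNAs match as exact
substrings of their reference sets. Summary tables follow the standard
library-statistics percentage conventions with half-up rounding.

**Hairpin discovery.** Each unannotated read seeds a candidate: a ±150 nt
genomic window is folded (nearest-neighbor MFE model, 37 °C, via
ViennaRNA's RNAfold), trimmed to the maximal stem-loop containing the
read, and scored by the four novel-miRNA criteria:

1. mature length 20–24 nt;
2. classical fold-back structure and precursor length ≥ 45 nt;
3. more than five reads in at least one library;
4. MFEI > 0.85 or an observed miRNA\*,

where MFEI = (|MFE| / precursor length × 100) / GC%. Passing candidates
sharing a mature sequence merge into one miRNA (`OsmiR-<serial>`, with
`-1, -2, …` precursor suffixes).

**Expression.** TPM = count / clean reads × 10⁶; Log₂(TPM + 1) views;
per-miRNA max-normalization, with a profile called differential when its
minimum normalized value is below 0.5 (ratio > 2-fold); Pearson
screening of miRNA–target pairs (folds > 2, r < −0.5); hierarchical
clustering (Euclidean, average linkage) and PCA; and the
efficiency-corrected RT-PCR ratio E_t^ΔCt(t) / E_ref^ΔCt(ref).

**Targets.** Ungapped antiparallel duplexes scored by six rules
(≤ 4 mismatches with G:U = 0.5; ≤ 2 adjacent mismatches; none adjacent
in positions 2–12; perfect 10–11; ≤ 2.5 mismatches in 1–12; duplex
energy ≥ 75 % of perfect). Degradome tags confirm a site when the
binomial tail probability of the tag count at the two-base slice window
(opposite miRNA positions 10–11, success probability 2/L) is below
0.05. Overlaps between rule presets and degradome evidence are reported
as Venn counts.

## Worked example

A miniature synthetic study, end to end:

```r
library(germir)
cfg <- pipeline_config(
  sim = list(genome_length = 60000, n_known_mirnas = 3,
             n_novel_mirnas = 5, n_decoy_hairpins = 4,
             reads_per_library = 30000, n_transcripts = 8),
  seed = 11)
bundle <- run_pipeline(cfg, "germir_demo")
#> [simulate] generating synthetic study (seed 11)
#> [annotate] 41380 reads classified
#> [discover] 17 candidates, 5 novel miRNAs
#> [express] 2 differential of 8 miRNAs
#> [targets] 4 sites (4 degradome-confirmed)

bundle$catalog
#> mirna_catalog: 5 miRNAs from 5 precursors
#>     name                   mature n_precursors
#>  OsmiR-1 ATCTAGATAGAAGTCTCTAGGTCG            1
#>  OsmiR-2 AGCCATCCTTTGCAGCGTCCTATA            1
#>  OsmiR-3 ACAAGAACACTTTCCTGGCGCGCC            1
#>  OsmiR-4    TGTGTCAGGGGTATCAAAATT            1
#>  OsmiR-5 GTCTTGGAGCCTTCGAGCCATAAA            1
```

All five planted novel hairpins are recovered; the four decoys (one per
criterion class) are rejected. The classification summary for the 0 HAI
library shows the standard table shape — reads and unique sequences per
category, with category percentages relative to the non-coding total and
unique percentages relative to the category's own reads:

```r
s <- bundle$summary; head(s[s$library == "0HAI", ], 11)
#>               row reads reads_pct unique unique_pct
#>               raw 30000        NA     NA         NA
#>          18-30 nt 30000     100.0  19447      100.0
#>            mapped 30000     100.0  19447      100.0
#>               CDS  3443      11.5   2675       13.8
#>  non-coding total 26557     100.0     NA         NA
#>       known_miRNA   343       1.3      3        0.9
#>              rRNA  9006      33.9   4438       49.3
#>              tRNA  3485      13.1   1043       29.9
#>            snoRNA  1537       5.8    806       52.4
#>             snRNA   995       3.7    687       69.0
#>             other 11191      42.1   9795       87.5
```

Two miRNAs were planted with > 2-fold profiles and both are called, with
their max-normalized profiles:

```r
bundle$differential[bundle$differential$is_differential,
                    c("id", "max_library", "0HAI", "12HAI", "24HAI")]
#>              id max_library  0HAI 12HAI 24HAI
#> OsmiR-3 OsmiR-3       24HAI 0.106 0.167 1.000
#> OsmiR-4 OsmiR-4       12HAI 0.252 1.000 0.322
```

The four planted target sites (the patterns that satisfy all six rules)
are found and degradome-confirmed:

```r
bundle$sites[, c("mirna", "transcript", "start", "mismatch_score",
                 "energy_ratio", "p_value", "confirmed")]
#>     mirna transcript start mismatch_score energy_ratio   p_value confirmed
#> 1 known-1       tx-1   446            0.0        1.000 5.49e-180      TRUE
#> 2 known-2       tx-2    93            0.0        1.000 1.16e-184      TRUE
#> 3 known-3       tx-3   453            0.5        0.884 3.35e-178      TRUE
#> 4 OsmiR-3       tx-4   409            0.5        0.916 1.86e-206      TRUE
```

A thin command-line wrapper with subcommands
(`simulate | annotate | discover | express | targets | report | run`)
lives at `inst/cli/germir.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","germir.R",package="germir"))')" \
  run --config config.yaml --outdir out
```

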