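---
title: "Methods: small RNA annotation, hairpin discovery and target analysis in germir"
author: "germir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA annotation, hairpin discovery and target analysis in germir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

germir reimplements, at desk scale, the computational core of a small
RNA-seq study of germinating seed embryos: three time-point libraries (0,
12 and 24 hours after imbibition) are classified against structural RNA
references and a known-miRNA catalog, unannotated reads seed a search for
novel miRNA hairpins filtered by the minimal folding free energy index
(MFEI), expression is quantified as transcripts per million (TPM) with a
max-normalization differential rule, and targets are predicted by a
six-rule complementarity scorer with degradome confirmation. This vignette
records the model, its assumptions, the tunable parameters and the design
decisions taken where the procedure left room.

## Read classification

Collapsed reads of 18-30 nt (inclusive bounds) are mapped to the genome by
exact matching on both strands; a read with no perfect hit is left
unclassified. Mapped reads are assigned exactly one category with the
precedence known_miRNA > rRNA > tRNA > snoRNA > snRNA > other:

* a known-miRNA match is an equal-length Hamming comparison with at most
  two substitutions against any catalog mature sequence. No indels are
  allowed — the mismatch allowance is phrased in substitutions, and an
  indel would dislocate every downstream position-based rule;
* a structural-RNA match is an exact substring of the corresponding
  reference set;
* `cds_overlap` flags reads whose genomic hit intersects an annotated CDS.

The precedence is configurable. Putting known miRNAs first is a deliberate
choice: the classical processing order discards structural-RNA matches
before the miRNA alignment, but reporting known miRNAs within the
non-coding hierarchy is only consistent if a read that matches both a
miRNA and an rRNA is counted as a miRNA. Reads containing N map nowhere
and count as mismatches everywhere (conservative).

Multi-mapping reads contribute their full count once to their category (no
fractional allocation); all genomic hits are retained for hairpin
discovery. Summary percentages follow the reporting conventions of sRNA
library-statistics tables: the genome-mapped and CDS rows are column-wise
percentages of the 18-30 nt totals, each non-coding category's reads
percentage is relative to the non-coding reads total, and its
unique-sequence percentage is relative to the same category's reads count.
All percentages are rounded half away from zero to one decimal, which
matches how such tables are conventionally printed (R's own `round()`
rounds half to even and does not).

## Hairpin discovery

Every unannotated, non-CDS read with enough support seeds a precursor
candidate at each of its (merged) genomic hits:

1. a window of 150 nt upstream and downstream of the hit is extracted
   (minus-strand hits are reverse complemented, so the window is always
   read 5'→3' on the read's strand). The flank figure is primary; the
   total window is therefore 150 + mature + 150 ≈ 321 nt rather than a
   fixed 300 bp;
2. the window is folded with a standard nearest-neighbor thermodynamic
   model at 37 °C (ViennaRNA's RNAfold behind `fold()`; a built-in
   Nussinov maximum-pairing engine is available as an energy-free
   fallback);
3. the fold is trimmed to the maximal single stem-loop containing the
   mature read: starting from the mature's own pairing, enclosing pairs
   are absorbed while the region contains exactly one terminal loop and
   the helix continues through interior loops of at most 8 nt per side.
   The gap bound stops a lone far-out pair between unrelated flank
   regions from stretching the precursor across long unpaired stretches;
   8 nt is generous for the interior loops seen in real plant precursors
   while excluding flank artifacts by an order of magnitude;
4. MFE is recomputed for the trimmed precursor and
   AMFE = |MFE| / length × 100, MFEI = AMFE / GC%. The length in the MFEI
   denominator is the precursor length (a mature-length variant is
   available): with published precursor MFEI values spanning roughly
   0.2-3.8 over 37-268 nt precursors, only the precursor-length reading
   is arithmetically consistent;
5. the star strand is the sequence pairing the mature in the fold,
   reported at mature length with the canonical 2-nt 3' overhang
   (`star = partner of the mature 5' end + 2`); `star_observed` requires
   an exact sequence match in the read set. No star is defined when more
   than half the mature is unpaired.

The four novel-miRNA criteria are then applied with strict boundaries:

1. mature length 20-24 nt inclusive;
2. classical fold-back — operationalized as ≥ 60% of mature bases paired,
   all partners on the opposite arm of a single stem-loop — and precursor
   length ≥ 45 nt;
3. read count strictly greater than five in at least one library
   (mature-strand counts only; star reads are not added);
4. MFEI strictly greater than 0.85, or an observed star.

Passing candidates with identical mature sequences merge into one miRNA
("OsmiR-" plus a serial assigned in order of first genomic coordinate);
multiple precursors of one mature get suffixes -1, -2, … in coordinate
order. Candidate seeding requires at least 4 reads in some library
(`candidate_min_reads`): strictly below the greater-than-five criterion,
so it can never decide a verdict, but it keeps the folding queue free of
the singleton background that dominates deep libraries. Genomic hits of
one sequence closer than 50 nt on the same strand are merged to avoid
duplicate precursors from overlapping windows.

## Expression analysis

TPM = count / total clean reads × 10⁶ per library. Log₂ views add a
pseudocount of 1 (the convention for sparse sRNA tables; configurable).
Each miRNA's profile is divided by its own maximum; a miRNA detected at
TPM ≥ 1 in at least one library whose minimum normalized value falls
below 0.5 (equivalently, max/min ratio > 2) is called differentially
expressed. The rule is scale-free: multiplying a profile by any positive
constant cannot change the call.

miRNA-target screening flags pairs where both profiles change more than
2-fold and the correlation index is below −0.5. The coefficient is
Pearson by default — the screening threshold of −0.5 suggests a linear
index, and Pearson on max-normalized profiles equals Pearson on the raw
profiles — with Spearman available. Hierarchical clustering uses
Euclidean distance with average linkage (the defaults of the MeV tool
this reporting emulates) and PCA is computed on the column (library)
profiles; both are deterministic.

Stem-loop RT-PCR quantification uses the efficiency-corrected ratio
E_target^ΔCt(target) / E_ref^ΔCt(ref) with ΔCt = Ct(control) −
Ct(sample); at E = 2 exactly this reduces to the 2^ΔΔCt method.
Efficiencies outside the ideal 1.8-2.05 window are flagged, not
rejected.

## Target prediction and degradome confirmation

Duplexes are ungapped and antiparallel: miRNA position i (from the 5'
end) pairs site position L+1−i. The positional rules are stated on miRNA
coordinates, which a gap would dislocate — hence no bulges. Each position
is a Watson-Crick match, a G:U wobble, or a mismatch. The six rules:

1. mismatch score ≤ 4, where G:U counts 0.5;
2. no more than two adjacent non-matches anywhere;
3. no adjacent non-matches within positions 2-12;
4. perfect matches at positions 10-11;
5. mismatch score over positions 1-12 ≤ 2.5;
6. duplex energy at least 75% of the perfect-complement energy.

G:U is half a mismatch only where the rules say so (1 and 5); for the
adjacency rules it is a non-match and for the energy it contributes no
stabilizing stack — the conservative reading wherever the wording is
silent. Rule 6 compares magnitudes: both energies are negative, and "not
less than 75%" is only meaningful on |MFE|. The duplex energy is a
Watson-Crick nearest-neighbor stack sum (Xia-style RNA parameters) over
consecutively matched positions; helix initiation terms cancel in the
ratio and are omitted. Every window of miRNA length on every transcript
is evaluated; the scan is exactly equivalent to scoring each window
independently.

The cleavage position is the transcript base opposite miRNA position 11,
so the two-base slice window (cleavage, cleavage+1) covers the bases
opposite positions 10-11 — the bond the silencing complex cuts.
Degradome confirmation counts tag 5' ends in that window and computes
the binomial tail probability of at least that many among all tags on
the transcript with success probability 2/L; a site is confirmed at
p < 0.05. The discrete test is conservative, so the realized type-I
error sits at or below the nominal level. The three-method overlap
report is exercised with the rule scorer under strict and relaxed
presets plus degradome confirmation; external prediction servers are
out of scope, but the Venn machinery is the same.

## The synthetic study and its ground truth

The generator emulates the study conditions end to end: three libraries
(0/12/24 HAI) of 10⁵ clean reads; background with 21- and 24-nt
abundance peaks (size mix 0.35/0.45/0.20) drawn from embedded rRNA,
tRNA, snoRNA and snRNA genes, coding exons and random intergenic
24-mers; mature 5' bases biased to A (0.662) for 24-nt miRNAs and to U
(0.693) for shorter ones; 60% of novel matures 24 nt; log-normal
intended abundances (σ = 0.7 on the log scale, heavy-tailed like real
sRNA libraries) with 30% of planted miRNAs given a 4-8-fold profile
biased toward the latest time point and all others held within
1.3-fold.

Hairpins are engineered as mature arm + loop + reverse-complement arm
with one to three non-pairing substitutions on the star arm (so the
mature never exact-maps to the opposite arm and duplicates no
precursor). Each decoy violates exactly one criterion: a 19-nt mature
(class 1); a 44-nt precursor insulated by poly-A flanks that cannot
extend the stem (class 2); a planted count of exactly five per library
(class 3); an A/T-only stem with a cytosine-only loop — the loop can
pair with neither itself nor the arms — giving a weak |MFE| at moderate
GC and hence MFEI below 0.85, with no planted star (class 4). Every
engineered hairpin is verified in its actual genomic context through
the same folding engine the pipeline uses, with margins (pass-like
hairpins must reach MFEI > 1.0 and ≥ 70% mature pairing; class 4 must
stay ≤ 0.75), and the construction is redrawn until the contract holds;
this makes the planted verdicts constructive truths rather than
statistical tendencies. Counts that decide criterion verdicts (class-3
decoys, star reads at 3 copies) are planted deterministically rather
than sampled, so a verdict is never left to multinomial noise; all other
planted counts are multinomial around their intended TPM.

Planted target sites instantiate named duplex patterns ("perfect",
"gu@5", "mm@10", "mm@6+7", "mm@5+6+7", "mm@1+4+8+14+18"); intended
verdicts for rules 1-5 follow combinatorially from the pattern, and the
intended rule-6 verdict is guaranteed with a margin — a site whose
retained-stack fraction falls between 0.70 and 0.80 is re-planted on a
different miRNA so the verdict cannot sit on the threshold. Degradome
tags fall on the canonical slice with the configured signal fraction
(0.5 by default, 200 tags per confirmed-by-design site) and uniformly
otherwise.

What the generator does not emulate: sequencing errors and quality
scores, adapter contamination, repeat-derived multi-mapping families,
isomiR end heterogeneity, and RNA-structure differences between naked
windows and chromatin context. Passing the recovery suites therefore
demonstrates the correctness of the pipeline's logic under clean planted
truth, not its sensitivity on noisy biological libraries.

## Problem sizes and numerical conventions

The recovery suites run the standard study at 10⁵ reads per library with
20 pass hairpins and five decoys per criterion class; differential-call
recovery uses 300 planted profiles (sensitivity and specificity each
≥ 95%); degradome calibration uses 500 null sites and 200 signal sites
at 200 tags each; the rule scorer is checked against a brute-force
checker on 10 000 enumerated state vectors. These sizes give every
binomial assertion a comfortable margin while keeping a full run in the
minutes range on one CPU. Reported TSV floats carry 10 significant
digits so outputs are byte-reproducible; percentages are half-up to one
decimal; all randomness flows from a single seed per run, with each
generator stage drawing from its own derived stream so stages are
reproducible independently of call order.

## Known limitations

Exact mapping only (no indels or mismatched alignment against the
genome); one genome at a time; hairpin discovery starts from mapped
reads, so a miRNA absent from the read set is invisible regardless of
its precursor; the degradome test models tag placement as uniform
multinomial background, not transcript-coverage-biased; and the
rule-based target scorer deliberately reproduces a fixed published
parameterization rather than a trainable model.
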