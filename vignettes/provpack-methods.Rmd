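---
title: "Methods: engineering and QC of AAV proviral plasmids with provpack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engineering and QC of AAV proviral plasmids with provpack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provpack)
```

## The problem

Recombinant AAV vectors are produced from a circular proviral (transfer)
plasmid whose ITR-flanked payload is the intended genome. A small fraction of
capsids instead package the ITR-flanked *backbone* of that plasmid
(cross-packaging), delivering bacterial and phage sequence — kanamycin
resistance gene, replication origins — into patients. Because AAV ITRs have
intrinsic promoter activity, cross-packaged prokaryotic ORFs can be
transcribed and translated in vivo. `provpack` implements both halves of a
mitigation-and-verification workflow:

1. **Design**: edit a base scAAV proviral plasmid so that (a) any
   cross-packaged genome is mostly benign human intron ("stuffer arm")
   sequence rather than bacterial DNA, (b) residual transcripts cannot
   initiate translation (every ATG in the arms mutated to ATT), (c) any
   read-through is terminated (stop cassettes with TAG in all three frames),
   and (d) ITR promoter activity is insulated by flanking CTCF-binding sites.
2. **QC**: classify packaged-genome sequencing reads into
   insert / backbone / RepCap / helper / host categories, quantify
   cross-packaging, and profile long reads for truncation hotspots and the
   bacterial-vs-human origin of cross-packaged material.

Raw sequencing data for this kind of experiment is typically not public, so
the package ships a seeded simulator that generates packaged-genome
populations with ground-truth labels; every statistical claim made by the
test suite is a recovery of a quantity the simulator planted.

## The edit series

`build_series()` starts from a base construct (C1: 2,052-bp ITR-to-ITR
insert in a 3,523-bp backbone; `synthetic_c1()` builds a stand-in with that
exact architecture) and produces four successively modified plasmids:

| step | addition | location |
|------|----------|----------|
| C2 | stop cassette + CTCF site + ATG-scrubbed 2,700-bp intron arm | backbone, mITR side |
| C3 | stop cassette + CTCF site + ATG-scrubbed 2,402-bp intron arm | backbone, ITR side |
| C4 | stop cassette + CTCF site | inside the insert, mITR side |
| C5 | CTCF site + stop cassette | inside the insert, ITR side |

The stop cassette always sits between the ITR and the CTCF site, so
ITR-driven transcripts meet a stop in every frame before anything else. The
insert-side additions total 182 bp (two 11-bp cassettes, two 80-bp sites).

Design choices worth stating explicitly:

* **Coordinates** are 0-based half-open internally; GenBank output converts
  to 1-based inclusive. Circular constructs are rotation-normalized so the
  mITR starts at offset 0, which makes insertion and arm arithmetic
  unambiguous; features may not wrap the origin after normalization.
* **Cloning mechanics are abstracted.** The real series was built through
  specific restriction sites (AseI, PvuI, AscI, BamHI/SacII); `provpack`
  models these as anchored insertions next to named features, because the
  published record specifies adjacency, not junction sequences.
* **Default stop cassette** is `TAGGTAGGTAG`: 11 bp with TAG at offsets
  0/4/8, covering all three frames (`verify_three_frame_stops()` accepts any
  user cassette that satisfies the same predicate). The exact synthesized
  cassette is not public; this is the shortest clean sequence satisfying the
  stated constraint while keeping the insert-side additions near the
  documented ~180 bp.
* **CTCF sites and intron arms are synthetic stand-ins** (random sequences of
  the documented lengths, 80 bp and 2,700/2,402 bp) because the published
  sequences are in unavailable supplementary material. They are labelled as
  stand-ins wherever they appear.
* **`scrub_atg()` defaults to the forward strand**, the orientation in which
  the cassettes were synthesized. Whether reverse-strand ATGs were also
  scrubbed in the original constructs is not stated; `strands = "both"` is
  offered because ITRs at both ends can drive transcription in either
  direction, but it is not the default.
* **`check_capacity()`** measures, for each ITR, the contiguous run of
  non-bacterial/non-phage backbone sequence adjacent to it (the "protective
  arm", capped at the full backbone arc) and compares both arms to the
  packaging limit (2,300 bp self-complementary, 4,700 bp single-stranded).
  This operationalizes the safety argument: if both arms exceed capacity, a
  cross-packaged genome that fits in a capsid cannot reach bacterial
  sequence. Unannotated backbone bases are conservatively treated as
  bacterial vector sequence.

```{r design}
c1 <- synthetic_c1()
series <- build_series(c1, default_design_spec())
vapply(series, length, integer(1))
check_capacity(series$C5, "sc")[c("arm_lengths", "arms_exceed_capacity")]
```

## The simulator

`prep_model()` + `simulate_prep()` draw genome categories from a multinomial
whose default mirrors a first-generation AAV2 prep: 95.65% insert, 1.90%
cross-packaged backbone, and 2.45% "other" split across RepCap, helper and
host sources. Within insert genomes, a fraction (default 0.5, i.e. roughly
half of packaged genomes) is truncated at a breakpoint drawn from a hotspot
mixture; the default plants two hotspots flanking the miRNA hairpin at
±15 bp, equal weights. Truncation is modeled as one-sided shortening — the
retained segment runs from the breakpoint to the ITR-side end — which is the
observable consistent with truncations that remove the upstream U6 promoter;
internal double-break deletions are not modeled. Backbone genomes span the
ITR-flanked backbone arc (both ITRs plus everything between them on the
backbone side), so their origin composition is inherited from the construct's
feature annotations.

Reads: `emit_short_reads()` places `depth` uniform fragments per genome and
emits 2×150 pairs (fragment length uniform on 250–450 bp, clipped to the
genome; shorter genomes emit full-length reads); `emit_long_reads()` emits
one full-molecule read per genome. Errors are uniform per-base substitutions
(default 0.001); no indels, no quality model, no coverage bias — which is
exactly why passing recovery tests demonstrate correctness of the
*computation*, not robustness to real instrument artifacts. All sampling
derives from one integer seed; a fixed seed reproduces the truth table
bit-exactly. Host contaminants are drawn from a small synthetic decoy, not a
genome assembly, keeping everything desk-scale.

What the simulator deliberately does not emulate: ITR secondary structure and
flip/flop orientation, chimeric reads, replication intermediates, PCR
duplicates, and any sequence homology between the helper plasmids and the
construct backbone (real helper plasmids share vector-backbone sequence with
proviral plasmids; the stand-ins are random and therefore separable — real
data would show some genuinely ambiguous reads).

## The classifier

`reference_set()` indexes a per-sample concatenated reference — construct
(split into the ITR-to-ITR insert interval and the backbone complement),
RepCap, helper, host — as exact k-mers on both strands (default k = 31, odd
so that a construct k-mer has a strict insert/backbone base majority).
`classify_reads()` scores each read by the number of read positions covered
by k-mer hits per category; the call is the argmax over
insert/backbone/RepCap/helper, an exact tie is `ambiguous`, a read with no
hits falls back to the host decoy, and `unassigned` means nothing matched.
Junction-spanning reads therefore go to the majority-base category, matching
how position-based mapping would count them. Mates are classified
independently and reconciled (`reconcile_pairs()`): agreement stands, an
`unassigned` mate defers, any other conflict is `ambiguous`.

This is deliberately alignment-free and dependency-free: packaged-genome QC
needs category calls, not base-level alignments, and exact k-mer evidence is
deterministic and fast (about 100,000 genome pairs per half-minute on one
core). For real data produced by an external mapper, alignment intervals can
be ingested directly (`read_paf_intervals()`, or any data frame of target
intervals).

"Unique mapped reads" — the summary denominator — is interpreted as
*unambiguously assigned* reads; `ambiguous`/`unassigned` are excluded and
reported separately. Percentages are rounded half-up to 2 decimals for
presentation (exact values retained); insert:backbone ratios are reported
exactly and as integers, with an infinity sentinel when the backbone count is
zero. Feeding the published per-sample read counts through
`classification_summary()` reproduces the published percentage table; one
cell of the printed "other" column (C4, 2.44%) recomputes to 2.43% from its
own printed counts, and the recomputed value is what the package asserts.

Host-aligned reads are attributed to genes with a ≥15-bp overlap rule
(`assign_reads_to_genes()`, backed by GenomicRanges); a read may count toward
several overlapping genes.

## The long-read profiler

`align_long_reads()` anchors each read with a handful of exact k-mers
(default k = 21, 12 anchors) and takes the majority alignment diagonal, which
is exact for contiguous substitution-error reads; both strands are tried.
`locate_breakpoints()` then calls a breakpoint wherever a read end falls
strictly inside the profiled interval, at least `min_anchor` (10 bp) from its
termini — natural full-length ends are never breakpoints.
`call_hotspots()` merges ends greedily around frequency peaks (±5 bp, so a
site spans at most 11 bp and dense uniform ends cannot chain into one giant
cluster) and reports sites above a frequency threshold (default 1%).
`promoter_loss_fraction()` is the fraction of aligned reads whose span fails
to cover the U6 interval, and `composition()` tallies aligned backbone bases
by feature origin (bacterial+phage pooled vs human vs other; ITR bases belong
to the insert interval and are excluded, and unannotated backbone bases count
as bacterial).

Numerical conventions: the ±5-bp merge window absorbs end jitter without
letting clusters grow unboundedly; `min_anchor` separates truncation ends
from terminal breathing; reads that cannot be anchored are skipped and
counted, never silently dropped; empty inputs raise errors rather than
returning NaN fractions.

## Report statistics

`paired_t_test()` (a thin wrapper over the classical paired t) optionally
log-transforms yields; the log base cannot affect t or p (it rescales all
differences by one constant), and base 10 is used for reporting.
Exact ties (zero-variance differences) raise an error rather than returning
p = 1. `group_summary()` returns mean, sample SD and SEM with 2-decimal
presentation fields. `dose_contaminant_load()` multiplies a vector-genome
dose by a cross-packaged percentage and reports 2 significant figures, the
precision used in dose discussions. `compare_constructs()` reports percent
change under **both** conventions — remaining fraction mean(B)/mean(A) and
reduction 1 − mean(B)/mean(A) — because the two are easily conflated when a
~46% remaining fraction meets a ~54% reduction; the package labels both and
adjudicates neither.

## Problem sizes and what the tests show

The shipped checks use a 100,000-genome prep (200,000 mates) for classifier
recovery, 20,000 genomes for long-read truncation profiling, and 2,000–3,000
backbone-only genomes for composition recovery; planted quantities are
accepted within 3 binomial standard deviations of their expectations, and
exact-arithmetic claims (table percentages, dose loads, truncation-site
fractions) are asserted at the printed precision. Passing these shows that
the computations are correct under the simulator's assumptions; it does not
certify performance on real preps, where mapping ambiguity, helper-plasmid
homology and instrument artifacts add error modes the simulator excludes by
design.

## Known limitations

* GenBank I/O is minimal (misc_feature spans with label/role/origin
  qualifiers), intended for round-tripping this package's constructs, not
  arbitrary vendor files; FASTA + feature-TSV is the robust interchange
  format.
* The classifier's k-mer evidence assumes references without long shared
  repeats; identical sequence shared across categories inflates both
  categories' matched bases and resolves as `ambiguous` rather than by
  mapping quality.
* Truncation profiling assumes substitution-only errors (CCS-like reads);
  indel-rich reads would break the constant-diagonal assumption and should be
  ingested as external alignments instead.
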