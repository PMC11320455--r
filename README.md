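# provpack

Engineering and sequencing QC of AAV proviral plasmids.

## The problem

Recombinant AAV gene-therapy vectors are manufactured from a circular
proviral (transfer) plasmid: a therapeutic payload flanked by inverted
terminal repeats (ITRs) sitting inside a bacterial backbone (resistance gene,
replication origins). A small percentage of capsids package the ITR-flanked
*backbone* instead of the payload — **cross-packaging** — and because ITRs
have intrinsic promoter activity, the delivered bacterial ORFs can be
expressed in patients. `provpack` is for vector engineers and sequencing-QC
analysts who need to (1) design proviral plasmids that make cross-packaged
material benign and untranslatable, and (2) quantify what actually got
packaged from short- and long-read sequencing of purified preps.

Two quantities anchor the analysis. For a prep with per-category read counts
over the unique mapped total \(U = n_\text{insert} + n_\text{backbone} +
n_\text{other}\):

* category percentages \(100\,n_c/U\) (reported to 2 decimals) and the
  insert:backbone ratio \(n_\text{insert}/n_\text{backbone}\);
* the dose-contamination load \(D \times p_\text{backbone}/100\) for a
  clinical dose of \(D\) vector genomes.

A read is classified by exact k-mer seed evidence against a concatenated
per-sample reference (construct split at the ITR outer edges into insert vs
backbone, RepCap plasmid, helper plasmid, host decoy fallback); the call is
the argmax of matched bases per category, exact ties are `ambiguous`.
Long reads are anchored by seed-and-diagonal voting; a truncation breakpoint
is a read end strictly inside the profiled interval, and hotspots are peak
positions whose merged end frequency exceeds 1%.

## Worked example

Build the insulated-stuffer edit series from a base plasmid, then simulate a
prep, classify its reads, and profile truncations:

```r
library(provpack)

c1 <- synthetic_c1()                       # 5,575-bp base proviral plasmid
series <- build_series(c1, default_design_spec())
vapply(series, length, integer(1))
#>    C2    C3    C4    C5
#>  8366 10859 10950 11041

check_capacity(series$C5, "sc")[c("arm_lengths", "arms_exceed_capacity")]
#> $arm_lengths
#> mITR  ITR
#> 2791 2493
#> $arms_exceed_capacity
#> [1] TRUE
```

Both protective arms (stop cassette + CTCF site + ATG-scrubbed intron arm)
exceed the 2,300-bp self-complementary packaging capacity, so a
cross-packaged genome that fits in a capsid cannot reach bacterial sequence.

```r
panel <- synthetic_reference_panel()
m <- prep_model(c1, panel$repcap, panel$phelper, panel$host)
prep <- simulate_prep(m, 20000, seed = 7)
sr <- emit_short_reads(prep, seed = 8)
rs <- reference_set(c1, panel$repcap, panel$phelper, panel$host)
pairs <- reconcile_pairs(classify_reads(sr$r1, rs), classify_reads(sr$r2, rs))
summarize_assignments(pairs, "AAV2.C1 (simulated)")
#> <classification_summary> AAV2.C1 (simulated)
#>   unique mapped reads: 19,988
#>   insert        19112   95.62%
#>   backbone        369    1.85%
#>   other           507    2.54%
#>   insert:backbone = 52:1   insert:other = 38:1
```

The planted mixture (95.65% insert, 1.90% backbone, 2.45% other) is
recovered within sampling noise. Long reads locate the planted truncation
hotspots flanking the miRNA hairpin and the resulting promoter loss:

```r
lr <- emit_long_reads(prep, seed = 9)
truncation_profile(lr[prep$truth$category == "insert"], c1)
#> <truncation_profile> 19112 aligned reads (0 skipped)
#>   truncated: 49.9%   promoter lost: 49.9%
#>   hotspots:
#>  position count frequency
#>       362  4797    25.10%
#>       480  4732    24.76%
#>   per-site truncation fractions:
#>     mi405      0.00%
```

The same summary arithmetic applied to a published AAV2 sequencing table
(bundled as `aav2_prep_counts()`) reproduces its printed cells:

```r
tab <- aav2_prep_counts()
classification_summary(c(insert = tab$insert[1], backbone = tab$backbone[1],
                         other = tab$other[1]), "C1")
#> <classification_summary> C1
#>   unique mapped reads: 79,646,796
#>   insert     76186037   95.65%
#>   backbone    1510889    1.90%
#>   other       1949870    2.45%
#>   insert:backbone = 50:1   insert:other = 39:1

dose_contaminant_load(2.2e14, 1.35)   # contaminant genomes at a 2.2e14-vg dose
#> [1] 3e+12
```

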