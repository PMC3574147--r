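---
title: "Methods: peak calling and RPKM-ratio enrichment for bacterial coIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling and RPKM-ratio enrichment for bacterial coIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripenrich)
```

## The analysis model

`ripenrich` analyses a pair of mapped short-read libraries from a
protein-RNA co-immunoprecipitation experiment: an IP library from a
tagged pull-down and a mock-control library from an untagged strain.
The analysis makes three assumptions about the data:

1. **Reads are unstranded.** The library preparation converts RNA to
   double-stranded cDNA without preserving orientation, so coverage is
   strand-collapsed and strand is recovered later from an independent
   TSS table mapped under the same growth conditions.
2. **One replicon, linear coordinates.** Bacterial chromosomes are
   circular, but no origin-spanning transcripts are modelled; multi-
   contig input is rejected.
3. **A single library per condition.** There is no replicate structure,
   so enrichment is a descriptive ratio, not a significance test.

The pipeline is: coverage → peak calling → quantification in both
samples → RPKM-ratio scoring → strand inference → classification →
summary. All coordinates are 1-based inclusive internally; BED and
bedGraph are converted at the I/O boundary. This convention is what
makes a peak's printed length equal `end - start + 1` (e.g. a peak at
474265–474410 has length 146).

## Parameters

| parameter | unit | default | why |
|---|---|---|---|
| `min_depth` | reads | 5 | peak definition: at least five reads per position (inclusive — "at least") |
| `min_run` | bp | 50 | minimum run of consecutive qualifying positions |
| `ratio_threshold` | — | 2 | enrichment cutoff on the RPKM ratio; boundary value counts as enriched so the partition is exhaustive |
| `control_pseudocount` | reads | 1 | keeps ratios finite when the control has zero reads in a peak; consistent with finite ">1000" ratios in real data |
| `tss_window` | bp | 500 | how far upstream of a peak a TSS may sit and still assign strand |
| `leader_max_length` | bp | 500 | maximum TSS-to-CDS distance for the leader category; 5' leaders are typically 150–400 nt |

RPKM is `count x 1e9 / (length_bp x total_mapped)`; `total_mapped` is
the number of retained uniquely mapped reads of that library, so
duplicating a library leaves RPKM and the ratio unchanged.

### Numerical and rule-level choices

* **No gap merging.** Any sub-threshold position splits a run; peaks
  are exactly the maximal qualifying runs, not extended into flanking
  sub-threshold coverage. The published definition states no merging or
  extension rule, and the reported peak lengths are consistent with raw
  runs.
* **Quantification over the union.** Whether the original analysis
  quantified control-called intervals separately is ambiguous; this
  package scores the union of intervals called in either sample, each
  quantified in both (`ip_only = TRUE` restricts to IP calls). Merged
  intervals inherit nothing: they are re-scored from the reads.
* **Read counting is any-overlap.** A read counts toward a peak when it
  overlaps by at least 1 bp. With ~35 nt reads and ≥50 nt peaks this is
  simple and monotone; no fractional assignment is attempted.
* **Unique mapping filter.** SAM records with the unmapped flag or
  mapping quality 0 are dropped; MAPQ 0 is the common aligner convention
  for ambiguous placement, matching the idea of reads "unambiguously
  matched" to the genome. The original aligner settings are unknown, so
  this is a convention, not a reconstruction.
* **Classification priority.** `trna_rrna` > `srna` > `leader` > ORF
  subclasses > `unknown`, reproducing mutually exclusive categories and
  the practice of filtering housekeeping RNAs first. Start/stop codons
  are the terminal three coding bases in strand orientation; a peak
  touching both codons without containing the CDS is `unknown` (the
  source analysis never describes that case). Ambiguous-strand peaks may
  still receive ORF categories positionally, since codon coordinates
  come from the CDS annotation, not from the peak's strand.

## What the synthetic generator emulates

`sim_config()` defaults define the study conditions at 1/100 library
scale:

* ~35 nt single-end reads (normal, sd 5, truncated at 20 bp);
* library asymmetry 100,000 : 15,000 (IP : control scale, mirroring
  ~10M : ~1.5M uniquely mapped reads);
* a 200 kb genome carrying 26 CDSs (20 ordinary + 6 with upstream
  leader TSSs), 6 tRNAs, 2 rRNAs and 6 sRNAs, non-overlapping with
  200–800 bp gaps; every CDS and sRNA gets a TSS at its 5' end;
* 20 enriched ground-truth regions — 6 sRNAs, 6 leaders and 8 ORF
  fragments cycling the four subclasses — with folds cycling through
  {5, 20, 100}; ORF fragment sizes follow the ranges observed for each
  subclass in real data (start 54–178 nt, stop 70–271 nt, internal
  52–425 nt);
* housekeeping tRNA/rRNA regions at a ~200-fold higher transcription
  rate than ordinary regions (`housekeeping_rate = 300000` vs
  `base_rate = 1500` reads/kb per unit library), always fold 1;
* a uniform background floor (`background_rate = 5` reads/kb per unit
  library, i.e. ~1% of the nominal IP scale).

Counts are Poisson: `count ~ Poisson(rate x region_kb x lib/1e5)`, the
rate multiplied by the region's fold in the IP only. Read starts are
uniform in the region and reads are clipped at region boundaries, so
category ground truth is never blurred by boundary-spanning reads.

**Why housekeeping dominance matters.** RPKM divides by the *realized*
mapped total. Extra reads drawn into enriched regions inflate the IP
denominator and compress every ratio by a factor
`C = 1 + (enriched extra reads) / (baseline reads)`; a fold-5 region is
observed near `5 / C`. This is a property of the RPKM-ratio statistic
itself, visible in any real pull-down with strong enrichment. When
tRNA/rRNA dominate both libraries — as they do in real total-RNA
pull-downs, and as the default rates enforce (rRNA+tRNA ≈ 98% of the
control) — `C ≈ 1.2` and even fold-5 regions score well above the
cutoff, while housekeeping ratios stay near 1 (slightly below, by
exactly the factor `C`). The defaults also keep ~30–45 control reads
over an ordinary 200 bp region, enough for the ratio to be stable at
desk scale; with weakly expressed regions the control count collapses
toward the pseudocount floor and ratios become erratic. Realized totals
(~1.2M IP / ~0.16M control at the defaults) are Poisson outcomes that
exceed the nominal scale factors because of the housekeeping excess;
their *ratio* equals the configured 6.67 asymmetry exactly when no
region is enriched, and exceeds it otherwise because fold enrichment
adds IP-only reads.

**What the generator does not emulate:** sequencing errors, base-level
sequence content, adapter contamination, non-uniform (GC- or
position-dependent) coverage bias, overdispersion beyond Poisson,
overlapping transcription units, and operon structure. Passing the
recovery tests therefore shows that the pipeline's logic is correct
under its own model of the data, not that the thresholds are optimal
for any particular real library.

## Strand inference and its failure modes

A plus-strand TSS supports a peak when it lies in
`[start - tss_window, end]`; a minus-strand TSS when in
`[start, end + tss_window]`. Exactly one supported strand assigns it;
both or neither yield `ambiguous`. With 500 bp windows and compact
bacterial gene spacing, a neighbouring gene on the opposite strand
occasionally places its TSS inside the window and makes a peak
ambiguous — on the synthetic genome this affects roughly 0–10% of
regions depending on the draw. Ambiguous peaks keep positional ORF
categories but can never be classified as leaders, because the leader
rule requires a strand-matched TSS.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic
data: the default 200 kb genome (~1.4M reads per study), a 60 kb
variant for unit tests, 100 random 10 kb tracks for the peak-caller
oracle, and 50 null-simulation seeds for calibration — sizes chosen so
the whole suite completes in about a minute on one core. Every random
stage is seeded through the configuration (`generate_annotation` uses
`seed`, `simulate_reads` uses `seed + 1`), and identical configurations
give bit-identical output; the pipeline itself contains no randomness.

## Known limitations

* Enrichment is descriptive; no error model, replicates or multiple
  testing. That matches the original single-library design.
* The RPKM-ratio compression described above means reported ratios are
  conservative when a large fraction of the IP library is specifically
  enriched.
* Peak boundaries are threshold crossings of raw coverage; at a region's
  5' edge the depth ramps up over a few bases, so called peaks are
  typically 1–3 bp narrower than the transcribed region and truth
  regions shorter than ~55 bp may fail the 50 bp run requirement.
* The leader rule uses the nearest downstream same-strand CDS within
  `leader_max_length`; nested or overlapping transcription units would
  need a transcript-aware annotation, which the GFF3 feature model here
  does not carry.
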