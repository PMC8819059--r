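---
title: "Scoring lncRNA-encoded peptides with pepScore"
author: "pepScore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lncRNA-encoded peptides with pepScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepScore)
```

## The problem

Long noncoding RNAs are defined by the absence of an annotated protein
product, yet ribosome profiling, proteomics and targeted studies keep
turning up lncRNA-encoded micropeptides. Any single line of evidence is
weak: a lncRNA can associate with ribosomes without productive
translation, coding-potential classifiers disagree near their decision
boundary, and a short ORF is present in almost any transcript by chance.
`pepScore` therefore treats peptide discovery as an evidence-integration
problem: call candidate ORFs under permissive, explicitly stated
conventions, map each class of evidence onto them with fixed rules, and
summarise the result as one additive score per peptide plus a
species-aware high-confidence classification.

This vignette documents the model, the conventions, the tunable
parameters, and the design decisions taken where more than one
reasonable choice existed.

## ORF calling

ORFs are called per transcript in all six frames by default
(`frames = 6`). Transcripts are single-stranded, so antisense calls are
best interpreted as a permissive screening convention inherited from
six-frame ORF finders; `frames = 3` restricts to the sense strand.

* **Start codons.** `startMode = "near-cognate"` (default) accepts ATG
  and its nine single-substitution neighbours (CTG, GTG, TTG, ACG, AAG,
  AGG, ATA, ATC, ATT), the standard near-cognate set of the
  translation-initiation literature. `"atg"` restricts to ATG.
* **Maximality.** An ORF runs from the most upstream qualifying start
  codon after the previous in-frame stop to the next in-frame stop.
  ORFs nested inside a longer call with the same stop are not reported
  separately. A consequence worth knowing: switching from ATG-only to
  near-cognate mode can move a call's start upstream, so ATG-mode
  intervals are contained in (not identical to) near-cognate intervals.
* **Coordinates.** 1-based, inclusive, on the forward transcript, stop
  codon inside the interval: a complete ORF of 354 nt encodes a
  354/3 − 1 = 117-aa peptide. Minus-strand calls are converted back to
  forward coordinates.
* **Length filter.** `minAa = 10` by default; a 10-aa floor is the
  conventional lower bound for annotatable micropeptides.
* **Stops.** `requireStop = TRUE` drops spans with no in-frame stop
  (the reported interval convention includes the stop, which only makes
  sense for stop-terminated spans); switching it off emits incomplete
  spans to the last full codon, flagged `complete = FALSE`.
* **N handling.** Codons containing `N` translate to `X`; a span whose
  start or stop codon contains `N` is never called (N-containing
  codons match neither the start set nor the stop set). This is the
  conservative reading for ambiguous bases.
* **Overlap resolution.** `selectLongestNonoverlapping()` keeps the
  longest ORF among any set of mutually overlapping calls, judging
  overlap on forward-coordinate nucleotide intervals across frames and
  strands — the strictest reading of "if peptides overlap, keep the
  longer". Ties break deterministically: smaller start, then `+`
  before `-`, then smaller frame. ORF numbering (`ORF-1`, `ORF-2`, …)
  is by descending length under the same tie-break, so `ORF-1` is
  always the longest call of its transcript.

## Evidence mapping

All mapping happens in transcript coordinates (1-based inclusive; the
on-disk track dialect is BED-like with 0-based half-open starts).
Genomic lift-over is deliberately out of scope: it belongs upstream,
and keeping the mapper in transcript space makes every rule exactly
testable.

* **Ribo-seq** (`countRiboseqHits`): a record counts when the fraction
  of the *record* overlapping the ORF is at least `minFraction = 0.9`.
  The fraction is relative to the record because that is bedtools `-f`
  query semantics, the instrument conventionally used for this step;
  `strict = TRUE` switches to a strictly-greater test for users who
  want the literal ">90%" reading. A "hit" is one track record at
  whatever granularity the user supplies (read, peak or merged
  interval); the package does not reinterpret it.
* **TIS** (`countTisHits`): a point counts anywhere inside the ORF,
  ends inclusive, since initiation-site catalogues include internal
  initiation events. `startWindow` restricts counting to
  `[start, start + w]` for stricter use.
* **m6A** (`countM6aHits`): 3' UTR m6A promotes translation, so sites
  count in the ORF-relative 3' UTR `(end, transcriptLength]`. For a
  multi-ORF transcript the "3' UTR of the lncRNA" is ambiguous;
  per-ORF is the only definition that assigns a site to a specific
  peptide, and it is the default (`m6aMode = "per_orf"`).
  `"per_transcript"` instead uses the region downstream of the most 3'
  selected ORF for every peptide of the transcript. Sites merged from
  several resources are deduplicated by (transcript, position) before
  counting, since a union of databases must not double-count.
* **Pfam** (`filterDomainHits`): hits with e-value strictly below
  `maxEvalue = 1e-4` are retained; a reader for raw
  `hmmsearch --tblout` output is included.
* **CPAT / CPC2**: consumed as per-transcript probability tables; the
  package does not re-derive them from sequence. A transcript absent
  from the table is "not assayed", mirroring species for which no
  resource exists; conflicting duplicate rows are an error.

## Scoring

For the four count-based kinds the score is the hit count divided by
the cohort median of that kind, with Ribo-seq — the most direct
evidence of translation — weighted five-fold:

$$S(k) = \frac{\mathrm{Hits}(k)}{\mathrm{Median}(k)}, \qquad
  S(\text{Ribo-seq}) = 5\,\frac{\mathrm{Hits}}{\mathrm{Median}},$$

CPAT and CPC2 probabilities pass through unchanged, and the composite
is the plain sum of the six components (checked to 1e-9 by the
`ScoredPeptides` validity method). A peptide with median-level Ribo-seq
support therefore contributes exactly 5 from that term.

Two decisions here were genuinely open:

* **Scoring mode.** Median normalization produces unbounded scores
  (hits/median, ×5 for Ribo-seq), while a presence/absence convention
  assigns 1 to any mapped peptide and 0 otherwise. Both are useful; the
  package defaults to `mode = "median_normalized"` because it is the
  fully parameterised variant, and ships `mode = "binary"` alongside.
  No silent clamping is done; `clamp = TRUE` caps median-normalized
  component scores at 1 for users who want bounded components.
* **The cohort.** The median's reference population is taken to be all
  scored peptides of the same species in the current run. Under the
  default `policy = "nonzero_only"` the median is computed over
  peptides with at least one hit, which avoids degenerate zero medians
  when a track is sparse; `"all_peptides"` computes the plain median
  and leaves the score at 0 when that median is zero. A kind with no
  hits anywhere has an undefined median and contributes 0.

**Evidence-type counting.** A count-based kind supports a peptide when
it was assayed and has ≥ 1 hit. For CPAT/CPC2 a threshold is needed;
`codingThreshold = 0.5` is both tools' conventional coding call and is
configurable. Not-assayed kinds never count, so a species with three
available resources can reach at most an evidence count of 3.

**HCP rules.** Human and mouse: Ribo-seq evidence required (these are
the species where Ribo-seq coverage is deep enough to be decisive).
Arabidopsis thaliana, C. elegans, fruit fly, rat, yeast, zebrafish:
at least 4 evidence types. Everything else: at least 3. Binomial-name
synonyms resolve automatically, and `hcpRules(overrides = ...)` changes
any species' rule. Whether the two coding-potential classifiers should
count as "pieces of evidence" at all is debatable; here they count,
under the threshold rule above.

## The simulator

`simulateTranscripts()` and `simulateEvidence()` generate a fully
synthetic study in which every downstream answer is known:

* Background sequence is drawn i.i.d. at the configured GC content and
  interleaved with a 12-mer stop cassette (`TTAATTAATTAA`, stop codons
  in all three frames of both strands) so spurious open frames stay
  short. A cassette sits flush against each side of every planted ORF;
  because the cassette length is a multiple of three, an in-frame TAA
  always ends three nucleotides before the plant's ATG, so a planted
  ORF can never be extended to an earlier start.
* Planted ORFs are ATG + random non-stop codons + a random stop, at
  10–200 aa by default. Each finished transcript is vetted by an
  internal brute-force scan (coded independently of the caller): if
  any candidate ORF overlapping a plant is at least as long as the
  plant, the transcript is redrawn. Planted ORFs therefore survive
  longest-wins selection with 100% recall by construction.
* Evidence counts are Poisson at configurable per-ORF rates (defaults:
  Ribo-seq 3, TIS 2, m6A 2, Pfam 1 — desk-scale stand-ins for the
  hit counts real resources produce); placements are uniform within
  the qualifying windows. Decoy records violate each rule by a margin
  (≤ 40% Ribo-seq overlap, TIS outside plants, m6A at or upstream of
  the stop, Pfam e-values ≥ 3e-4), so boundary tests are not flaky.
  Signal Pfam e-values are ≤ 1e-5.
* Truth counts are recomputed from the final record set by direct rule
  arithmetic inside the generator, independently of the mapper, so
  recovery tests compare two implementations.
* Everything is a pure function of `seed` (R's default Mersenne
  Twister; `simulateEvidence` uses `seed + 1` so the two stages are
  decoupled).

What the simulator does *not* emulate: ribosome-profiling periodicity
and P-site structure, m6A DRACH-motif placement, realistic length and
expression distributions, or correlated evidence across kinds. Passing
recovery tests therefore demonstrates that the mapping/scoring
machinery is correct, not that real-data evidence is this clean.

## Numerical and degenerate-input choices

* Composite additivity is asserted to a fixed 1e-9 absolute tolerance.
* Empty inputs are contracts, not errors: an empty FASTA or a
  transcript with no ORFs yields an empty report with a warning; an
  empty track counts 0 everywhere.
* Counters are invariant to record order and file chunking, and
  monotone under appended records (property-tested).
* e-values must be positive; probabilities must lie in [0, 1];
  duplicate transcript ids and conflicting coding-score rows abort.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at desk scale, chosen so the
whole suite completes in well under a half hour on one core while
still exercising every rule: oracle equivalence on 200 random 300-nt
transcripts and ≥ 500-record tracks, simulation recovery on 20–30
transcripts, and a 120-transcript run for the Poisson-rate check.

## Known limitations

* Coordinates are transcript-relative throughout; genomic lift-over
  and isoform-aware grouping belong upstream.
* The ×5 Ribo-seq weight and the evidence-type thresholds are adopted
  conventions, not fitted quantities; the package exposes them as
  parameters rather than defending them statistically.
* Cohort medians make scores comparable within a species and run, not
  across runs with different peptide sets.
* Near-cognate calling is permissive by design; users wanting
  conservative call sets should use `startMode = "atg"` and
  `frames = 3`.
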