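---
title: "Scanning sequencing traces for editing signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning sequencing traces for editing signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The problem

Deaminating enzymes edit nucleic acids in clusters. ADAR enzymes convert
adenosine to inosine in double-stranded RNA; inosine is read as guanosine, so
edited transcripts show runs of A>G mismatches against the genome (or T>C,
when the read is the reverse complement of the transcript). APOBEC3 enzymes
deaminate cytidine on the minus strand of retroelement cDNA, which surfaces
as clustered G>A mismatches after plus-strand synthesis. Capillary
("trace") archives — long reads of 400–900 bp with per-base phred scores —
are deep enough to catch both phenomena, but they also carry a systematic
base-calling artifact that mimics them: a dye chemistry defect puts a small
echo of every peak one position ahead of it, and in an `AGA` or `AGG`
context the tall `A` sub-peak can swallow the weak `G` peak, mis-calling it
`A`. The scanner's job is to find same-type mismatch runs, recognise the
artifact, and keep only editing candidates supported by high-quality base
calls.

## Pipeline and model

1. **Placement.** Traces are accepted only on long (≥ 400 bp), high-identity
   (≥ 97%), strictly ungapped, unique alignments. The internal aligner is
   seed-and-extend: exact 60-mers are hashed over the reference; each seed
   hit fixes a diagonal, and the alignment is extended along it to the
   maximal window bounded by sequence ends or by an `N` in either sequence.
   Identity counts every aligned column. Candidates at the same locus (same
   chromosome and strand, ≥ 50% reciprocal overlap) collapse into one, so
   seed hits tiling one placement cannot fake multiplicity; traces with two
   or more passing loci are discarded.
2. **Run detection.** A *run* is a maximal block of consecutive mismatches
   of one substitution type along the trace. "Consecutive" refers to the
   ordered mismatch list: matching bases between members do not break a run,
   a mismatch of a different type does. Types are kept as the 12 ordered
   substitutions in read orientation (for a minus-strand placement the
   reference base is reverse-complemented); complementary pairs such as
   A>G/T>C are aggregated only in statistics. Runs spanning under 100 bp are
   discarded as local error bursts, and — for the motif survey — runs whose
   members do not share one 3-bp trace context.
3. **Quality sets.** The *high-quality* (editing-enriched) set takes traces
   with a run of ≥ 3 same-type mismatches of any quality containing at
   least two mismatches at phred ≥ 40 separated by ≥ 100 bp; only the
   phred ≥ 40 mismatches are reported. The *low-quality* set mirrors it
   exactly with the predicate inverted (phred < 10) and characterises the
   artifact. Phred 40 means an expected error rate of 1 in 10,000, which is
   where the artifact's quality distribution dies out.
4. **Artifact detection.** Two independent routes: the motif signature
   (G>A runs in `AGA`→`AAA` or `AGG`→`AAG` context, evaluated strand-
   literally — the artifact lives in the read chemistry, not the genome)
   and the alternate-call offset test: when a base caller emits the
   second-best call per position, a sub-peak trace's alternate sequence is
   the primary sequence shifted by one, so a long block of agreement at
   offset ±1 flags the trace.
5. **Enrichment statistics.** A log-space two-sided Fisher exact test for
   contingency tables with entries up to ~10^5, a one-sided binomial tail
   for repeat-interval overlap, upstream-nucleotide context profiles in
   editing-sense orientation, SNP monomorphism against a genotype panel,
   and an editing rate per unique (deduplicated) covered base.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| min alignment length | 400 bp | excludes short, noisy placements; also the shortest capillary read simulated |
| min identity | 0.97 | tolerates hypermutated editing targets while rejecting paralogous placements |
| seed length | 60 bp | long enough to make random hits negligible, short enough to survive mismatch spacing |
| run length | 5 (motif survey) / 3 (quality sets) | 5 isolates the strong motif signal; 3 maximises sensitivity once quality filtering carries the specificity |
| run span | ≥ 100 bp | sequencing errors cluster in short mismatch-dense bursts; genuine editing clusters spread out |
| quality threshold | phred ≥ 40 (high), < 10 (low) | the artifact persists at phred 20–35 and vanishes at 40 |
| offset-test block | 50 bp | the longest chance ±1 agreement between two random 400-mers is ~log₄(400) ≈ 4; 50 leaves orders of magnitude of margin while shifted calls give blocks of hundreds |

### Two-sided Fisher convention

The two-sided p-value is the minimum-likelihood convention: the sum of
hypergeometric probabilities of all tables with the observed margins that
are no more probable than the observed table (with a 1e-7 relative guard
against ties lost to floating point). Probabilities are evaluated in log
space through the log-gamma function, so archive-scale tables remain exact
to well over ten significant digits; the test suite checks every table with
total ≤ 30 against direct enumeration via binomial coefficients, and the
large published tables against an independent implementation.

## The simulator

`simulate_cohort()` generates the study conditions the package is tested
under: a uniform-ACGT reference (default 50 kb) with a planted family of
near-identical 300 bp repeats (1% divergence, an Alu/IAP stand-in), and a
cohort of 400–900 bp traces sampled uniformly in position and strand.

* **Base quality and error.** Reads carry a flat phred-45 body degrading
  linearly over the final 20% to phred 25, echoing real capillary traces.
  Each base errs independently with probability 10^(−q/10), uniformly over
  the three alternative bases. The suite verifies the realised error rate
  against the profile in aggregate over ~2.6×10^5 bases.
* **True variation.** The sequenced individual differs from the reference
  at a rate of 10^-3 per bp (a heterozygosity-scale choice), uniformly over
  substitution types. These variants carry the position's phred, which is
  what produces the even, symmetric mismatch spectrum above phred 40.
* **RNA editing.** Half of RNA-origin traces (40% of non-artifact traces)
  receive one A>G cluster of 6 sites in transcript sense within a 350 bp
  window, span ≥ 200 bp, quals drawn from 40–50. Sites sit on sense-strand
  adenosines whose 5′ sense neighbour is non-G with 4:1 weight — a minimal
  encoding of the ADAR upstream-G depletion, sufficient for the context-
  profile checks. The transcript sense is drawn independently of the read
  strand, so about half of edited traces surface as T>C runs.
* **DNA editing.** Repeat-overlapping DNA traces receive G>A clusters
  (5 sites, span ≥ 150 bp, quals 40–50) with 5′ dinucleotide preference
  GG : GA : other of 8 : 3 : 1, after the APOBEC3 signature.
* **Artifact traces.** 15% of traces are read through the sub-peak model:
  each `AGA`/`AGG` site is mis-called with probability 0.6 and the
  alternate call sequence equals the primary shifted by +1. Mis-call phred
  scores are drawn low-skewed on [2, 35] (q = 2 + ⌊33·u²⌋): the swallowed
  G peak is a low-confidence call, and the cap at 35 < 40 makes it a
  structural property that artifact traces can never enter the
  high-quality set, while the low tail lets the phred < 10 set capture
  them — the behaviour the low-quality set exists to characterise. Artifact
  traces carry no additional background error; their mismatch load is
  already near the identity cutoff.

What the generator does **not** emulate: chromatogram peak shapes,
indel sequencing errors (the pipeline rejects gapped placements by
construction), mate-pair structure, genome-scale repeat content, and
base-caller quality miscalibration. Passing recovery tests therefore shows
that the filters separate the modelled signals at realistic rates and
qualities — not that archive data are free of failure modes outside the
model.

## Numerical and design choices

* All genomic coordinates are 0-based half-open everywhere, including BED
  output; 1-based inclusive coordinates exist only at the tabular-alignment
  boundary, where `sstart > send` encodes the minus strand.
* Any base outside `ACGTN` becomes `N` at read time, and N-handling happens
  in exactly one place downstream: extension stops at `N`, `N` columns are
  never mismatches, and a run containing an N-context member is dropped
  whole (the minimal unit larger than the mismatch that the filters
  operate on).
* The quality-set predicate is evaluated within a single run, the stricter
  of the two readings of "the trace must have two such mismatches";
  evaluating it trace-wide would let two unrelated runs combine.
* A trace with qualifying runs of several types is counted once per type;
  duplicate same-type runs count once (the run with the most passing
  mismatches is reported).
* Run-level motif uniformity splits artifact evidence across the two
  signature contexts, so trace-level artifact flagging
  (`motif_artifact_trace_flag`) groups a G>A run's members by context and
  fires when either context holds ≥ 3 members.
* Spectra over quality bins use closed-left, open-right bins; a phred-39
  call never lands in the 40 bin.
* Degenerate inputs: a zero margin gives Fisher p = 1; an empty site list
  is an error for overlap enrichment (a fraction of nothing is not 0); a
  zero coverage denominator is an error for the editing rate.

## Problem sizes in the test suite

The suite regenerates everything it tests: cohorts of 100–500 traces on
50 kb references for recovery checks, 400 traces for the spectrum shape,
500 sub-peak replicates and 1,000 random alternate-call pairs for the
artifact detector, exhaustive run-detection oracles to length 8 (plus
sampled length-12 cases), and full Fisher enumeration for all tables with
total ≤ 30. These sizes keep each property at comfortable statistical
margins while the whole suite runs in a couple of minutes.

## Limitations

* The aligner is a test-scale stand-in: it is exact for the simulated
  conditions (substitution-only, unique loci, modest references) but makes
  no claim to archive-scale sensitivity or speed; external placements can
  be ingested through the 12-column tabular format instead.
* The score semantics of the original archive-scale aligner are
  represented by their length/identity gloss (≥ 400 bp, ≥ 97%), not by a
  reimplementation of its scoring.
* Published archive-scale counts (hundreds of thousands of artifact
  traces) are functions of the 2009 archive and are not reproducible from
  a desk-scale simulation; the package reproduces the published
  self-contained statistics exactly and the archive-scale phenomena only
  qualitatively, at simulation scale.
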