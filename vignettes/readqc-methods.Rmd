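---
title: "Methods: read quality assessment, filtering and copy-number management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read quality assessment, filtering and copy-number management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readqc)
```

## Scope and data model

`readqc` operates on sets of fixed-length nucleotide reads, the data shape
produced by Illumina-class instruments (typically 30–120 bases). A
`read_set` holds, per record: an identifier, an upper-cased sequence over
{A, C, G, T, N, other}, an optional per-base Phred quality string, and an
integer copy number ≥ 1. Copy numbers default to 1 and become meaningful
aggregates once the set is *collapsed* (all sequences pairwise distinct).
Two invariants anchor the design and are enforced by the test suite:

* `total_reads = Σ count` is **exactly** conserved by deduplication,
  reverse-complement merging and sorting;
* a collapsed set has pairwise-distinct sequences.

Reads of unequal length are rejected by default (the fixed-length assumption
is what makes positional statistics a meaningful matrix); a permissive flag
admits them, in which case positional panels divide by per-position coverage.
Sequences are upper-cased on ingest and original case is discarded: every
filter here is case-insensitive in effect, so preserving case would only
create spurious distinctions during deduplication.

## File formats

FASTQ is the strict Sanger 4-line dialect, Phred+33 or Phred+64, with the
offset auto-detected by the classic range heuristic: any quality code < 59
implies Phred+33, any code > 74 implies Phred+64, and an all-ambiguous
sample defaults to Phred+33 with a warning (modern data is overwhelmingly
Phred+33). Decoded scores must lie in [0, 62]; anything else is reported as
a malformed record with its line number. FASTA input accepts wrapped
sequences; output is unwrapped. Both formats are gzip-transparent by file
suffix.

The AS format stores unique reads with copy numbers. Its on-disk dialect is
defined here (header line `#AS\tv1\tread_length=<L>\ttotal_reads=<T>`, then
`SEQUENCE\tCOUNT` per line, count-descending with lexicographic
tie-breaks, `\n` endings, no trailing blank line) and chosen to be trivially
parseable, diff-able and hand-editable. The parser validates the dialect
strictly — field count, count positivity, distinctness, ordering, and
header/body total agreement — so a corrupted file fails loudly rather than
silently skewing copy numbers. Writing FASTA/FASTQ from a collapsed set
expands each record `count` times with `/copy<k>` suffixes, conserving the
copy-number mass on disk; writing AS from a non-collapsed set deduplicates
implicitly with a notice.

One ordering question was genuinely open: the task catalogue describes
sorting "by ascending copy number" for storage while the format description
calls for descending order. We serialize AS descending (the most abundant —
and most suspect — reads first suits curation) and expose both orders in
`sort_by_copy_number()`.

## The eleven manipulation tasks

Each task is a pure `read_set → read_set` function; filters only ever drop
records, and sequence-only filters commute with deduplication on the
(sequence → count) map, a property the suite asserts against brute-force
per-read oracles. Choices worth recording:

1. **Quality filtering** — the threshold semantics were unspecified, so both
   per-base-minimum and mean-score modes are offered; the default is `min`,
   the stricter reading consistent with "each low-quality nucleotide"
   phrasing elsewhere in the catalogue.
2. **Quality masking** — bases scoring below the threshold become `N`;
   qualities and counts are untouched.
3. **Single-N expansion** — a read with exactly one `N` becomes four reads
   (N→A, C, G, T), each inheriting count and quality; the substituted
   position keeps its original quality symbol since no information exists to
   improve it. Multi-N reads pass through by default (`drop_multi_n` removes
   them). On a set with *u* single-N records and *v* others the output has
   exactly 4u + v records.
4. **Trimming** — prefix/suffix removal; must leave ≥ 1 base.
5. **Odd-character filtering** — removes reads with symbols outside ACGT
   (ACGTN with `allow_n`).
6. **Low-complexity filtering** — removes reads whose dominant symbol
   fraction exceeds the threshold; `N` counts as a fifth symbol so `NNNN…`
   is low-complexity.
7. **Template exclusion** — exact contiguous substring match against adapter
   or primer fragments, optionally including their reverse complements.
   No mismatch model: exact matching keeps the operation auditable, and
   adapter hits at 20 nt are effectively unambiguous.
8. **Top-abundance removal** — a deterministic replacement for interactive
   deletion: remove exactly `k` unique reads ranked by count descending,
   ties broken lexicographically ascending; an explicit sequence list is the
   alternative entry point.
9. **Deduplication** — sums counts over identical sequences,
   first-occurrence order, conserving `total_reads` exactly. Per-base
   quality is dropped on collapse: merged duplicates have no single
   meaningful quality string and AS carries none.
10. **Reverse-complement merging** — each pair {s, revcomp(s)} collapses
    onto the lexicographically smaller member; palindromes are untouched;
    reads containing `N` pass through unmerged with a notice (their strand
    pairing is ill-defined). Idempotent, conserves `total_reads`.
11. **Copy-number sorting** — ascending or descending, lexicographic
    tie-break; all ordering in the package uses byte-order (radix)
    comparisons so results are locale-independent.

When several tasks are requested in one CLI invocation they execute in the
catalogue order 1→11 regardless of flag order, and the order is logged —
determinism is preferred over flag-order surprises.

## Statistical summary

`compute_summary()` produces: GC and entropy histograms in weighted (by copy
number) and unique variants; the position × base composition matrix (rows
sum to 1 over covering reads); the position × {A, C, G, T, N, overall} mean
quality matrix; the copy-number spectrum; and the top-k most frequent
reads, k = 50 by default.

The per-read entropy is the five-category sum E = −Σ pᵢ ln pᵢ over
A, C, G, T, N. The five-symbol form is used deliberately (an N-rich read
should not look maximal-entropy over four categories); symbols outside the
canonical five are counted as N.

Numerical choices that a reimplementation would need: histograms use 50
equal-width bins on [0, 1] for GC and [0, ln 5] for entropy, with bin edges
reported so third-party re-plotting is exact; a value exactly at the upper
domain edge falls in the last bin. Per-position quality is the arithmetic
mean of Phred scores, not error-probability-domain averaging — the panel is
a diagnostic for *where* quality changes, and the arithmetic mean keeps the
drop depth in interpretable Phred points. The per-base quality rows average
only over positions where that base was called, which is what lets a
calibration fault confined to one nucleotide stand out.

## Sessions, checkpoints, roll-back

A session is a chain of steps over a working directory. Every step stores a
**full snapshot** of the dataset (AS when collapsed and quality-free, FASTQ
when quality is present, FASTA otherwise) rather than a delta: byte-identity
of restored state is verifiable directly, at the cost of disk — the right
trade for datasets that fit a desktop workflow. Steps are atomic: all
computation happens before any file or state is touched, so a failing task
leaves checkpoints, report and session untouched.

Roll-back repoints the session at an earlier checkpoint; subsequent steps
branch with fresh indices, and the checkpoints and report history of
abandoned branches are **kept**, enabling before/after comparison across
branches. Whether the original interactive tool discarded downstream state
on roll-back is not documented; keeping it is strictly more informative and
costs only disk. The report is an append-only plain-text log — per step:
tasks with parameters, reads/unique in and out, then every summary panel as
a labeled CSV block — and regenerating it from the session is
byte-deterministic. Replaying the logged task sequence from the original
input reproduces every checkpoint byte-identically, which the suite asserts.

## The synthetic generator

`generate_reads()` exists so that every test and the acceptance script run
without external data. It emulates exactly the defect classes the positional
panels are designed to expose, each with one knob:

* **composition skew** — i.i.d. bases from `base_probs` (e.g. A = 0.4 to
  emulate a scanner calibration bias);
* **adapter contamination** — with probability `contamination_rate` a
  template's prefix is *replaced* by the adapter (replacement, not
  insertion, preserves the fixed read length); the default adapter is the
  20-nt universal Illumina adapter prefix `AGATCGGAAGAGCACACGTC`;
* **per-cycle quality drop** — a flat per-cycle mean (default Phred 34, a
  typical healthy run) minus `drop_depth` at `drop_position`, with integer
  jitter in ±3 clipped to [0, 40], so encoding round-trips are exercised;
* **duplication** — copy numbers drawn geometric(p) with support ≥ 1
  (default p = 0.5, mean 2): a single-knob heavy-ish tail, adequate for
  exercising copy-number logic without claiming to model PCR kinetics;
* **strand structure** — duplicated copies (index ≥ 2) of N-free templates
  are reverse-complemented with probability `revcomp_rate`;
* **N injection** — per-base probability `n_rate` of masking to `N`.

Contamination and N injection are **template-level** events inherited by all
copies. This is both the physically sensible reading (they are library
artefacts of the fragment, not of one cluster) and what makes the generator
a usable oracle: adapter filtering must remove exactly the manifest-flagged
reads, and deduplication plus strand merging must recover each template's
drawn copy number exactly — per-copy artefacts would make both checks
impossible by construction. Reverse complementing is withheld from templates
containing N because strand merging deliberately leaves N reads unmerged.

Given one seed the generator is byte-deterministic. The ground-truth
manifest (one row per emitted read: template, copy index, strand,
contamination flag, N positions) is what tests score against.

What the generator does *not* emulate — cycle-dependent substitution error
matrices, quality-dependent miscalls, paired-end structure, flexible-length
chemistry — bounds what green tests mean: they certify the bookkeeping
(filters, counts, formats, checkpoints) and the statistical machinery on
data with known structure, not calling accuracy on real runs.

## Verification conditions and problem sizes

The package's end-to-end checks run at sizes chosen to make the statistics
sharp while keeping the suite fast on one CPU: contamination recovery and
bias estimation use 20,000 reads × 100 cycles; entropy bounds use 10,000
random 30-mers; conservation properties run over 100 random sets; oracle
equivalence compares every filter with naive per-read reimplementations on
sets of up to 200 reads of length ≤ 20. The positional-bias check asserts
|p̂(A) − 0.4| < 3·SE with the binomial standard error over n·L independent
bases, and therefore runs with duplication disabled (duplicated reads are
not independent draws; with duplication on, the same check would need an
effective sample size computed per template). The quality-drop check asserts
that the injected cycle is the arg-min of the mean-quality curve, which
holds whenever `drop_depth` comfortably exceeds the ±3 jitter.

## Limitations

Single-end, fixed-length reads only; no paired-end mate linkage, no
quality-aware adaptive (sliding-window) trimming, no fuzzy adapter matching,
no SAM/BAM or color-space input. Deduplication discards quality. The AS
dialect defined here is this package's own; other tools using a format of
the same name would need a converter. Sessions assume a single writer per
working directory.
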