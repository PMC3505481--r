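# readqc

Quality assessment, filtering, deduplication and copy-number management for
fixed-length short sequencing reads, in R.

Short-read instruments of the Illumina class emit millions of reads of equal
length, and every stage of a sequencing run can stamp a recognizable defect
onto them: a miscalibrated scanner skews the proportion of one nucleotide
across all cycles, adapter or primer carry-over biases the first 10–20
positions of the reads, and a mechanical disturbance during one cycle
produces a sharp dip in the per-position quality curve. `readqc` gives an
individual investigator the tools to *see* these defects in positional
statistics, *treat* them with a catalogue of eleven read-manipulation tasks,
and *keep an audit trail*: every step of an analysis is checkpointed, summarized,
and can be rolled back and branched.

## The core quantities

**Per-read Shannon entropy.** Each read is scored by

  E = −Σᵢ pᵢ ln pᵢ,  i ∈ {A, C, G, T, N},

where pᵢ is the within-read proportion of each of the five symbol
categories. E = 0 for a homopolymer, ln 4 ≈ 1.386 for an equimolar read and
ln 5 maximal; the entropy distribution separates low-complexity reads from
informative ones.

**Copy numbers and the AS format.** Deduplication collapses identical reads
into one record carrying an integer copy number, conserving the total read
count exactly; reverse-complementary pairs can be merged the same way onto a
canonical strand. The collapsed set round-trips through the plain-text
**AS (Array Subsequences)** format — unique reads with their copy numbers,
ordered by copy number descending:

```
#AS	v1	read_length=4	total_reads=11
AAAA	5
ACGT	5
TTTT	1
```

**Per-step statistics.** Every dataset (and every pipeline step) is
summarized by GC-content and entropy distributions (copy-number-weighted and
unique variants), position-by-position base composition and mean Phred
quality (overall and conditioned on the called base), the copy-number
spectrum, and the 50 most frequent reads.

## Worked example

Generate a synthetic dataset carrying all three defect classes (A-skew 0.4,
10 % adapter-contaminated templates, a 20-point quality drop at cycle 13,
geometric duplication), then strip the adapter, collapse duplicates and sort:

```r
library(readqc)
cfg <- synthetic_config(n_reads = 5000, read_length = 60,
                        base_probs = c(A = 0.4, C = 0.2, G = 0.2, T = 0.2),
                        contamination_rate = 0.1, dup_geometric_p = 0.5,
                        drop_position = 13, drop_depth = 20, seed = 7)
g <- generate_reads(cfg, fastq = "demo.fastq")
clean <- apply_tasks(g$reads, list(
  list(task = "filter_templates", templates = cfg$adapter),
  list(task = "deduplicate"),
  list(task = "sort_by_copy_number", order = "descending")), quiet = FALSE)
#> filter_templates       reads 5000 -> 4546 (records 5000 -> 4546)
#> deduplicate            reads 4546 -> 4546 (records 4546 -> 2235)
#> sort_by_copy_number    reads 4546 -> 4546 (records 2235 -> 2235)
compute_summary(clean)
#> read_stats: 4546 total reads, 2235 unique, read length 60
#>   mean GC (weighted):      0.4019
#>   mean entropy (weighted): 1.3060 nats
#>   top read: ATTAGACAGTAAAGTTCTACTTGTAGGGAGTATAGCTCAAATAGACGCAAAGTGAATAAG (x13)
```

The adapter filter removed 454 reads — the 10 % of templates flagged
contaminated in the generator's ground-truth manifest — and deduplication
collapsed 4546 reads into 2235 unique records without losing a single copy
(`total_reads` is conserved exactly). The mean GC of ≈ 0.40 reflects the
injected A-skew (A = 0.4 leaves G + C = 0.4).

The same pipeline from a shell:

```sh
exec/readqc generate demo.fastq --n 5000 --length 60 --seed 7 \
    --base-probs 0.4,0.2,0.2,0.2 --contamination-rate 0.1 \
    --drop-pos 13 --drop-depth 20 --manifest truth.tsv
exec/readqc filter demo.fastq clean.as --exclude-template AGATCGGAAGAGCACACGTC \
    --dedup --sort desc --out-format as --phred 33
exec/readqc stats clean.as --report report.txt
```

Checkpointed sessions with roll-back live behind
`session_init() / session_apply() / session_rollback() / session_report()`
(or `exec/readqc session ...`); each step writes a full dataset snapshot and
appends its summary tables to a plain-text report from which every figure
can be re-plotted with third-party software.

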