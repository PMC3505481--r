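Package: readqc
Title: Quality Assessment, Filtering and Copy-Number Management for
    Fixed-Length Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive-style quality control for fixed-length short
    sequencing reads. Reads and writes FASTA, FASTQ (Phred+33/+64, gzip)
    and the AS unique-read/copy-number format; applies eleven data
    manipulation tasks (quality filtering and masking, single-N
    expansion, trimming, odd-character and low-complexity filters,
    adapter/template exclusion, abundance pruning, deduplication with
    copy numbers, reverse-complement collapsing, copy-number sorting);
    computes per-step statistical summaries (GC and Shannon-entropy
    distributions, positional base composition and quality, copy-number
    spectrum, most-frequent reads); chains steps in a checkpointed,
    roll-back-able session with a plain-text report; and generates
    synthetic FASTQ benchmarks with controlled composition bias, adapter
    contamination, per-cycle quality drops and duplication structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
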