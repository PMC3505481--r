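#' Configuration for the synthetic read generator
#'
#' Bundles and validates the generator knobs. The generator emulates the
#' classic Illumina-style artefact classes observable in positional
#' diagnostics: a skewed single-nucleotide proportion across all cycles
#' (scanner calibration bias), adapter-contaminated read prefixes (library
#' preparation carry-over) and a sharp per-cycle quality drop (a mechanical
#' disturbance during one sequencing cycle) — plus controlled duplication
#' with geometric copy numbers, reverse-complement pairs and N injection.
#'
#' @param n_reads total number of reads to emit
#' @param read_length read length in bases (fixed across the dataset;
#'   default 100, mid-range for the 30--120 b reads this model targets)
#' @param base_probs sampling probabilities for `A`, `C`, `G`, `T`
#'   (must sum to 1; uniform by default — set e.g. `A` to 0.4 to emulate a
#'   calibration bias)
#' @param adapter adapter sequence used for prefix contamination, or `NULL`;
#'   the default is the 20-nt universal Illumina adapter prefix
#' @param contamination_rate fraction of templates whose read prefix is
#'   replaced by the adapter (default 0: clean library)
#' @param qual_mean baseline mean Phred score per cycle (default 34, a
#'   typical well-behaved run)
#' @param drop_position optional cycle at which quality drops
#' @param drop_depth Phred points subtracted at `drop_position`
#' @param dup_geometric_p success parameter of the geometric copy-number
#'   distribution (support >= 1); 1 means every template is emitted once,
#'   0.5 (the default) gives mean copy number 2 with a heavy-ish tail
#' @param revcomp_rate probability that a duplicated copy (copy index >= 2)
#'   of an N-free template is emitted as its reverse complement
#' @param n_rate per-base probability of replacing a template base with `N`
#' @param seed integer RNG seed; the same seed and config reproduce the
#'   output byte-for-byte
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_reads = 10000L, read_length = 100L,
                             base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             adapter = "AGATCGGAAGAGCACACGTC",
                             contamination_rate = 0,
                             qual_mean = 34L,
                             drop_position = NULL, drop_depth = 0L,
                             dup_geometric_p = 0.5,
                             revcomp_rate = 0, n_rate = 0,
                             seed = 1L) {
  n_reads <- as.integer(n_reads); read_length <- as.integer(read_length)
  stopifnot(n_reads >= 1L, read_length >= 1L)
  if (length(base_probs) != 4L || abs(sum(base_probs) - 1) > 1e-12 || any(base_probs < 0)) {
    stop("base_probs must be four non-negative probabilities over A,C,G,T summing to 1",
         call. = FALSE)
  }
  names(base_probs) <- c("A", "C", "G", "T")
  for (r in c(contamination_rate, revcomp_rate, n_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (dup_geometric_p <= 0 || dup_geometric_p > 1) {
    stop("dup_geometric_p must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (grepl("[^ACGT]", adapter)) stop("adapter must be over A,C,G,T", call. = FALSE)
    if (nchar(adapter) > read_length) {
      stop("adapter (", nchar(adapter), " nt) longer than read_length (",
           read_length, ")", call. = FALSE)
    }
  }
  if (contamination_rate > 0 && is.null(adapter)) {
    stop("contamination_rate > 0 requires an adapter sequence", call. = FALSE)
  }
  if (!is.null(drop_position)) {
    drop_position <- as.integer(drop_position)
    stopifnot(drop_position >= 1L, drop_position <= read_length)
  }
  structure(list(n_reads = n_reads, read_length = read_length,
                 base_probs = base_probs, adapter = adapter,
                 contamination_rate = contamination_rate,
                 qual_mean = as.integer(qual_mean),
                 drop_position = drop_position,
                 drop_depth = as.integer(drop_depth),
                 dup_geometric_p = dup_geometric_p,
                 revcomp_rate = revcomp_rate, n_rate = n_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic FASTQ dataset with a ground-truth manifest
#'
#' Draws templates with geometric copy numbers until `n_reads` reads are
#' accumulated (the last template's copies are truncated to land exactly on
#' `n_reads`), then emits each template's copies in order. Adapter
#' contamination and N injection are template-level events: all copies of a
#' contaminated template carry the adapter prefix, so duplicate collapsing
#' still recovers the drawn copy numbers exactly. Reverse-complement
#' emission applies per duplicated copy (never to the first copy, and never
#' to templates containing N, whose complement is ill-defined for strand
#' merging). Quality strings follow the configured per-cycle mean with
#' integer jitter in `[-3, 3]`, clipped to `[0, 40]`, Phred+33 encoded.
#'
#' The manifest records, per emitted read: its id, template id, copy index,
#' whether it was reverse complemented, whether it is adapter contaminated
#' and the injected N positions — the ground truth against which filter and
#' deduplication behaviour can be scored.
#'
#' @param cfg a [synthetic_config()]
#' @param fastq optional path: write the reads as FASTQ (`.gz` supported)
#' @param manifest optional path: write the manifest as TSV
#' @return a list with elements `reads` (a `read_set`), `manifest`
#'   (a data.frame) and the paths written (or `NULL`)
#' @export
generate_reads <- function(cfg, fastq = NULL, manifest = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  L <- cfg$read_length
  n <- cfg$n_reads

  # copy numbers: geometric with support >= 1, truncated to hit n exactly
  copies <- integer(0)
  tot <- 0L
  while (tot < n) {
    draw <- stats::rgeom(max(64L, n %/% 2L), cfg$dup_geometric_p) + 1L
    copies <- c(copies, draw)
    tot <- tot + sum(draw)
    if (tot >= n) break
  }
  cum <- cumsum(copies)
  n_tpl <- which(cum >= n)[1]
  copies <- copies[seq_len(n_tpl)]
  copies[n_tpl] <- copies[n_tpl] - (cum[n_tpl] - n)

  # template sequences (one row per template)
  bases <- sample(c("A", "C", "G", "T"), n_tpl * L, replace = TRUE,
                  prob = cfg$base_probs)
  tpl_mat <- matrix(bases, nrow = n_tpl, ncol = L)
  contaminated <- if (!is.null(cfg$adapter) && cfg$contamination_rate > 0) {
    stats::runif(n_tpl) < cfg$contamination_rate
  } else rep.int(FALSE, n_tpl)
  if (any(contaminated)) {
    ad <- strsplit(cfg$adapter, "", fixed = TRUE)[[1]]
    tpl_mat[contaminated, seq_along(ad)] <-
      matrix(ad, nrow = sum(contaminated), ncol = length(ad), byrow = TRUE)
  }
  n_positions <- vector("list", n_tpl)
  if (cfg$n_rate > 0) {
    nmask <- matrix(stats::runif(n_tpl * L) < cfg$n_rate, nrow = n_tpl)
    tpl_mat[nmask] <- "N"
    n_positions <- apply(nmask, 1L, which, simplify = FALSE)
  }
  tpl_seq <- do.call(paste0, as.data.frame(tpl_mat, stringsAsFactors = FALSE))
  has_n <- if (cfg$n_rate > 0) vapply(n_positions, length, integer(1)) > 0L else
    rep.int(FALSE, n_tpl)

  # per-read provenance
  tpl_of <- rep.int(seq_len(n_tpl), copies)
  copy_index <- sequence(copies)
  is_rc <- copy_index >= 2L & !has_n[tpl_of] &
    stats::runif(n) < cfg$revcomp_rate
  seqs <- tpl_seq[tpl_of]
  if (any(is_rc)) seqs[is_rc] <- reverse_complement(seqs[is_rc])

  # quality: per-cycle mean profile + integer jitter, clipped to [0, 40]
  profile <- rep.int(cfg$qual_mean, L)
  if (!is.null(cfg$drop_position)) {
    profile[cfg$drop_position] <- profile[cfg$drop_position] - cfg$drop_depth
  }
  jitter <- matrix(sample(-3:3, n * L, replace = TRUE), nrow = n)
  qmat <- pmin(pmax(sweep(jitter, 2L, profile, `+`), 0L), 40L)
  qual <- vapply(seq_len(n), function(i) intToUtf8(qmat[i, ] + 33L), character(1))

  ids <- sprintf("synth_t%06d_c%d", tpl_of, copy_index)
  man <- data.frame(
    read_id = ids,
    template_id = sprintf("t%06d", tpl_of),
    copy_index = copy_index,
    is_revcomp = is_rc,
    is_adapter_contaminated = contaminated[tpl_of],
    n_positions = vapply(tpl_of, function(t)
      paste(n_positions[[t]], collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  rs <- read_set(sequence = seqs, id = ids, quality = qual,
                 quality_encoding = "phred33")
  if (!is.null(fastq)) write_sequences(rs, fastq, format = "fastq")
  if (!is.null(manifest)) {
    utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(reads = rs, manifest = man, fastq = fastq, manifest_path = manifest,
       template_copies = data.frame(template_id = sprintf("t%06d", seq_len(n_tpl)),
                                    sequence = tpl_seq, copies = copies,
                                    stringsAsFactors = FALSE))
}
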