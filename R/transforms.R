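require_quality <- function(rs, task) {
  if (is.null(rs$quality) || rs$quality_encoding == "none") {
    stop(task, " requires per-base quality (FASTQ input); ",
         "this set carries none", call. = FALSE)
  }
}

require_collapsed <- function(rs, task) {
  if (!rs$collapsed) {
    stop(task, " requires a collapsed set with meaningful copy numbers; ",
         "run deduplicate() first", call. = FALSE)
  }
}

#' Exclude reads below a quality threshold (task 1)
#'
#' Keeps a read iff its per-base Phred scores clear `threshold`: under
#' `mode = "min"` every base must score at least `threshold` (the default,
#' strictest reading); under `mode = "mean"` the arithmetic mean score must.
#' Surviving records are unchanged.
#'
#' @param rs a `read_set` with quality (FASTQ-derived)
#' @param threshold integer Phred threshold
#' @param mode `"min"` or `"mean"`
#' @return the filtered `read_set`
#' @export
filter_by_quality <- function(rs, threshold, mode = c("min", "mean")) {
  mode <- match.arg(mode)
  require_quality(rs, "filter_by_quality")
  scores <- decode_quality(rs$quality, rs$quality_encoding, id = rs$id)
  stat <- vapply(scores, if (mode == "min") min else mean, numeric(1))
  subset_read_set(rs, stat >= threshold)
}

#' Mask low-quality bases with N (task 2)
#'
#' Every base whose Phred score falls below `threshold` is replaced by `N`
#' in the sequence. Quality strings and copy numbers are untouched, so
#' `total_reads()` is invariant.
#'
#' @inheritParams filter_by_quality
#' @return a `read_set` with low-quality positions masked
#' @export
mask_low_quality <- function(rs, threshold) {
  require_quality(rs, "mask_low_quality")
  scores <- decode_quality(rs$quality, rs$quality_encoding, id = rs$id)
  seqs <- rs$sequence
  for (i in seq_along(seqs)) {
    low <- scores[[i]] < threshold
    if (any(low)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      ch[low] <- "N"
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  rebuild_read_set(rs, sequence = seqs, collapsed = FALSE)
}

count_symbol <- function(seqs, symbol) {
  nchar(seqs) - nchar(gsub(symbol, "", seqs, fixed = TRUE))
}

#' Expand single-N reads into four alternatives (task 3)
#'
#' A read containing exactly one unknown base is replaced by four reads in
#' which the `N` is substituted by `A`, `C`, `G` and `T` in turn, each
#' inheriting the original copy number and quality string (the masked
#' position's quality symbol is retained: there is no information with which
#' to improve it). This recovers data from runs where a single damaged cycle
#' left one low-quality base in the middle of every read. Reads without `N`
#' pass through; reads with two or more `N` pass through unchanged unless
#' `drop_multi_n = TRUE` removes them.
#'
#' @param rs a `read_set`
#' @param drop_multi_n drop reads containing two or more `N`s
#' @return the expanded `read_set` (no longer marked collapsed)
#' @export
expand_single_n <- function(rs, drop_multi_n = FALSE) {
  n_n <- count_symbol(rs$sequence, "N")
  if (drop_multi_n) rs <- subset_read_set(rs, count_symbol(rs$sequence, "N") < 2L)
  n_n <- count_symbol(rs$sequence, "N")
  single <- which(n_n == 1L)
  if (length(single) == 0L) return(rs)
  keep_idx <- rep.int(seq_len(n_records(rs)), ifelse(n_n == 1L, 4L, 1L))
  base_of <- character(length(keep_idx))
  expanded_rows <- keep_idx %in% single
  base_of[expanded_rows] <- rep(c("A", "C", "G", "T"), times = length(single))
  seqs <- rs$sequence[keep_idx]
  ids <- rs$id[keep_idx]
  for (j in which(expanded_rows)) {
    seqs[j] <- sub("N", base_of[j], seqs[j], fixed = TRUE)
    ids[j] <- paste0(ids[j], "/N=", base_of[j])
  }
  rebuild_read_set(rs,
                   sequence = seqs, id = ids,
                   quality = if (!is.null(rs$quality)) rs$quality[keep_idx],
                   count = rs$count[keep_idx],
                   collapsed = FALSE)
}

#' Trim read prefixes and suffixes (task 4)
#'
#' Removes the first `prefix_len` and last `suffix_len` symbols from every
#' sequence (and quality string). Useful against adapter-biased read starts
#' and the quality decline typical of late cycles. The trim must leave at
#' least one base in every read.
#'
#' @param rs a `read_set`
#' @param prefix_len non-negative integer
#' @param suffix_len non-negative integer
#' @return the trimmed `read_set`
#' @export
trim_reads <- function(rs, prefix_len = 0L, suffix_len = 0L) {
  prefix_len <- as.integer(prefix_len); suffix_len <- as.integer(suffix_len)
  if (prefix_len < 0L || suffix_len < 0L) {
    stop("trim lengths must be non-negative", call. = FALSE)
  }
  if (n_records(rs) && prefix_len + suffix_len >= min(nchar(rs$sequence))) {
    stop(sprintf("cannot trim %d + %d symbols from reads of length %d",
                 prefix_len, suffix_len, min(nchar(rs$sequence))), call. = FALSE)
  }
  lens <- nchar(rs$sequence)
  seqs <- substr(rs$sequence, prefix_len + 1L, lens - suffix_len)
  qual <- if (!is.null(rs$quality)) {
    substr(rs$quality, prefix_len + 1L, lens - suffix_len)
  }
  rebuild_read_set(rs, sequence = seqs, quality = qual, collapsed = FALSE)
}

#' Remove reads containing odd or unknown characters (task 5)
#'
#' Drops every read whose sequence contains a symbol outside `A`, `C`, `G`,
#' `T` (outside `A`, `C`, `G`, `T`, `N` when `allow_n = TRUE`).
#'
#' @param rs a `read_set`
#' @param allow_n treat `N` as acceptable
#' @return the filtered `read_set`
#' @export
filter_odd_characters <- function(rs, allow_n = FALSE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  subset_read_set(rs, !grepl(pat, rs$sequence))
}

#' Remove low-complexity (near-homopolymer) reads (task 6)
#'
#' A read is removed iff the proportion of its most frequent symbol (over
#' the five categories `A`, `C`, `G`, `T`, `N`) exceeds `max_mono_fraction`.
#' `N` counts as a fifth symbol, so an all-N read is low complexity.
#'
#' @param rs a `read_set`
#' @param max_mono_fraction maximum tolerated single-symbol proportion,
#'   in `(0, 1]`
#' @return the filtered `read_set`
#' @export
filter_low_complexity <- function(rs, max_mono_fraction) {
  if (max_mono_fraction <= 0 || max_mono_fraction > 1) {
    stop("max_mono_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (n_records(rs) == 0L) return(rs)
  cnt <- vapply(c("A", "C", "G", "T", "N"),
                function(s) count_symbol(rs$sequence, s),
                numeric(n_records(rs)))
  if (n_records(rs) == 1L) cnt <- matrix(cnt, nrow = 1L)
  frac <- apply(cnt, 1L, max) / nchar(rs$sequence)
  subset_read_set(rs, frac <= max_mono_fraction)
}

#' Exclude reads containing template subsequences (task 7)
#'
#' Removes every read in which any template (an adapter or PCR-primer
#' fragment) occurs as an exact contiguous substring. With
#' `search_revcomp = TRUE` the reverse complement of each template is also
#' searched. Matching is exact; no mismatch model.
#'
#' @param rs a `read_set`
#' @param templates non-empty character vector of sequences over
#'   `A`, `C`, `G`, `T`
#' @param search_revcomp also search template reverse complements
#' @return the filtered `read_set`
#' @export
filter_templates <- function(rs, templates, search_revcomp = FALSE) {
  templates <- toupper(as.character(templates))
  if (length(templates) == 0L || any(nchar(templates) == 0L)) {
    stop("templates must be a non-empty list of non-empty sequences", call. = FALSE)
  }
  bad <- grepl("[^ACGT]", templates)
  if (any(bad)) {
    stop("invalid template '", templates[bad][1],
         "': only A, C, G, T are allowed", call. = FALSE)
  }
  if (search_revcomp) templates <- unique(c(templates, reverse_complement(templates)))
  hit <- rep.int(FALSE, n_records(rs))
  for (tpl in templates) {
    hit <- hit | grepl(tpl, rs$sequence, fixed = TRUE)
  }
  subset_read_set(rs, !hit)
}

#' Remove the most abundant unique reads (task 8)
#'
#' Deterministic stand-in for interactive deletion: removes exactly
#' `min(k, n_records)` unique sequences ranked by copy number descending,
#' ties broken by sequence ascending. Alternatively an explicit vector of
#' sequences to delete may be given.
#'
#' @param rs a collapsed `read_set`
#' @param k number of top-abundance sequences to remove
#' @param sequences explicit sequences to remove instead of a rank cutoff
#' @return the pruned `read_set`
#' @export
remove_top_abundant <- function(rs, k = 0L, sequences = NULL) {
  require_collapsed(rs, "remove_top_abundant")
  if (!is.null(sequences)) {
    return(subset_read_set(rs, !(rs$sequence %in% toupper(sequences))))
  }
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  if (k == 0L || n_records(rs) == 0L) return(rs)
  ord <- order(-rs$count, rs$sequence, method = "radix")
  drop <- ord[seq_len(min(k, n_records(rs)))]
  subset_read_set(rs, -drop)
}

#' Collapse duplicated reads, accumulating copy numbers (task 9)
#'
#' Merges identical sequences into one record whose count is the sum of the
#' merged counts, preserving first-occurrence order. The result is marked
#' collapsed; `total_reads()` is conserved exactly. Per-base quality is
#' dropped on collapse (merged duplicates have no single meaningful quality
#' string, and the AS format carries none).
#'
#' @param rs a `read_set`
#' @return a collapsed `read_set`
#' @export
deduplicate <- function(rs) {
  first <- !duplicated(rs$sequence)
  key <- match(rs$sequence, rs$sequence[first])
  counts <- as.integer(rowsum(rs$count, key, reorder = TRUE))
  read_set(sequence = rs$sequence[first], id = rs$id[first], count = counts,
           collapsed = TRUE, allow_mixed_length = TRUE)
}

#' Merge reverse-complementary reads (task 10)
#'
#' Each pair `{s, reverse_complement(s)}` collapses onto the
#' lexicographically smaller of the two as canonical representative, with
#' summed copy numbers; palindromic reads (their own reverse complement)
#' are untouched. Records containing `N` or other non-ACGT symbols pass
#' through unmerged with a notice (their complement is ill-defined).
#' `total_reads()` is conserved and the operation is idempotent.
#'
#' @param rs a collapsed `read_set`
#' @return a collapsed `read_set` with strand pairs merged
#' @export
merge_revcomp <- function(rs) {
  require_collapsed(rs, "merge_revcomp")
  if (n_records(rs) == 0L) return(rs)
  clean <- !grepl("[^ACGT]", rs$sequence)
  if (any(!clean)) {
    message(sum(!clean), " read(s) contain non-ACGT symbols and pass through unmerged")
  }
  canonical <- rs$sequence
  rc <- reverse_complement(rs$sequence[clean])
  canonical[clean] <- pmin(rs$sequence[clean], rc)
  first <- !duplicated(canonical)
  key <- match(canonical, canonical[first])
  counts <- as.integer(rowsum(rs$count, key, reorder = TRUE))
  read_set(sequence = canonical[first], id = rs$id[first], count = counts,
           collapsed = TRUE, allow_mixed_length = TRUE)
}

#' Sort reads by copy number (task 11)
#'
#' Reorders the records of a collapsed set by copy number, ascending or
#' descending, ties broken by sequence ascending. Contents are otherwise
#' identical. Ascending order suits manual curation of the rare tail; the
#' AS serializer always emits descending order regardless.
#'
#' @param rs a collapsed `read_set`
#' @param order `"ascending"` or `"descending"`
#' @return the reordered `read_set`
#' @export
sort_by_copy_number <- function(rs, order = c("ascending", "descending")) {
  order <- match.arg(order)
  require_collapsed(rs, "sort_by_copy_number")
  ord <- if (order == "ascending") {
    base::order(rs$count, rs$sequence, method = "radix")
  } else {
    base::order(-rs$count, rs$sequence, method = "radix")
  }
  subset_read_set(rs, ord)
}

# Registry mapping task names to implementations and their canonical
# catalogue order (1-11). apply_tasks() executes a task list; the CLI sorts
# requested tasks into this order before execution.
task_registry <- function() {
  list(
    filter_by_quality     = list(rank = 1L,  fn = filter_by_quality),
    mask_low_quality      = list(rank = 2L,  fn = mask_low_quality),
    expand_single_n       = list(rank = 3L,  fn = expand_single_n),
    trim                  = list(rank = 4L,  fn = trim_reads),
    filter_odd_characters = list(rank = 5L,  fn = filter_odd_characters),
    filter_low_complexity = list(rank = 6L,  fn = filter_low_complexity),
    filter_templates      = list(rank = 7L,  fn = filter_templates),
    remove_top_abundant   = list(rank = 8L,  fn = remove_top_abundant),
    deduplicate           = list(rank = 9L,  fn = deduplicate),
    merge_revcomp         = list(rank = 10L, fn = merge_revcomp),
    sort_by_copy_number   = list(rank = 11L, fn = sort_by_copy_number)
  )
}

#' Apply an ordered list of manipulation tasks
#'
#' Each task is a list with a `task` name (`filter_by_quality`, `mask_low_quality`,
#' `expand_single_n`, `trim`, `filter_odd_characters`,
#' `filter_low_complexity`, `filter_templates`, `remove_top_abundant`,
#' `deduplicate`, `merge_revcomp`, `sort_by_copy_number`) plus that task's
#' parameters. Tasks run in the order given.
#'
#' @param rs a `read_set`
#' @param tasks list of task descriptors, e.g.
#'   `list(list(task = "trim", prefix_len = 2), list(task = "deduplicate"))`
#' @param quiet suppress the per-task reads-in/out log lines
#' @return the transformed `read_set`
#' @export
apply_tasks <- function(rs, tasks, quiet = TRUE) {
  reg <- task_registry()
  for (t in tasks) {
    name <- t$task
    if (is.null(name) || !name %in% names(reg)) {
      stop("unknown task '", if (is.null(name)) "<missing>" else name, "'",
           call. = FALSE)
    }
    before <- c(total_reads(rs), n_records(rs))
    args <- t[setdiff(names(t), "task")]
    rs <- do.call(reg[[name]]$fn, c(list(rs), args))
    if (!quiet) {
      message(sprintf("%-22s reads %d -> %d (records %d -> %d)",
                      name, before[1], total_reads(rs), before[2], n_records(rs)))
    }
  }
  rs
}

# Sort a task list into canonical catalogue order, stable within rank.
order_tasks <- function(tasks) {
  reg <- task_registry()
  ranks <- vapply(tasks, function(t) reg[[t$task]]$rank, integer(1))
  tasks[order(ranks)]
}
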