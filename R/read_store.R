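#' Construct a read set
#'
#' A `read_set` is the package's central container: an ordered collection of
#' fixed-length sequencing reads, each with an identifier, an upper-case
#' sequence, an optional per-base Phred quality string and an integer copy
#' number. Copy numbers default to 1; they become meaningful aggregates once
#' a set has been collapsed (see [deduplicate()]).
#'
#' Sequences are upper-cased on ingest; all downstream filters are
#' case-insensitive in effect, so original case is not preserved. By default
#' all reads must share one length (the instrument model emulated here
#' produces reads of equal size); `allow_mixed_length = TRUE` admits ragged
#' sets, in which case positional statistics use per-position coverage
#' denominators.
#'
#' @param sequence character vector of read sequences. Canonical symbols are
#'   `A`, `C`, `G`, `T`, `N`; other symbols are admitted but flagged by the
#'   odd-character filter.
#' @param id optional character vector of identifiers (defaults to
#'   `read_1`, `read_2`, ...).
#' @param quality optional character vector of quality strings, one Phred
#'   symbol per base, same lengths as `sequence`.
#' @param count optional integer vector of copy numbers, all `>= 1`
#'   (default 1 per record).
#' @param quality_encoding one of `"none"`, `"phred33"`, `"phred64"`. Must
#'   be `"none"` exactly when `quality` is absent.
#' @param collapsed logical; `TRUE` asserts all sequences are pairwise
#'   distinct and counts carry original multiplicities.
#' @param allow_mixed_length logical; admit reads of unequal length.
#' @return An object of class `read_set`.
#' @examples
#' rs <- read_set(c("ACGT", "ACGT", "TTTT"))
#' total_reads(rs)
#' @export
read_set <- function(sequence, id = NULL, quality = NULL, count = NULL,
                     quality_encoding = c("none", "phred33", "phred64"),
                     collapsed = FALSE, allow_mixed_length = FALSE) {
  quality_encoding <- match.arg(quality_encoding)
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (is.null(id)) id <- if (n) paste0("read_", seq_len(n)) else character(0)
  id <- as.character(id)
  if (length(id) != n) stop("`id` must have one entry per sequence", call. = FALSE)
  if (is.null(count)) count <- rep.int(1L, n)
  if (length(count) == 1L && n > 1L) count <- rep.int(as.integer(count), n)
  count <- as.integer(count)
  if (length(count) != n) stop("`count` must have one entry per sequence", call. = FALSE)
  if (anyNA(count) || any(count < 1L)) {
    stop("copy numbers must be integers >= 1", call. = FALSE)
  }
  if (!is.null(quality)) {
    quality <- as.character(quality)
    if (length(quality) != n) {
      stop("`quality` must have one entry per sequence", call. = FALSE)
    }
    bad <- which(nchar(quality) != nchar(sequence))
    if (length(bad)) {
      stop(sprintf("quality length differs from sequence length for record '%s'",
                   id[bad[1]]), call. = FALSE)
    }
    if (quality_encoding == "none") {
      stop("quality strings present: quality_encoding must be phred33 or phred64",
           call. = FALSE)
    }
  } else if (quality_encoding != "none") {
    stop("quality_encoding given but no quality strings present", call. = FALSE)
  }
  lens <- nchar(sequence)
  if (n == 0L) {
    read_length <- 0L
  } else if (length(unique(lens)) == 1L) {
    read_length <- lens[1]
  } else if (allow_mixed_length) {
    read_length <- "mixed"
  } else {
    stop("reads have unequal lengths (", paste(utils::head(sort(unique(lens)), 5),
         collapse = ", "), ", ...); pass allow_mixed_length = TRUE to admit them",
         call. = FALSE)
  }
  if (collapsed && anyDuplicated(sequence)) {
    stop("collapsed = TRUE but sequences are not pairwise distinct", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, quality = quality, count = count,
         read_length = read_length, quality_encoding = quality_encoding,
         collapsed = isTRUE(collapsed)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d record%s (%d total reads), read length %s, quality %s%s\n",
              n_records(x), if (n_records(x) == 1) "" else "s", total_reads(x),
              as.character(x$read_length), x$quality_encoding,
              if (x$collapsed) ", collapsed" else ""))
  k <- min(6L, n_records(x))
  if (k) {
    for (i in seq_len(k)) {
      cat(sprintf("  %s  %s  x%d\n", x$id[i], x$sequence[i], x$count[i]))
    }
    if (n_records(x) > k) cat(sprintf("  ... and %d more\n", n_records(x) - k))
  }
  invisible(x)
}

#' Number of records (unique rows) in a read set
#' @param rs a `read_set`
#' @return integer record count
#' @export
n_records <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  length(rs$sequence)
}

#' Total number of reads, counting copy numbers
#'
#' The copy-number mass of a set: the sum of record counts. This quantity is
#' conserved exactly by deduplication, reverse-complement merging and
#' sorting, which the test suite asserts.
#'
#' @param rs a `read_set`
#' @return non-negative integer
#' @export
total_reads <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  sum(rs$count)
}

#' Phred offset for an encoding name
#' @param encoding `"phred33"` or `"phred64"`
#' @return integer offset (33 or 64)
#' @export
quality_offset <- function(encoding) {
  switch(encoding,
         phred33 = 33L,
         phred64 = 64L,
         stop("no Phred offset for encoding '", encoding, "'", call. = FALSE))
}

#' Decode Phred quality strings to integer scores
#'
#' Each character decodes to `utf8ToInt(char) - offset`. Decoded scores must
#' lie in `[0, 62]`; anything outside that range signals a malformed quality
#' string (typically a Phred+64 file read as Phred+33 or vice versa).
#'
#' @param quality character vector of quality strings
#' @param encoding `"phred33"` or `"phred64"`
#' @param id optional identifiers used in error messages
#' @return a list of integer vectors, one per input string
#' @examples
#' decode_quality("I", "phred33")[[1]]  # 40
#' @export
decode_quality <- function(quality, encoding, id = NULL) {
  offset <- quality_offset(encoding)
  if (is.null(id)) id <- paste0("record_", seq_along(quality))
  out <- vector("list", length(quality))
  for (i in seq_along(quality)) {
    sc <- utf8ToInt(quality[i]) - offset
    if (length(sc) && (min(sc) < 0L || max(sc) > 62L)) {
      stop(sprintf(
        "malformed quality for record '%s': decoded score outside [0, 62] under %s",
        id[i], encoding), call. = FALSE)
    }
    out[[i]] <- as.integer(sc)
  }
  out
}

#' Encode integer Phred scores as a quality string
#' @param scores integer vector of scores in `[0, 62]`
#' @param encoding `"phred33"` or `"phred64"`
#' @return a single quality string
#' @export
encode_quality <- function(scores, encoding) {
  offset <- quality_offset(encoding)
  scores <- as.integer(scores)
  if (length(scores) == 0L) return("")
  if (min(scores) < 0L || max(scores) > 62L) {
    stop("Phred scores must lie in [0, 62]", call. = FALSE)
  }
  intToUtf8(scores + offset)
}

# Subset the records of a read set, preserving metadata. `keep` is a logical
# or integer index; collapsed status survives subsetting (distinctness does).
subset_read_set <- function(rs, keep) {
  rs$id <- rs$id[keep]
  rs$sequence <- rs$sequence[keep]
  if (!is.null(rs$quality)) rs$quality <- rs$quality[keep]
  rs$count <- rs$count[keep]
  if (!identical(rs$read_length, "mixed") && length(rs$sequence) == 0L) {
    # empty sets keep their nominal read length for downstream headers
  }
  rs
}

# Replace record fields wholesale (used by transforms that rewrite sequences).
rebuild_read_set <- function(rs, sequence = rs$sequence, id = rs$id,
                             quality = rs$quality, count = rs$count,
                             quality_encoding = rs$quality_encoding,
                             collapsed = rs$collapsed) {
  read_set(sequence = sequence, id = id, quality = quality, count = count,
           quality_encoding = quality_encoding, collapsed = collapsed,
           allow_mixed_length = TRUE)
}

#' Reverse complement of nucleotide sequences
#'
#' A↔T and C↔G are swapped and the string reversed. Only `A`, `C`, `G`, `T`
#' are complemented; other symbols (including `N`) map to themselves.
#'
#' @param x character vector of sequences
#' @return character vector of reverse complements
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
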