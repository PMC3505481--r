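#' @name as_format
#' @title The AS unique-read/copy-number format
#' @description
#' The AS (Array Subsequences) format stores only the unique reads of a
#' dataset together with their copy numbers, ordered by copy number
#' descending (ties broken by sequence, ascending). The on-disk dialect is:
#'
#' ```
#' #AS<TAB>v1<TAB>read_length=<L><TAB>total_reads=<T>
#' SEQUENCE<TAB>COUNT
#' ...
#' ```
#'
#' one entry per line, `\n` line endings, no trailing blank line. The header
#' `total_reads` must equal the sum of entry counts and the entry order is
#' validated on parse. The dialect is deliberately diff-able and hand
#' editable so users can inspect or curate collapsed datasets in a text
#' editor.
NULL

format_from_path <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", basename(p)))
  switch(ext,
         fastq = , fq = "fastq",
         fasta = , fa = , fna = "fasta",
         as = "as",
         stop("cannot infer format from file name '", basename(path),
              "'; pass `format` explicitly", call. = FALSE))
}

open_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # gzfile reads both plain and gzip-compressed text transparently
  con <- gzfile(path, "rt")
  con
}

write_lines_to <- function(lines, path) {
  con <- if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    gzfile(path, "wt")
  } else {
    file(path, "wt")
  }
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Detect the Phred encoding of FASTQ quality strings
#'
#' Applies the classic range heuristic to a sample of quality strings: any
#' character code below 59 implies Phred+33 (Phred+64 scores would be
#' negative); any code above 74 implies Phred+64 (Phred+33 scores would
#' exceed 41, beyond what base callers emit). If every observed code lies in
#' the ambiguous 59--74 band, Phred+33 is assumed with a warning.
#'
#' @param quality character vector of quality strings (a sample suffices)
#' @return `"phred33"` or `"phred64"`
#' @export
detect_quality_encoding <- function(quality) {
  quality <- quality[nchar(quality) > 0L]
  if (length(quality) == 0L) {
    stop("no quality characters observed", call. = FALSE)
  }
  codes <- utf8ToInt(paste(quality, collapse = ""))
  if (min(codes) < 59L) return("phred33")
  if (max(codes) > 74L) return("phred64")
  warning("quality codes all in the ambiguous 59-74 range; assuming phred33",
          call. = FALSE)
  "phred33"
}

parse_fastq_lines <- function(lines, phred = c("auto", "33", "64")) {
  phred <- match.arg(as.character(phred), c("auto", "33", "64"))
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (truncated record near line %d)",
                 length(lines), length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(read_set(character(0)))
  }
  i1 <- seq.int(1L, by = 4L, length.out = n)
  hdr <- lines[i1]; seqs <- lines[i1 + 1L]; plus <- lines[i1 + 2L]; qual <- lines[i1 + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: record header must start with '@'",
                 i1[bad[1]]), call. = FALSE)
  }
  ids <- sub("^@", "", hdr)
  ids <- sub("[ \t].*$", "", ids)
  bad <- which(!(plus == "+" | plus == paste0("+", ids) |
                   plus == paste0("+", sub("^@", "", hdr))))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: '+' separator line inconsistent with record header",
                 i1[bad[1]] + 2L), call. = FALSE)
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: quality length (%d) differs from sequence length (%d) for record '%s'",
                 i1[bad[1]] + 3L, nchar(qual[bad[1]]), nchar(seqs[bad[1]]),
                 ids[bad[1]]), call. = FALSE)
  }
  enc <- switch(phred,
                auto = detect_quality_encoding(utils::head(qual, 1000L)),
                "33" = "phred33",
                "64" = "phred64")
  # validate decodability up front so malformed files fail at parse time
  invisible(decode_quality(qual, enc, id = ids))
  read_set(sequence = seqs, id = ids, quality = qual, quality_encoding = enc,
           allow_mixed_length = TRUE)
}

parse_fasta_lines <- function(lines) {
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, ";")
  lines <- lines[keep]
  if (length(lines) == 0L) return(read_set(character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("malformed FASTA at line 1: expected '>' header before sequence data",
         call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  ids <- sub("^>", "", lines[is_hdr])
  ids <- sub("[ \t].*$", "", ids)
  seq_lines <- split(lines[!is_hdr], rec[!is_hdr])
  seqs <- character(length(ids))
  present <- as.integer(names(seq_lines))
  seqs[present] <- vapply(seq_lines, paste, character(1), collapse = "")
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop(sprintf("malformed FASTA: record '%s' has no sequence lines",
                 ids[empty[1]]), call. = FALSE)
  }
  read_set(sequence = seqs, id = ids, allow_mixed_length = TRUE)
}

#' Parse AS-format lines into a read set
#'
#' See [as_format] for the dialect. Validation is strict: the header must be
#' well formed, every entry line must have exactly two tab-separated fields
#' with a positive integer count, sequences must be pairwise distinct, the
#' entries must be ordered by count descending (ties by sequence ascending)
#' and the header `total_reads` must equal the sum of counts.
#'
#' @param lines character vector of AS lines (no trailing blank line)
#' @return a collapsed `read_set`
#' @export
parse_as <- function(lines) {
  if (length(lines) == 0L) {
    stop("malformed AS at line 1: missing header", call. = FALSE)
  }
  m <- regmatches(lines[1],
    regexec("^#AS\tv1\tread_length=([0-9]+|mixed)\ttotal_reads=([0-9]+)$", lines[1]))[[1]]
  if (length(m) != 3L) {
    stop("malformed AS at line 1: bad header '", lines[1], "'", call. = FALSE)
  }
  total_declared <- as.integer(m[3])
  body <- lines[-1]
  if (length(body) == 0L) {
    if (total_declared != 0L) {
      stop("malformed AS: header declares ", total_declared,
           " reads but file has no entries", call. = FALSE)
    }
    return(read_set(character(0), collapsed = TRUE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed AS at line %d: expected exactly two tab-separated fields",
                 bad[1] + 1L), call. = FALSE)
  }
  seqs <- vapply(parts, `[[`, character(1), 1L)
  count_chr <- vapply(parts, `[[`, character(1), 2L)
  bad <- which(!grepl("^[0-9]+$", count_chr))
  if (length(bad)) {
    stop(sprintf("malformed AS at line %d: count '%s' is not a non-negative integer",
                 bad[1] + 1L, count_chr[bad[1]]), call. = FALSE)
  }
  counts <- as.integer(count_chr)
  bad <- which(counts < 1L)
  if (length(bad)) {
    stop(sprintf("malformed AS at line %d: count must be >= 1", bad[1] + 1L),
         call. = FALSE)
  }
  if (anyDuplicated(seqs)) {
    stop("malformed AS: duplicate sequence '", seqs[anyDuplicated(seqs)], "'",
         call. = FALSE)
  }
  ord <- order(-counts, seqs, method = "radix")
  if (!identical(ord, seq_along(seqs))) {
    stop(sprintf("malformed AS at line %d: entries not in descending-count order",
                 which(ord != seq_along(seqs))[1] + 1L), call. = FALSE)
  }
  if (sum(counts) != total_declared) {
    stop(sprintf("malformed AS: header total_reads=%d but entry counts sum to %d",
                 total_declared, sum(counts)), call. = FALSE)
  }
  read_set(sequence = seqs, id = paste0("as_", seq_along(seqs)),
           count = counts, collapsed = TRUE, allow_mixed_length = TRUE)
}

#' Serialize a collapsed read set to AS-format lines
#'
#' Entries are emitted sorted by copy number descending, ties broken by
#' sequence ascending; `parse_as(serialize_as(rs))` is the identity on the
#' (sequence, count) content. The input must already be collapsed
#' (pairwise-distinct sequences); deduplicate first otherwise.
#'
#' @param rs a `read_set` with pairwise-distinct sequences
#' @return character vector of AS lines
#' @seealso [as_format], [deduplicate()]
#' @export
serialize_as <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (anyDuplicated(rs$sequence)) {
    stop("read set contains duplicate sequences; deduplicate() before writing AS",
         call. = FALSE)
  }
  header <- sprintf("#AS\tv1\tread_length=%s\ttotal_reads=%d",
                    as.character(rs$read_length), total_reads(rs))
  if (n_records(rs) == 0L) return(header)
  ord <- order(-rs$count, rs$sequence, method = "radix")
  c(header, paste(rs$sequence[ord], rs$count[ord], sep = "\t"))
}

#' Read sequences from a FASTA, FASTQ or AS file
#'
#' The format is inferred from the file extension by default
#' (`.fastq`/`.fq`, `.fasta`/`.fa`/`.fna`, `.as`, each optionally `.gz`).
#' FASTQ quality encoding is auto-detected unless pinned with `phred`.
#' AS input yields a collapsed set with meaningful copy numbers; FASTA and
#' FASTQ records ingest with count 1 each.
#'
#' @param path path to a plain or gzip-compressed file
#' @param format `"auto"`, `"fasta"`, `"fastq"` or `"as"`
#' @param phred `"auto"`, `"33"` or `"64"` (FASTQ only)
#' @param allow_mixed_length admit reads of unequal length
#' @return a `read_set`
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq", "as"),
                           phred = "auto", allow_mixed_length = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  rs <- switch(format,
               fastq = parse_fastq_lines(lines, phred = phred),
               fasta = parse_fasta_lines(lines),
               as = parse_as(lines))
  if (!allow_mixed_length && identical(rs$read_length, "mixed")) {
    stop("reads in '", path, "' have unequal lengths; pass allow_mixed_length = TRUE",
         call. = FALSE)
  }
  rs
}

expand_counts <- function(rs) {
  if (all(rs$count == 1L)) return(rs)
  idx <- rep.int(seq_len(n_records(rs)), rs$count)
  copy_k <- sequence(rs$count)
  ids <- rs$id[idx]
  multi <- rs$count[idx] > 1L
  ids[multi] <- paste0(ids[multi], "/copy", copy_k[multi])
  rebuild_read_set(rs,
                   sequence = rs$sequence[idx], id = ids,
                   quality = if (!is.null(rs$quality)) rs$quality[idx],
                   count = rep.int(1L, length(idx)),
                   collapsed = FALSE)
}

#' Write a read set to FASTA, FASTQ or AS
#'
#' FASTA and FASTQ expansion of a collapsed set emits each sequence `count`
#' times with `/copy<k>` suffixed identifiers, so the copy-number mass is
#' conserved on disk. FASTQ output requires quality strings. AS output
#' requires a collapsed set; a non-collapsed set is implicitly deduplicated
#' with a notice. Paths ending in `.gz` are gzip-compressed.
#'
#' @param rs a `read_set`
#' @param path output path
#' @param format `"auto"` (from extension), `"fasta"`, `"fastq"` or `"as"`
#' @return the path, invisibly
#' @export
write_sequences <- function(rs, path, format = c("auto", "fasta", "fastq", "as")) {
  stopifnot(inherits(rs, "read_set"))
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  lines <- switch(format,
    fastq = {
      if (is.null(rs$quality)) {
        stop("FASTQ output requires per-base quality; write fasta or as instead",
             call. = FALSE)
      }
      ex <- expand_counts(rs)
      as.vector(rbind(paste0("@", ex$id), ex$sequence, "+", ex$quality))
    },
    fasta = {
      ex <- expand_counts(rs)
      as.vector(rbind(paste0(">", ex$id), ex$sequence))
    },
    as = {
      out <- rs
      if (anyDuplicated(out$sequence)) {
        message("AS output requires unique reads; deduplicating implicitly")
        out <- deduplicate(out)
      }
      serialize_as(out)
    })
  write_lines_to(lines, path)
}
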