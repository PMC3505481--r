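# Fixture builders --------------------------------------------------------

random_sequences <- function(n, len, alphabet = c("A", "C", "G", "T"),
                             probs = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

random_quality <- function(n, len, lo = 0L, hi = 40L, encoding = "phred33") {
  off <- if (encoding == "phred33") 33L else 64L
  vapply(seq_len(n), function(i) {
    intToUtf8(sample(lo:hi, len, replace = TRUE) + off)
  }, character(1))
}

random_read_set <- function(n, len, with_quality = FALSE,
                            alphabet = c("A", "C", "G", "T"),
                            max_count = 1L, collapsed = FALSE,
                            encoding = "phred33") {
  seqs <- random_sequences(n, len, alphabet)
  if (collapsed) {
    seqs <- unique(seqs)
    n <- length(seqs)
  }
  counts <- if (max_count > 1L) sample(seq_len(max_count), n, replace = TRUE)
            else rep.int(1L, n)
  read_set(seqs,
           quality = if (with_quality) random_quality(n, len, encoding = encoding),
           count = counts,
           quality_encoding = if (with_quality) encoding else "none",
           collapsed = collapsed)
}

write_temp_fastq <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# Independent brute-force oracles ------------------------------------------
# Deliberately naive per-read implementations built from character loops,
# kept free of the package's vectorized code paths.

oracle_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

oracle_entropy <- function(s) {
  ch <- oracle_chars(s)
  ch[!(ch %in% c("A", "C", "G", "T"))] <- "N"
  tab <- table(factor(ch, levels = c("A", "C", "G", "T", "N")))
  p <- as.numeric(tab) / length(ch)
  -sum(vapply(p, function(pi) if (pi > 0) pi * log(pi) else 0, numeric(1)))
}

oracle_keep_quality <- function(qual, offset, threshold, mode) {
  sc <- vapply(oracle_chars(qual), function(c) utf8ToInt(c) - offset, numeric(1))
  if (mode == "min") all(sc >= threshold) else mean(sc) >= threshold
}

oracle_keep_odd <- function(s, allow_n) {
  ok <- c("A", "C", "G", "T", if (allow_n) "N")
  all(oracle_chars(s) %in% ok)
}

oracle_keep_complexity <- function(s, max_frac) {
  ch <- oracle_chars(s)
  mx <- max(vapply(c("A", "C", "G", "T", "N"),
                   function(b) sum(ch == b), numeric(1)))
  mx / length(ch) <= max_frac
}

oracle_revcomp <- function(s) {
  ch <- rev(oracle_chars(s))
  paste(vapply(ch, function(c) switch(c, A = "T", C = "G", G = "C", T = "A", c),
               character(1)), collapse = "")
}

oracle_contains <- function(s, tpl) {
  k <- nchar(tpl)
  if (k > nchar(s)) return(FALSE)
  for (i in seq_len(nchar(s) - k + 1L)) {
    if (substr(s, i, i + k - 1L) == tpl) return(TRUE)
  }
  FALSE
}

oracle_keep_template <- function(s, templates, search_revcomp) {
  if (search_revcomp) {
    templates <- c(templates, vapply(templates, oracle_revcomp, character(1)))
  }
  !any(vapply(templates, function(t) oracle_contains(s, t), logical(1)))
}

# (sequence -> summed count) map of a read set, for order-insensitive
# comparisons of collapsed content
count_map <- function(rs) {
  sp <- split(rs$count, rs$sequence)
  v <- vapply(sp, sum, integer(1))
  v[order(names(v), method = "radix")]
}
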