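qrs <- function(seqs, quals, counts = NULL) {
  read_set(seqs, quality = quals, count = counts, quality_encoding = "phred33")
}

test_that("quality filtering honours min and mean thresholds", {
  rs <- qrs(c("ACGT", "ACGT", "ACGT"), c("IIII", "!!!!", "II!I"))
  # Q40,Q40,Q40,Q40 / Q0 x4 / (40,40,0,40)
  kept_min <- filter_by_quality(rs, 20, mode = "min")
  expect_identical(kept_min$quality, "IIII")
  kept_mean <- filter_by_quality(rs, 20, mode = "mean")
  expect_identical(kept_mean$quality, c("IIII", "II!I"))
  expect_error(filter_by_quality(read_set("ACGT"), 20), "quality")
})

test_that("low-quality masking replaces bases but not qualities or counts", {
  q <- intToUtf8(c(40L, 0L, 40L, 0L) + 33L)
  rs <- qrs("ACGT", q)
  out <- mask_low_quality(rs, 20)
  expect_identical(out$sequence, "ANGN")
  expect_identical(out$quality, q)
  expect_identical(total_reads(out), total_reads(rs))
  expect_identical(mask_low_quality(qrs("ACGT", "IIII"), 20)$sequence, "ACGT")
  expect_identical(mask_low_quality(qrs("ACGT", "!!!!"), 20)$sequence, "NNNN")
})

test_that("single-N reads expand to four alternatives", {
  out <- expand_single_n(read_set("ACNT"))
  expect_identical(sort(out$sequence), c("ACAT", "ACCT", "ACGT", "ACTT"))
  expect_identical(out$count, rep(1L, 4))
  expect_identical(expand_single_n(read_set("ACGT"))$sequence, "ACGT")
  expect_identical(expand_single_n(read_set("ANNT"))$sequence, "ANNT")
  expect_identical(n_records(expand_single_n(read_set("ANNT"),
                                             drop_multi_n = TRUE)), 0L)
  # quality and count inherited; N position's symbol retained
  rs <- qrs("ACNT", "IB!I", counts = 5L)
  out <- expand_single_n(rs)
  expect_identical(out$quality, rep("IB!I", 4))
  expect_identical(out$count, rep(5L, 4))
})

test_that("expansion multiplies single-N mass by four and leaves the rest", {
  set.seed(31)
  for (i in 1:10) {
    rs <- random_read_set(60, 10, alphabet = c("A", "C", "G", "T", "N"))
    nn <- vapply(strsplit(rs$sequence, "", fixed = TRUE),
                 function(ch) sum(ch == "N"), numeric(1))
    u <- sum(nn == 1L); v <- sum(nn != 1L)
    out <- expand_single_n(rs)
    expect_identical(n_records(out), as.integer(4L * u + v))
    expect_identical(total_reads(out),
                     total_reads(rs) + 3L * sum(rs$count[nn == 1L]))
  }
})

test_that("trimming cuts prefixes and suffixes of sequence and quality", {
  rs <- qrs("ACGTA", "IJKLM")
  out <- trim_reads(rs, 2, 1)
  expect_identical(out$sequence, "GT")
  expect_identical(out$quality, "KL")
  expect_identical(out$read_length, 2L)
  same <- trim_reads(rs, 0, 0)
  expect_identical(same$sequence, rs$sequence)
  expect_error(trim_reads(read_set("ACGT"), 2, 2), "cannot trim")
})

test_that("odd-character filtering distinguishes N from other symbols", {
  rs <- read_set(c("ACGX", "ACGN", "ACGT"))
  expect_identical(filter_odd_characters(rs)$sequence, "ACGT")
  expect_identical(filter_odd_characters(rs, allow_n = TRUE)$sequence,
                   c("ACGN", "ACGT"))
})

test_that("low-complexity filtering thresholds the dominant-symbol fraction", {
  rs <- read_set(c("AAAA", "AAAT", "ACGT", "NNNN"))
  out <- filter_low_complexity(rs, 0.8)
  expect_identical(out$sequence, c("AAAT", "ACGT"))
  expect_error(filter_low_complexity(rs, 0), "\\(0, 1\\]")
})

test_that("template exclusion matches exact substrings, optionally revcomp", {
  rs <- read_set(c("TTACGTTT", "TTTTTTTT"))
  expect_identical(filter_templates(rs, "ACGT")$sequence, "TTTTTTTT")
  rs2 <- read_set("CCGTTTCC")
  expect_identical(n_records(filter_templates(rs2, "AAAC")), 1L)
  expect_identical(n_records(filter_templates(rs2, "AAAC", search_revcomp = TRUE)), 0L)
  expect_error(filter_templates(rs, "ACNT"), "invalid template")
  expect_error(filter_templates(rs, character(0)), "non-empty")
})

test_that("top-abundance removal ranks by count then sequence", {
  rs <- read_set(c("AAAA", "CCCC"), count = c(5L, 2L), collapsed = TRUE)
  expect_identical(remove_top_abundant(rs, 1)$sequence, "CCCC")
  expect_identical(remove_top_abundant(rs, 0)$sequence, rs$sequence)
  tie <- read_set(c("AAAA", "CCCC", "GGGG"), count = c(3L, 3L, 1L), collapsed = TRUE)
  expect_identical(remove_top_abundant(tie, 1)$sequence, c("CCCC", "GGGG"))
  expect_identical(n_records(remove_top_abundant(tie, 10)), 0L)
  expect_identical(remove_top_abundant(tie, sequences = "CCCC")$sequence,
                   c("AAAA", "GGGG"))
  expect_error(remove_top_abundant(read_set(c("AAAA", "AAAA")), 1), "deduplicate")
})

test_that("deduplication sums counts over identical sequences", {
  out <- deduplicate(read_set(c("ACGT", "ACGT", "TTTT")))
  expect_true(out$collapsed)
  expect_identical(unname(count_map(out)), c(2L, 1L))
  uniq <- read_set(c("AAAA", "CCCC"), count = c(4L, 1L), collapsed = TRUE)
  expect_identical(count_map(deduplicate(uniq)), count_map(uniq))
  mixed <- read_set(c("ACGT", "ACGT"), count = c(2L, 1L))
  expect_identical(unname(count_map(deduplicate(mixed))), 3L)
})

test_that("reverse-complement merging picks canonical representatives", {
  out <- merge_revcomp(read_set(c("AAAA", "TTTT"), count = c(2L, 3L),
                                collapsed = TRUE))
  expect_identical(out$sequence, "AAAA")
  expect_identical(out$count, 5L)
  pal <- merge_revcomp(read_set("ACGT", count = 2L, collapsed = TRUE))
  expect_identical(pal$count, 2L)
  lone <- merge_revcomp(read_set("AAAA", collapsed = TRUE))
  expect_identical(lone$sequence, "AAAA")
  expect_message(
    nn <- merge_revcomp(read_set(c("ANAA", "TTTT"), collapsed = TRUE)),
    "unmerged")
  expect_identical(sort(nn$sequence), c("AAAA", "ANAA"))
})

test_that("merge_revcomp is idempotent and conserves reads", {
  set.seed(32)
  for (i in 1:10) {
    rs <- deduplicate(random_read_set(80, 6, max_count = 4L))
    once <- merge_revcomp(rs)
    twice <- merge_revcomp(once)
    expect_identical(count_map(twice), count_map(once))
    expect_identical(total_reads(once), total_reads(rs))
  }
})

test_that("copy-number sorting orders records without altering content", {
  rs <- read_set(c("AAAA", "CCCC"), count = c(1L, 3L), collapsed = TRUE)
  expect_identical(sort_by_copy_number(rs, "descending")$sequence,
                   c("CCCC", "AAAA"))
  expect_identical(sort_by_copy_number(rs, "ascending")$sequence,
                   c("AAAA", "CCCC"))
  tie <- read_set(c("GGGG", "AAAA"), count = c(2L, 2L), collapsed = TRUE)
  expect_identical(sort_by_copy_number(tie, "ascending")$sequence,
                   c("AAAA", "GGGG"))
  expect_error(sort_by_copy_number(read_set(c("A", "A"))), "deduplicate")
})

test_that("filters are monotone subsets and commute with deduplication", {
  set.seed(33)
  for (i in 1:8) {
    rs <- random_read_set(100, 8, alphabet = c("A", "C", "G", "T", "N", "X"))
    for (f in list(function(x) filter_odd_characters(x, allow_n = TRUE),
                   function(x) filter_low_complexity(x, 0.7),
                   function(x) filter_templates(x, c("ACG", "TTT")))) {
      out <- f(rs)
      expect_true(all(out$sequence %in% rs$sequence))
      expect_true(n_records(out) <= n_records(rs))
      # sequence-only filters commute with deduplicate on the count map
      expect_identical(count_map(deduplicate(f(rs))), count_map(f(deduplicate(rs))))
    }
  }
})

test_that("every filter matches its brute-force per-read oracle", {
  set.seed(34)
  for (i in 1:6) {
    n <- sample(50:200, 1); len <- sample(5:20, 1)
    rs <- random_read_set(n, len, with_quality = TRUE,
                          alphabet = c("A", "C", "G", "T", "N", "Y"))
    thr <- sample(5:35, 1)
    for (mode in c("min", "mean")) {
      keep <- vapply(rs$quality, oracle_keep_quality, logical(1),
                     offset = 33L, threshold = thr, mode = mode,
                     USE.NAMES = FALSE)
      expect_identical(filter_by_quality(rs, thr, mode)$id, rs$id[keep])
    }
    for (allow_n in c(TRUE, FALSE)) {
      keep <- vapply(rs$sequence, oracle_keep_odd, logical(1),
                     allow_n = allow_n, USE.NAMES = FALSE)
      expect_identical(filter_odd_characters(rs, allow_n)$id, rs$id[keep])
    }
    frac <- runif(1, 0.3, 0.9)
    keep <- vapply(rs$sequence, oracle_keep_complexity, logical(1),
                   max_frac = frac, USE.NAMES = FALSE)
    expect_identical(filter_low_complexity(rs, frac)$id, rs$id[keep])
    tpls <- random_sequences(2, sample(2:4, 1))
    for (rc in c(FALSE, TRUE)) {
      keep <- vapply(rs$sequence, oracle_keep_template, logical(1),
                     templates = tpls, search_revcomp = rc, USE.NAMES = FALSE)
      expect_identical(filter_templates(rs, tpls, search_revcomp = rc)$id,
                       rs$id[keep])
    }
  }
})

test_that("apply_tasks runs a named task chain in the order given", {
  rs <- read_set(c("ACGT", "ACGT", "TTTT", "AANA"))
  out <- apply_tasks(rs, list(list(task = "filter_odd_characters"),
                              list(task = "deduplicate"),
                              list(task = "sort_by_copy_number",
                                   order = "descending")))
  expect_identical(out$sequence, c("ACGT", "TTTT"))
  expect_identical(out$count, c(2L, 1L))
  expect_error(apply_tasks(rs, list(list(task = "nope"))), "unknown task")
})
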