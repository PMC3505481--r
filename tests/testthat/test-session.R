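session_fixture <- function() {
  td <- tempfile("sess")
  dir.create(td)
  fq <- file.path(td, "input.fastq")
  # quality '5' = Q20 under Phred+33, unambiguous for encoding detection
  write_temp_fastq(c("r1", "r2", "r3"), c("ACGT", "ACGT", "TTTT"),
                   c("5555", "5555", "5555"), fq)
  list(dir = td, fastq = fq, workdir = file.path(td, "wd"))
}

init_quiet <- function(fx) session_init(fx$fastq, fx$workdir)

test_that("a step records tasks, counts and a checkpoint", {
  fx <- session_fixture()
  s <- init_quiet(fx)
  expect_identical(s$current, 1L)
  s <- session_apply(s, list(list(task = "deduplicate")))
  st <- s$steps[[2]]
  expect_identical(unname(st$input_counts), c(3L, 3L))
  expect_identical(unname(st$output_counts), c(3L, 2L))
  expect_true(file.exists(file.path(fx$workdir, st$checkpoint)))
  # collapsed, quality-free output checkpoints as AS
  expect_match(st$checkpoint, "\\.as$")
  # identity step
  s <- session_apply(s, list())
  expect_identical(unname(s$steps[[3]]$output_counts), c(3L, 2L))
})

test_that("a failing task leaves session state, checkpoints and report unchanged", {
  fx <- session_fixture()
  s <- init_quiet(fx)
  files_before <- list.files(fx$workdir)
  report_before <- readLines(file.path(fx$workdir, "report.txt"))
  expect_error(session_apply(s, list(list(task = "trim", prefix_len = 2,
                                          suffix_len = 2))), "cannot trim")
  expect_identical(list.files(fx$workdir), files_before)
  expect_identical(readLines(file.path(fx$workdir, "report.txt")), report_before)
  expect_identical(s$current, 1L)
})

test_that("rollback restores the checkpointed dataset byte-for-byte", {
  fx <- session_fixture()
  s <- init_quiet(fx)
  snap1 <- readBin(file.path(fx$workdir, s$steps[[1]]$checkpoint), "raw", 1e6)
  s <- session_apply(s, list(list(task = "filter_templates", templates = "TTTT")))
  expect_identical(unname(s$steps[[2]]$output_counts), c(2L, 2L))
  s <- session_rollback(s, 1)
  expect_identical(s$current, 1L)
  active <- session_active(s)
  # re-serializing the active set reproduces the snapshot exactly
  p <- tempfile(fileext = ".fastq")
  write_sequences(active, p, "fastq")
  expect_identical(readBin(p, "raw", 1e6), snap1)
  # downstream checkpoints are kept; branching gets a fresh index
  s <- session_apply(s, list(list(task = "deduplicate")))
  expect_identical(s$current, 3L)
  expect_true(file.exists(file.path(fx$workdir, s$steps[[2]]$checkpoint)))
  # no-op rollback and out-of-range rollback
  s <- session_rollback(s, 3)
  expect_identical(s$current, 3L)
  expect_error(session_rollback(s, 0), "steps 1\\.\\.")
})

test_that("replaying the logged task sequence reproduces checkpoints byte-identically", {
  fx <- session_fixture()
  s <- init_quiet(fx)
  s <- session_apply(s, list(list(task = "mask_low_quality", threshold = 20)))
  s <- session_apply(s, list(list(task = "deduplicate"),
                             list(task = "sort_by_copy_number",
                                  order = "descending")))
  rs <- read_sequences(fx$fastq)
  for (i in 2:3) {
    rs <- apply_tasks(rs, s$steps[[i]]$tasks)
    p <- tempfile()
    ext <- sub(".*\\.", "", s$steps[[i]]$checkpoint)
    write_sequences(rs, p, format = ext)
    expect_identical(readBin(p, "raw", 1e6),
                     readBin(file.path(fx$workdir, s$steps[[i]]$checkpoint),
                             "raw", 1e6))
  }
})

test_that("the report keeps both branches, marks rollbacks, and regenerates identically", {
  fx <- session_fixture()
  s <- init_quiet(fx)
  s <- session_apply(s, list(list(task = "filter_templates", templates = "TTTT")))
  s <- session_rollback(s, 1)
  s <- session_apply(s, list(list(task = "deduplicate")))
  p1 <- tempfile(); p2 <- tempfile()
  session_report(s, p1); session_report(s, p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
  rep <- readLines(p1)
  expect_true(any(grepl("== step 2: filter_templates ==", rep)))
  expect_true(any(grepl("== roll-back: step 2 -> step 1 ==", rep)))
  expect_true(any(grepl("== step 3: deduplicate ==", rep)))
  # one summary block per step
  expect_identical(sum(rep == "[top_reads]"), 3L)
  # the incrementally maintained report equals the regenerated one
  expect_identical(readLines(file.path(fx$workdir, "report.txt")), rep)
})

test_that("sessions persist to disk and reload for multi-process use", {
  fx <- session_fixture()
  s <- init_quiet(fx)
  s <- session_apply(s, list(list(task = "deduplicate")))
  readqc:::session_save(s)
  s2 <- readqc:::session_load(fx$workdir)
  expect_identical(s2$current, s$current)
  expect_identical(length(s2$steps), length(s$steps))
  expect_identical(s2$steps[[2]]$checkpoint, s$steps[[2]]$checkpoint)
  expect_identical(s2$log, s$log)
  s3 <- session_apply(s2, list(list(task = "sort_by_copy_number",
                                    order = "ascending")))
  expect_identical(s3$current, 3L)
})
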