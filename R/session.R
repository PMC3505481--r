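checkpoint_ext <- function(rs) {
  if (!is.null(rs$quality) && rs$quality_encoding != "none") return("fastq")
  if (rs$collapsed) return("as")
  "fasta"
}

write_checkpoint <- function(rs, workdir, index) {
  ext <- checkpoint_ext(rs)
  path <- file.path(workdir, sprintf("step_%d.%s", index, ext))
  write_sequences(rs, path, format = ext)
  basename(path)
}

read_checkpoint <- function(workdir, file) {
  read_sequences(file.path(workdir, file), allow_mixed_length = TRUE)
}

counts_pair <- function(rs) c(total = total_reads(rs), unique = n_records(rs))

step_section <- function(index, label, tasks, before, after, stats) {
  task_lines <- if (length(tasks) == 0L) {
    "  (no tasks: identity step)"
  } else {
    vapply(tasks, function(t) {
      params <- t[setdiff(names(t), "task")]
      if (length(params) == 0L) {
        paste0("  task: ", t$task)
      } else {
        paste0("  task: ", t$task, "  ",
               paste(names(params), vapply(params, function(p)
                 paste(as.character(p), collapse = "+"), character(1)),
                 sep = "=", collapse = " "))
      }
    }, character(1))
  }
  c(sprintf("== step %d: %s ==", index, label),
    task_lines,
    sprintf("  reads in:  %d total, %d unique", before["total"], before["unique"]),
    sprintf("  reads out: %d total, %d unique", after["total"], after["unique"]),
    "",
    format_summary(stats),
    "")
}

append_report <- function(s, lines) {
  s$log <- c(s$log, lines)
  con <- file(file.path(s$workdir, "report.txt"), "at")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  s
}

#' Start an analysis session
#'
#' A session chains data-manipulation steps over a working directory. Every
#' step writes a full dataset checkpoint (AS format for collapsed
#' quality-free sets, FASTQ when quality is present, FASTA otherwise) and a
#' statistical summary, and appends a section to `report.txt`. Checkpoints
#' make every step's state recoverable byte-for-byte, which is what enables
#' [session_rollback()]. Loading the input is recorded as step 1.
#'
#' @param input path to a FASTA/FASTQ/AS file, or a `read_set`
#' @param workdir directory for checkpoints and the report (created if
#'   missing; must not already contain a session)
#' @param format input format passed to [read_sequences()]
#' @return a `read_session` object
#' @export
session_init <- function(input, workdir, format = "auto") {
  if (dir.exists(workdir) && file.exists(file.path(workdir, "report.txt"))) {
    stop("workdir '", workdir, "' already contains a session", call. = FALSE)
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  rs <- if (inherits(input, "read_set")) input else read_sequences(input, format)
  label <- if (inherits(input, "read_set")) "<in-memory read_set>" else input
  stats <- compute_summary(rs)
  cp <- write_checkpoint(rs, workdir, 1L)
  step <- list(index = 1L, label = paste0("load ", label), tasks = list(),
               input_counts = counts_pair(rs), output_counts = counts_pair(rs),
               checkpoint = cp, summary = stats)
  s <- structure(list(steps = list(step), workdir = workdir, current = 1L,
                      log = character(0)),
                 class = "read_session")
  s <- append_report(s, step_section(1L, step$label, list(),
                                     step$input_counts, step$output_counts, stats))
  s
}

#' @export
print.read_session <- function(x, ...) {
  cat(sprintf("read_session in '%s': %d step(s), current = %d\n",
              x$workdir, length(x$steps), x$current))
  for (st in x$steps) {
    cat(sprintf("  step %d%s: %s -> %d reads / %d unique [%s]\n",
                st$index, if (st$index == x$current) " *" else "",
                st$label, st$output_counts["total"], st$output_counts["unique"],
                st$checkpoint))
  }
  invisible(x)
}

#' Apply a step (an ordered list of tasks) to the session
#'
#' Loads the current checkpoint, applies the tasks in order (see
#' [apply_tasks()]), writes a new checkpoint and summary, and appends the
#' step to the chain and the report. The step is atomic: if any task fails,
#' the session, its checkpoints and its report are left unchanged and the
#' error is re-thrown.
#'
#' @param s a `read_session`
#' @param tasks list of task descriptors,
#'   e.g. `list(list(task = "deduplicate"))`
#' @param label optional human-readable step label
#' @return the updated `read_session`
#' @export
session_apply <- function(s, tasks, label = NULL) {
  stopifnot(inherits(s, "read_session"))
  rs <- read_checkpoint(s$workdir, s$steps[[s$current]]$checkpoint)
  before <- counts_pair(rs)
  # all computation happens before any file or state is touched (atomicity)
  out <- apply_tasks(rs, tasks)
  stats <- compute_summary(out)
  index <- length(s$steps) + 1L
  if (is.null(label)) {
    label <- if (length(tasks)) {
      paste(vapply(tasks, `[[`, character(1), "task"), collapse = " + ")
    } else "identity"
  }
  cp <- write_checkpoint(out, s$workdir, index)
  step <- list(index = index, label = label, tasks = tasks,
               input_counts = before, output_counts = counts_pair(out),
               checkpoint = cp, summary = stats)
  s$steps[[index]] <- step
  s$current <- index
  append_report(s, step_section(index, label, tasks, before,
                                step$output_counts, stats))
}

#' Roll back to an earlier step
#'
#' Restores the active dataset to the checkpoint of `to_index`; subsequent
#' [session_apply()] calls branch from there. Checkpoints of abandoned
#' branches are kept (read-only) and their report history is preserved, so
#' before/after comparisons across branches remain possible. The roll-back
#' event itself is logged in the report.
#'
#' @param s a `read_session`
#' @param to_index index of the step to return to
#' @return the updated `read_session`
#' @export
session_rollback <- function(s, to_index) {
  stopifnot(inherits(s, "read_session"))
  to_index <- as.integer(to_index)
  if (is.na(to_index) || to_index < 1L || to_index > length(s$steps)) {
    stop("cannot roll back to step ", to_index, ": session has steps 1..",
         length(s$steps), call. = FALSE)
  }
  from <- s$current
  s$current <- to_index
  append_report(s, c(sprintf("== roll-back: step %d -> step %d ==", from, to_index), ""))
}

#' The active dataset of a session
#'
#' Reads the checkpoint of the current step back into memory.
#'
#' @param s a `read_session`
#' @return a `read_set`
#' @export
session_active <- function(s) {
  stopifnot(inherits(s, "read_session"))
  read_checkpoint(s$workdir, s$steps[[s$current]]$checkpoint)
}

#' Write the session report
#'
#' Writes the cumulative plain-text report — per step: index, tasks and
#' parameters, reads in/out, unique in/out, then every summary panel as a
#' labeled CSV table; roll-back events are marked in place. The report is
#' deterministic given the session: regenerating it yields a byte-identical
#' file, and it retains the history of abandoned branches.
#'
#' @param s a `read_session`
#' @param path output path (defaults to `report.txt` in the workdir, which
#'   is maintained incrementally anyway)
#' @return the path, invisibly
#' @export
session_report <- function(s, path = file.path(s$workdir, "report.txt")) {
  stopifnot(inherits(s, "read_session"))
  if (length(s$steps) == 0L) stop("session has no steps", call. = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(s$log, con, sep = "\n")
  invisible(path)
}

# Persistence of session metadata (used by the CLI so that `session apply`
# invocations in separate processes share one chain). Summaries are not
# persisted; the report text carries them.
session_save <- function(s) {
  meta <- list(
    workdir = s$workdir,
    current = s$current,
    log = s$log,
    steps = lapply(s$steps, function(st) {
      st$summary <- NULL
      st$input_counts <- as.list(st$input_counts)
      st$output_counts <- as.list(st$output_counts)
      st
    })
  )
  jsonlite::write_json(meta, file.path(s$workdir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(s)
}

session_load <- function(workdir) {
  path <- file.path(workdir, "session.json")
  if (!file.exists(path)) {
    stop("no session found in '", workdir, "'; run `session init` first",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- lapply(meta$steps, function(st) {
    list(index = as.integer(st$index), label = st$label,
         tasks = lapply(st$tasks, function(t) t),
         input_counts = c(total = as.integer(st$input_counts$total),
                          unique = as.integer(st$input_counts$unique)),
         output_counts = c(total = as.integer(st$output_counts$total),
                           unique = as.integer(st$output_counts$unique)),
         checkpoint = st$checkpoint, summary = NULL)
  })
  structure(list(steps = steps, workdir = workdir,
                 current = as.integer(meta$current),
                 log = as.character(unlist(meta$log))),
            class = "read_session")
}
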