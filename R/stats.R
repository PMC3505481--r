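#' Shannon entropy of a read
#'
#' The entropy of a read is \eqn{E = -\sum_{i=1}^{5} p_i \ln p_i}, where
#' \eqn{p_i} is the within-read proportion of each of the five symbol
#' categories `A`, `C`, `G`, `T` and `N` (symbols outside the canonical four
#' are counted as `N`). Terms with \eqn{p_i = 0} contribute 0; the natural
#' logarithm is used, so `E` lies in `[0, ln 5]`: 0 for a homopolymer,
#' `ln 4` for a read with the four nucleotides in equal proportion, `ln 5`
#' maximal. Low-entropy reads flag low-complexity sequence.
#'
#' @param sequence character vector of non-empty read sequences
#' @return numeric vector of entropies (nats)
#' @examples
#' read_entropy(c("AAAA", "ACGT"))  # 0 and log(4)
#' @export
read_entropy <- function(sequence) {
  if (any(nchar(sequence) == 0L)) {
    stop("cannot compute entropy of an empty sequence", call. = FALSE)
  }
  cnt <- symbol_count_matrix(sequence)
  p <- cnt / nchar(sequence)
  terms <- ifelse(p > 0, -p * log(p), 0)
  unname(rowSums(terms))
}

# n x 5 matrix of per-read symbol counts over A,C,G,T,N; any symbol outside
# {A,C,G,T} falls in the N column.
symbol_count_matrix <- function(sequence) {
  n <- length(sequence)
  m <- matrix(0, nrow = n, ncol = 5L, dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (s in c("A", "C", "G", "T")) {
    m[, s] <- count_symbol(sequence, s)
  }
  m[, "N"] <- nchar(sequence) - rowSums(m[, 1:4, drop = FALSE])
  m
}

#' GC fraction of a read
#'
#' `(G + C) / length`; `N` and other symbols count in the denominator only.
#'
#' @param sequence character vector of non-empty read sequences
#' @return numeric vector of fractions in `[0, 1]`
#' @examples
#' gc_fraction("ACGN")  # 0.5
#' @export
gc_fraction <- function(sequence) {
  if (any(nchar(sequence) == 0L)) {
    stop("cannot compute GC fraction of an empty sequence", call. = FALSE)
  }
  (count_symbol(sequence, "G") + count_symbol(sequence, "C")) / nchar(sequence)
}

# Weighted histogram on fixed equal-width bins over [lo, hi]. Values exactly
# at hi fall in the last bin. Returns a data.frame of bin edges and masses.
weighted_hist <- function(x, w, lo, hi, n_bins) {
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- numeric(n_bins)
  agg <- rowsum(as.numeric(w), bin)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  data.frame(bin_lower = breaks[-length(breaks)], bin_upper = breaks[-1],
             reads = mass)
}

# position x symbol byte matrix helpers -------------------------------------

# For uniform-length sets, an L x n matrix of raw bytes built in one pass.
byte_matrix <- function(strings, len) {
  matrix(charToRaw(paste(strings, collapse = "")), nrow = len)
}

#' Per-step statistical summary of a read set
#'
#' Computes every panel of the per-step dataset summary as numeric tables:
#' \describe{
#'   \item{gc_hist_weighted / gc_hist_unique}{histograms of per-read GC
#'     fraction, weighting each unique read by its copy number vs by 1.}
#'   \item{entropy_hist_weighted / entropy_hist_unique}{histograms of
#'     per-read entropy ([read_entropy()]) on `[0, ln 5]`.}
#'   \item{pos_quality}{position-by-position mean Phred score, overall and
#'     conditioned on the base called at that position (columns `A`, `C`,
#'     `G`, `T`, `N`, `overall`); `NULL` when the set carries no quality.
#'     The per-base rows expose calibration faults confined to one
#'     nucleotide.}
#'   \item{pos_composition}{position-by-position proportion of each symbol
#'     (columns `A`, `C`, `G`, `T`, `N`, `other`); each row sums to 1 over
#'     the reads covering that position.}
#'   \item{copy_number_hist}{copy-number spectrum: for each copy-number
#'     value, how many unique reads carry it.}
#'   \item{top_reads}{the `k` most frequent reads (count descending, ties
#'     by sequence ascending), 50 by default.}
#' }
#' Weighted panels weight each record by its copy number; unique panels
#' ignore copy numbers. The two coincide when all counts are 1. Mixed-length
#' sets use per-position coverage denominators.
#'
#' @param rs a non-empty `read_set`
#' @param k number of top reads to list (default 50)
#' @param n_bins number of equal-width histogram bins (default 50); bin
#'   edges are reported so third-party re-plotting is exact
#' @return an object of class `read_stats`
#' @export
compute_summary <- function(rs, k = 50L, n_bins = 50L) {
  stopifnot(inherits(rs, "read_set"))
  if (n_records(rs) == 0L) stop("cannot summarize an empty read set", call. = FALSE)
  gc <- gc_fraction(rs$sequence)
  ent <- read_entropy(rs$sequence)
  w <- as.numeric(rs$count)
  gc_w <- weighted_hist(gc, w, 0, 1, n_bins)
  gc_u <- weighted_hist(gc, rep(1, length(gc)), 0, 1, n_bins)
  en_w <- weighted_hist(ent, w, 0, log(5), n_bins)
  en_u <- weighted_hist(ent, rep(1, length(ent)), 0, log(5), n_bins)

  lens <- nchar(rs$sequence)
  L <- max(lens)
  uniform <- all(lens == L)
  syms <- c("A", "C", "G", "T", "N")

  if (uniform) {
    sm <- byte_matrix(rs$sequence, L)
    cover <- rep(sum(w), L)
    counts_pos <- matrix(0, nrow = L, ncol = 6L,
                         dimnames = list(NULL, c(syms, "other")))
    for (s in syms) {
      counts_pos[, s] <- as.vector((sm == charToRaw(s)) %*% w)
    }
    counts_pos[, "other"] <- cover - rowSums(counts_pos[, syms, drop = FALSE])
  } else {
    counts_pos <- matrix(0, nrow = L, ncol = 6L,
                         dimnames = list(NULL, c(syms, "other")))
    cover <- numeric(L)
    for (i in seq_len(n_records(rs))) {
      ch <- strsplit(rs$sequence[i], "", fixed = TRUE)[[1]]
      pos <- seq_along(ch)
      cover[pos] <- cover[pos] + w[i]
      col <- ifelse(ch %in% syms, ch, "other")
      for (j in pos) counts_pos[j, col[j]] <- counts_pos[j, col[j]] + w[i]
    }
  }
  pos_composition <- counts_pos / cover

  pos_quality <- NULL
  if (!is.null(rs$quality) && rs$quality_encoding != "none") {
    off <- quality_offset(rs$quality_encoding)
    if (uniform) {
      qm <- matrix(as.integer(charToRaw(paste(rs$quality, collapse = ""))),
                   nrow = L) - off
      sm <- byte_matrix(rs$sequence, L)
      qual_cols <- matrix(NA_real_, nrow = L, ncol = 6L,
                          dimnames = list(NULL, c(syms, "overall")))
      qw <- qm %*% w
      qual_cols[, "overall"] <- as.vector(qw) / sum(w)
      for (s in syms) {
        mask <- sm == charToRaw(s)
        denom <- as.vector(mask %*% w)
        num <- as.vector((qm * mask) %*% w)
        qual_cols[, s] <- ifelse(denom > 0, num / denom, NA_real_)
      }
      pos_quality <- qual_cols
    } else {
      num <- matrix(0, nrow = L, ncol = 6L,
                    dimnames = list(NULL, c(syms, "overall")))
      den <- matrix(0, nrow = L, ncol = 6L,
                    dimnames = list(NULL, c(syms, "overall")))
      for (i in seq_len(n_records(rs))) {
        sc <- utf8ToInt(rs$quality[i]) - off
        ch <- strsplit(rs$sequence[i], "", fixed = TRUE)[[1]]
        pos <- seq_along(sc)
        num[pos, "overall"] <- num[pos, "overall"] + sc * w[i]
        den[pos, "overall"] <- den[pos, "overall"] + w[i]
        colk <- ifelse(ch %in% syms, ch, NA)
        for (j in pos) {
          if (!is.na(colk[j])) {
            num[j, colk[j]] <- num[j, colk[j]] + sc[j] * w[i]
            den[j, colk[j]] <- den[j, colk[j]] + w[i]
          }
        }
      }
      pos_quality <- ifelse(den > 0, num / den, NA_real_)
      dimnames(pos_quality) <- dimnames(num)
    }
  }

  cn <- table(rs$count)
  copy_number_hist <- data.frame(copy_number = as.integer(names(cn)),
                                 unique_reads = as.integer(cn))
  copy_number_hist <- copy_number_hist[order(copy_number_hist$copy_number), ,
                                       drop = FALSE]
  rownames(copy_number_hist) <- NULL

  ord <- order(-rs$count, rs$sequence, method = "radix")
  top <- ord[seq_len(min(k, n_records(rs)))]
  top_reads <- data.frame(sequence = rs$sequence[top], count = rs$count[top])

  structure(
    list(gc_hist_weighted = gc_w, gc_hist_unique = gc_u,
         entropy_hist_weighted = en_w, entropy_hist_unique = en_u,
         pos_quality = pos_quality, pos_composition = pos_composition,
         copy_number_hist = copy_number_hist, top_reads = top_reads,
         total_reads = total_reads(rs), unique_reads = n_records(rs),
         read_length = rs$read_length),
    class = "read_stats"
  )
}

#' @export
print.read_stats <- function(x, ...) {
  cat(sprintf("read_stats: %d total reads, %d unique, read length %s\n",
              x$total_reads, x$unique_reads, as.character(x$read_length)))
  cat(sprintf("  mean GC (weighted):      %.4f\n",
              sum((x$gc_hist_weighted$bin_lower + x$gc_hist_weighted$bin_upper) / 2 *
                    x$gc_hist_weighted$reads) / sum(x$gc_hist_weighted$reads)))
  cat(sprintf("  mean entropy (weighted): %.4f nats\n",
              sum((x$entropy_hist_weighted$bin_lower + x$entropy_hist_weighted$bin_upper) / 2 *
                    x$entropy_hist_weighted$reads) / sum(x$entropy_hist_weighted$reads)))
  cat(sprintf("  top read: %s (x%d)\n",
              x$top_reads$sequence[1], x$top_reads$count[1]))
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                sprintf("%.6g", x)))
}

csv_block <- function(title, df) {
  header <- paste(colnames(df), collapse = ",")
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  rows <- do.call(paste, c(cols, sep = ","))
  c(paste0("[", title, "]"), header, rows, "")
}

#' Render a statistical summary as labeled CSV blocks
#'
#' Produces the plain-text report form of a summary: one labeled CSV table
#' per panel, suitable for re-plotting with third-party software. The
#' rendering is deterministic given the summary.
#'
#' @param stats a `read_stats` object
#' @return character vector of report lines
#' @export
format_summary <- function(stats) {
  stopifnot(inherits(stats, "read_stats"))
  gc <- stats$gc_hist_weighted
  gc$reads_unique <- stats$gc_hist_unique$reads
  names(gc)[names(gc) == "reads"] <- "reads_weighted"
  en <- stats$entropy_hist_weighted
  en$reads_unique <- stats$entropy_hist_unique$reads
  names(en)[names(en) == "reads"] <- "reads_weighted"
  out <- c(
    sprintf("total_reads,%d", stats$total_reads),
    sprintf("unique_reads,%d", stats$unique_reads),
    sprintf("read_length,%s", as.character(stats$read_length)),
    "",
    csv_block("gc_content_distribution", gc),
    csv_block("entropy_distribution", en)
  )
  if (!is.null(stats$pos_quality)) {
    pq <- data.frame(position = seq_len(nrow(stats$pos_quality)), stats$pos_quality)
    out <- c(out, csv_block("position_quality", pq))
  }
  pc <- data.frame(position = seq_len(nrow(stats$pos_composition)),
                   stats$pos_composition)
  out <- c(out,
           csv_block("position_composition", pc),
           csv_block("copy_number_distribution", stats$copy_number_hist),
           csv_block("top_reads",
                     data.frame(rank = seq_len(nrow(stats$top_reads)),
                                stats$top_reads)))
  out
}

#' Plot the summary panels
#'
#' Base-graphics rendering of the summary: GC and entropy distributions,
#' positional mean quality, positional base composition, and the
#' copy-number spectrum.
#'
#' @param x a `read_stats` object
#' @param ... ignored
#' @return invisibly, `x`
#' @export
plot.read_stats <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  mid <- function(h) (h$bin_lower + h$bin_upper) / 2
  graphics::plot(mid(x$gc_hist_weighted), x$gc_hist_weighted$reads, type = "h",
                 xlab = "GC fraction", ylab = "reads", main = "GC content")
  graphics::plot(mid(x$entropy_hist_weighted), x$entropy_hist_weighted$reads,
                 type = "h", xlab = "entropy (nats)", ylab = "reads",
                 main = "Read entropy")
  if (!is.null(x$pos_quality)) {
    graphics::matplot(x$pos_quality[, c("A", "C", "G", "T")], type = "l",
                      lty = 1, xlab = "position", ylab = "mean Phred",
                      main = "Positional quality")
    graphics::lines(x$pos_quality[, "overall"], lwd = 2)
  } else {
    graphics::plot.new(); graphics::title("no quality data")
  }
  graphics::matplot(x$pos_composition[, c("A", "C", "G", "T", "N")], type = "l",
                    lty = 1, xlab = "position", ylab = "proportion",
                    main = "Positional composition")
  graphics::plot(x$copy_number_hist$copy_number, x$copy_number_hist$unique_reads,
                 type = "h", log = "y", xlab = "copy number",
                 ylab = "unique reads", main = "Copy-number spectrum")
  invisible(x)
}
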