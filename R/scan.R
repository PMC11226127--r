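#' Scan both strands of a genome for consensus matches
#'
#' Reports every position, on both strands, where each column set of the
#' consensus contains the corresponding base (`N` matches nothing).
#' Matching is implemented directly over column sets: the reverse strand is
#' scanned by sliding the reverse-complemented pattern along the forward
#' string, which makes strand behavior exactly symmetric. Overlapping
#' matches are all reported; a palindromic hit yields one `+` and one `-`
#' record.
#'
#' @param genome A [genome_sequence()].
#' @param pattern A [degenerate_consensus()].
#' @return A data.frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand` and `seq` (the matched sequence,
#'   5'->3' on the match strand), sorted by `start` with `+` before `-` at
#'   equal start.
#' @export
scan_genome <- function(genome, pattern) {
  stopifnot(inherits(genome, "genome_sequence"),
            inherits(pattern, "degenerate_consensus"))
  k <- length(pattern$columns)
  if (k > genome$length) {
    stop("pattern (", k, " columns) is longer than genome '", genome$id,
         "' (", genome$length, " bp)")
  }
  chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  scan_cols <- function(cols) {
    noff <- genome$length - k + 1L
    hit <- rep(TRUE, noff)
    for (j in seq_len(k)) {
      hit <- hit & chars[j:(j + noff - 1L)] %in% cols[[j]]
    }
    which(hit) - 1L
  }
  fwd <- scan_cols(pattern$columns)
  rev_ <- scan_cols(.revcomp_pattern(pattern)$columns)
  out <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+"),
    if (length(rev_)) data.frame(start = rev_, strand = "-")
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      seq = character()))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  fwd_seq <- substring(genome$seq, out$start + 1L, out$start + k)
  seqs <- ifelse(out$strand == "+", fwd_seq,
                 vapply(fwd_seq, revcomp, "", USE.NAMES = FALSE))
  data.frame(genome_id = genome$id, start = out$start, end = out$start + k,
             strand = out$strand, seq = seqs, row.names = NULL)
}

#' Count consensus matches in a genome
#'
#' @param genome A [genome_sequence()].
#' @param pattern A [degenerate_consensus()].
#' @return Named numeric vector `c(total, forward, reverse)`, consistent
#'   with [scan_genome()] output.
#' @export
count_matches <- function(genome, pattern) {
  m <- scan_genome(genome, pattern)
  c(total = nrow(m), forward = sum(m$strand == "+"),
    reverse = sum(m$strand == "-"))
}

#' Write scan matches as BED6
#'
#' @param matches Data.frame from [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(matches)) matches$genome_id else character(),
    ranges = IRanges::IRanges(start = matches$start + 1L,
                              end = matches$end),
    strand = if (nrow(matches)) matches$strand else character()
  )
  gr$name <- if (nrow(matches)) paste0("match_", seq_len(nrow(matches)))
    else character()
  gr$score <- if (nrow(matches)) rep(0, nrow(matches)) else numeric()
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
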