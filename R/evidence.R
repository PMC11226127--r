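#' Score a pattern match for the initiation coverage signature
#'
#' Evaluates the same jump-then-decay statistic used by
#' [detect_initiation_sites()] at the match position, in the orientation
#' implied by the match strand: a `+` match should step up at its start and
#' decay rightward, a `-` match mirrors that. Because initiation cuts are
#' scattered over a ~120 bp region, the statistic is taken as the best over
#' bin boundaries within `slack_bins` bins of the match (fixed, hence
#' deterministic). A match is `supported` when both the jump ratio and the
#' decay fraction reach the detection thresholds.
#'
#' @param match One row of [scan_genome()] output (or a list with
#'   `genome_id`, `start`, `end`, `strand`).
#' @param track The [coverage_track()] for the same genome.
#' @param params A [detection_params()].
#' @param slack_bins Boundary search slack in bins (default 3).
#' @return A one-row data.frame: `start`, `end`, `strand`,
#'   `local_jump_ratio`, `decay_fraction`, `classification`
#'   (`"supported"`/`"unsupported"`).
#' @export
score_match_support <- function(match, track, params = detection_params(),
                                slack_bins = 3L) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.null(match$genome_id) && match$genome_id != track$genome_id) {
    stop("match genome '", match$genome_id, "' does not name track genome '",
         track$genome_id, "'")
  }
  if (match$start < 0L || match$end > track$genome_length) {
    stop("match [", match$start, ", ", match$end,
         ") lies outside the track extent [0, ", track$genome_length, ")")
  }
  v <- track$values
  n <- length(v)
  pos <- if (match$strand == "+") match$start else match$end
  b0 <- round(pos / track$binsize)
  bs <- (b0 - slack_bins):(b0 + slack_bins)
  bs <- bs[bs >= params$flank_bins & bs <= n - params$flank_bins]
  best <- list(ratio = 0, decay = 0)
  for (b in bs) {
    st <- .stats_at_boundary(v, b, match$strand, params$flank_bins,
                             params$decay_span_bins)
    if (!is.null(st) && !is.na(st$decay) && st$ratio > best$ratio) best <- st
  }
  supported <- best$ratio >= params$min_jump_ratio &&
    best$decay >= params$min_decay_fraction
  data.frame(start = match$start, end = match$end, strand = match$strand,
             local_jump_ratio = best$ratio, decay_fraction = best$decay,
             classification = if (supported) "supported" else "unsupported",
             row.names = NULL)
}

#' Classify all scan matches by coverage support
#'
#' @param matches Data.frame from [scan_genome()].
#' @param track The [coverage_track()] for the same genome.
#' @param params A [detection_params()].
#' @param slack_bins Passed to [score_match_support()].
#' @return `matches` with `local_jump_ratio`, `decay_fraction` and
#'   `classification` columns appended.
#' @export
classify_matches <- function(matches, track, params = detection_params(),
                             slack_bins = 3L) {
  if (nrow(matches) == 0L) {
    matches$local_jump_ratio <- numeric()
    matches$decay_fraction <- numeric()
    matches$classification <- character()
    return(matches)
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(matches)), function(i) {
    score_match_support(matches[i, ], track, params, slack_bins)
  }))
  matches$local_jump_ratio <- ev$local_jump_ratio
  matches$decay_fraction <- ev$decay_fraction
  matches$classification <- ev$classification
  matches
}

#' Assemble the final pseudo-pac site table
#'
#' One row per supported site, numbered in order of detection provenance:
#' coverage-detected candidates first (in position order), then supported
#' scan matches at new loci (in position order). Entries at the same locus
#' (same genome, overlapping intervals) are deduplicated, coverage
#' provenance winning.
#'
#' @param matches Classified matches from [classify_matches()] (may be
#'   empty).
#' @param candidates Coverage-detected candidates from [find_candidates()]
#'   (may be empty or `NULL`).
#' @return A data.frame with columns `site`, `genome_id`, `start`, `end`
#'   (0-based half-open), `strand`, `seq`, `provenance`
#'   (`"coverage"`/`"scan"`).
#' @export
summarize_sites <- function(matches, candidates = NULL) {
  empty <- data.frame(site = integer(), genome_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), seq = character(),
                      provenance = character())
  cov <- if (!is.null(candidates) && nrow(candidates)) {
    data.frame(genome_id = candidates$genome_id, start = candidates$start,
               end = candidates$end, strand = candidates$strand,
               seq = candidates$seq, provenance = "coverage")
  } else empty[-1]
  sc <- if (nrow(matches)) {
    sup <- matches[matches$classification == "supported", , drop = FALSE]
    data.frame(genome_id = sup$genome_id, start = sup$start, end = sup$end,
               strand = sup$strand, seq = sup$seq, provenance = "scan")
  } else empty[-1]

  dedup <- function(df) {
    if (!nrow(df)) return(df)
    df <- df[order(df$start), , drop = FALSE]
    df[!duplicated(df[c("genome_id", "start", "end", "strand")]), ,
       drop = FALSE]
  }
  cov <- dedup(cov)
  sc <- dedup(sc)
  if (nrow(sc) && nrow(cov)) {
    overlaps_cov <- vapply(seq_len(nrow(sc)), function(i) {
      any(cov$genome_id == sc$genome_id[i] & cov$start < sc$end[i] &
            cov$end > sc$start[i])
    }, TRUE)
    sc <- sc[!overlaps_cov, , drop = FALSE]
  }
  out <- rbind(cov, sc)
  if (!nrow(out)) return(empty)
  out <- cbind(site = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write the site table as TSV
#'
#' Coordinates in the written table are 1-based inclusive (human-facing);
#' the header comment says so.
#'
#' @param site_table Data.frame from [summarize_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(site_table, path) {
  out <- site_table
  if (nrow(out)) {
    out$start <- out$start + 1L   # 1-based inclusive
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pseudo-pac site table",
               "# coordinates: 1-based inclusive"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
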