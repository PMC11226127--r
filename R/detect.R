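#' Detection parameters for initiation-site calling
#'
#' The initiation signature is a sharp step in binned coverage followed by a
#' stair-like decay in the packaging direction. A boundary between bins is
#' called when the ratio of downstream to upstream flank means exceeds
#' `min_jump_ratio`, the absolute difference exceeds `min_abs_jump`, and at
#' least `min_decay_fraction` of adjacent bin pairs over the next
#' `decay_span_bins` bins are non-increasing. Half a depth unit is added to
#' the upstream mean in the ratio so zero background never divides by zero.
#'
#' @param flank_bins Bins averaged on each side of a boundary (default 20).
#' @param min_jump_ratio Minimum downstream/upstream mean ratio (default 3).
#' @param min_abs_jump Minimum downstream minus upstream mean, in depth
#'   units (default 5).
#' @param decay_span_bins Bins over which the decay test runs (default 400).
#' @param min_decay_fraction Minimum fraction of non-increasing adjacent bin
#'   pairs within the decay span (default 0.6).
#' @param min_separation Calls closer than this many bp are collapsed to the
#'   single strongest call (default 50000).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(flank_bins = 20L, min_jump_ratio = 3,
                             min_abs_jump = 5, decay_span_bins = 400L,
                             min_decay_fraction = 0.6,
                             min_separation = 50000L) {
  p <- list(flank_bins = as.integer(flank_bins),
            min_jump_ratio = min_jump_ratio,
            min_abs_jump = min_abs_jump,
            decay_span_bins = as.integer(decay_span_bins),
            min_decay_fraction = min_decay_fraction,
            min_separation = as.integer(min_separation))
  stopifnot(p$flank_bins >= 1L, p$decay_span_bins >= 1L,
            p$min_jump_ratio >= 1, p$min_abs_jump >= 0,
            p$min_decay_fraction >= 0, p$min_decay_fraction <= 1,
            p$min_separation >= 0L)
  structure(p, class = "detection_params")
}

# Ratio denominator offset: tolerates zero background without masking jumps.
.RATIO_EPS <- 0.5

# Jump statistics on the + orientation of a bin vector for every eligible
# boundary b (b bins to the left, 1-based, flank <= b <= n - flank).
# Returns a data.frame(b, upstream, downstream, ratio, jump_abs, decay).
.plus_boundary_stats <- function(v, flank, span) {
  n <- length(v)
  b <- seq.int(flank, n - flank)
  cs <- c(0, cumsum(v))
  up <- (cs[b + 1L] - cs[b - flank + 1L]) / flank
  dn <- (cs[b + flank + 1L] - cs[b + 1L]) / flank
  ok <- as.numeric(v[-1L] <= v[-n])           # pair i: bins i, i+1
  cok <- c(0, cumsum(ok))
  i1 <- b + 1L
  i2 <- pmin(b + span, n) - 1L
  npair <- pmax(i2 - i1 + 1L, 0L)
  decay <- ifelse(npair > 0L, (cok[i2 + 1L] - cok[i1]) / npair, NA_real_)
  data.frame(b = b, upstream = up, downstream = dn,
             ratio = dn / (up + .RATIO_EPS), jump_abs = dn - up,
             decay = decay)
}

# Single-boundary jump statistic in a given orientation; used by the
# evidence module. b is the + orientation boundary index (bins to the left).
.stats_at_boundary <- function(v, b, strand, flank, span) {
  n <- length(v)
  if (b < flank || b > n - flank) return(NULL)
  if (strand == "-") {
    v <- rev(v)
    b <- n - b
  }
  up <- mean(v[(b - flank + 1L):b])
  dn <- mean(v[(b + 1L):(b + flank)])
  i2 <- min(b + span, n) - 1L
  decay <- if (i2 >= b + 1L) {
    idx <- (b + 1L):i2
    mean(v[idx + 1L] <= v[idx])
  } else NA_real_
  list(ratio = dn / (up + .RATIO_EPS), jump_abs = dn - up, decay = decay)
}

#' Detect packaging initiation sites in a coverage track
#'
#' Scans every bin boundary for the initiation signature (see
#' [detection_params()]). `+` sites step up left-to-right and decay with
#' increasing coordinate (packaging proceeds rightward); `-` sites are the
#' mirror image and are found by running the same statistic on the reversed
#' track, which makes detection exactly equivariant under coverage reversal.
#' Calls within `min_separation` bp of a stronger call are suppressed; ties
#' are broken by larger absolute jump, then leftmost position.
#'
#' @param track A [coverage_track()].
#' @param params A [detection_params()].
#' @return A data.frame with columns `genome_id`, `position` (bp, 0-based
#'   boundary of the jump), `strand`, `jump_ratio`, `jump_abs`,
#'   `decay_fraction`, sorted by position.
#' @export
detect_initiation_sites <- function(track, params = detection_params()) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(params, "detection_params"))
  v <- track$values
  n <- length(v)
  need <- 2L * params$flank_bins + params$decay_span_bins
  if (n < need) {
    stop("track has ", n, " bins but detection needs at least ", need,
         " (2*flank_bins + decay_span_bins)")
  }

  pass <- function(st) {
    keep <- st$ratio >= params$min_jump_ratio &
      st$jump_abs >= params$min_abs_jump &
      !is.na(st$decay) & st$decay >= params$min_decay_fraction
    st[keep, , drop = FALSE]
  }
  fwd <- pass(.plus_boundary_stats(v, params$flank_bins,
                                   params$decay_span_bins))
  rev_ <- pass(.plus_boundary_stats(rev(v), params$flank_bins,
                                    params$decay_span_bins))

  calls <- rbind(
    if (nrow(fwd)) data.frame(b = fwd$b, strand = "+", jump_ratio = fwd$ratio,
                              jump_abs = fwd$jump_abs,
                              decay_fraction = fwd$decay),
    if (nrow(rev_)) data.frame(b = n - rev_$b, strand = "-",
                               jump_ratio = rev_$ratio,
                               jump_abs = rev_$jump_abs,
                               decay_fraction = rev_$decay)
  )
  empty <- data.frame(genome_id = character(), position = integer(),
                      strand = character(), jump_ratio = numeric(),
                      jump_abs = numeric(), decay_fraction = numeric())
  if (is.null(calls) || nrow(calls) == 0L) return(empty)

  calls$position <- calls$b * track$binsize
  ord <- order(-calls$jump_ratio, -calls$jump_abs, calls$position)
  calls <- calls[ord, , drop = FALSE]
  keep_pos <- integer(0)
  keep_row <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!length(keep_pos) ||
        all(abs(calls$position[i] - keep_pos) >= params$min_separation)) {
      keep_row[i] <- TRUE
      keep_pos <- c(keep_pos, calls$position[i])
    }
  }
  calls <- calls[keep_row, , drop = FALSE]
  calls <- calls[order(calls$position), , drop = FALSE]
  data.frame(genome_id = track$genome_id, position = calls$position,
             strand = calls$strand, jump_ratio = calls$jump_ratio,
             jump_abs = calls$jump_abs,
             decay_fraction = calls$decay_fraction,
             row.names = NULL)
}

#' Write detected sites as BED6
#'
#' Names are `site_1 ... site_n` in position order; the score is
#' `min(1000, round(100 * jump_ratio))`.
#'
#' @param sites Data.frame from [detect_initiation_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(sites)) sites$genome_id else character(),
    ranges = IRanges::IRanges(start = sites$position + 1L,
                              end = sites$position + 1L),
    strand = if (nrow(sites)) sites$strand else character()
  )
  gr$name <- if (nrow(sites)) paste0("site_", seq_len(nrow(sites))) else
    character()
  gr$score <- if (nrow(sites)) pmin(1000, round(100 * sites$jump_ratio)) else
    numeric()
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
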