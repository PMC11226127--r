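#' Search parameters for pac-candidate extraction
#'
#' The packaging machinery of P22 makes its initiation cuts within a 120-bp
#' region around the pac site, so a 120-bp window centered on the detected
#' jump is searched for the best match to the seed consensus, the 12-bp P22
#' pac consensus `AAGATTTATCTG`.
#'
#' @param window_len Window length in bp (default 120).
#' @param seed Seed consensus sequence (default [pac_seed()]).
#' @param offset Shift of the window center in the packaging direction, in
#'   bp (default 0, i.e. the window is centered on the detected boundary).
#'   Useful because the maximal coverage jump sits at the edge, not the
#'   center, of a jittered cut region.
#' @return An object of class `search_params`.
#' @export
search_params <- function(window_len = 120L, seed = pac_seed(),
                          offset = 0L) {
  seed <- toupper(seed)
  stopifnot(is.character(seed), length(seed) == 1L, nzchar(seed))
  if (grepl("[^ACGT]", seed)) stop("seed must be over {A,C,G,T}")
  window_len <- as.integer(window_len)
  if (window_len < nchar(seed)) {
    stop("window_len (", window_len, ") must be >= seed length (",
         nchar(seed), ")")
  }
  structure(list(window_len = window_len, seed = seed,
                 offset = as.integer(offset)),
            class = "search_params")
}

#' Extract the oriented window around an initiation site
#'
#' For a `+` site the forward-strand slice
#' `[position - window_len/2, position + window_len/2)` is returned; for a
#' `-` site its reverse complement, so the window always reads 5'->3' on the
#' packaging strand. Windows running past a genome end are clamped with a
#' warning (never silently); a genome shorter than the window is an error.
#'
#' @param genome A [genome_sequence()].
#' @param site One row of [detect_initiation_sites()] output (or any list
#'   with `position` and `strand`).
#' @param window_len Window length in bp (default 120).
#' @param offset Window-center shift in the packaging direction, in bp
#'   (default 0).
#' @return A list with `seq` (oriented window), `start`, `end`
#'   (forward-strand, 0-based half-open) and `strand`. For a `-` site,
#'   window offset `o` maps back to forward-strand interval
#'   `[end - o - k, end - o)` for a match of length `k`.
#' @export
extract_window <- function(genome, site, window_len = 120L, offset = 0L) {
  stopifnot(inherits(genome, "genome_sequence"))
  window_len <- as.integer(window_len)
  if (genome$length < window_len) {
    stop("genome '", genome$id, "' (", genome$length,
         " bp) is shorter than the ", window_len, " bp window")
  }
  pos <- as.integer(site$position) +
    if (site$strand == "-") -as.integer(offset) else as.integer(offset)
  half <- window_len %/% 2L
  start <- pos - half
  end <- pos + (window_len - half)
  if (start < 0L || end > genome$length) {
    start <- max(start, 0L)
    end <- min(end, genome$length)
    warning("window around position ", pos, " clamped to [", start, ", ",
            end, ") at the ", genome$id, " genome end")
  }
  seq <- .slice(genome, start, end)
  if (site$strand == "-") seq <- revcomp(seq)
  list(seq = seq, start = start, end = end, strand = site$strand)
}

#' Best ungapped match of a seed inside a window
#'
#' Slides the seed along the window and returns the offset minimizing the
#' Hamming distance; ties are broken by the smallest offset. `N` in the
#' window counts as a mismatch.
#'
#' @param window Nucleotide string, at least as long as `seed`.
#' @param seed Nucleotide string over `{A,C,G,T}`.
#' @return A list with `offset` (0-based), `seq` (the matched substring) and
#'   `mismatches`.
#' @export
best_match <- function(window, seed) {
  window <- toupper(window); seed <- toupper(seed)
  k <- nchar(seed)
  W <- nchar(window)
  if (W < k) stop("window (", W, " bp) shorter than seed (", k, " bp)")
  wv <- strsplit(window, "", fixed = TRUE)[[1]]
  sv <- strsplit(seed, "", fixed = TRUE)[[1]]
  noff <- W - k + 1L
  dist <- integer(noff)
  for (j in seq_len(k)) {
    dist <- dist + (wv[j:(j + noff - 1L)] != sv[j])
  }
  off <- which.min(dist)   # which.min takes the first (leftmost) minimum
  list(offset = off - 1L, seq = substr(window, off, off + k - 1L),
       mismatches = dist[off])
}

#' Find the pac-candidate for each detected initiation site
#'
#' Combines [extract_window()] and [best_match()]: for every site the
#' oriented window is searched for the best seed match, and the match is
#' mapped back to forward-strand coordinates.
#'
#' @param genome A [genome_sequence()].
#' @param sites Data.frame from [detect_initiation_sites()].
#' @param params A [search_params()].
#' @return A data.frame with one row per site: `site` (index into `sites`),
#'   `genome_id`, `start`, `end` (forward strand, 0-based half-open),
#'   `strand`, `seq` (5'->3' on the packaging strand) and `mismatches`.
#' @export
find_candidates <- function(genome, sites, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  k <- nchar(params$seed)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    win <- extract_window(genome, site, params$window_len, params$offset)
    bm <- best_match(win$seq, params$seed)
    if (win$strand == "+") {
      start <- win$start + bm$offset
    } else {
      start <- win$end - bm$offset - k
    }
    data.frame(site = i, genome_id = site$genome_id, start = start,
               end = start + k, strand = win$strand, seq = bm$seq,
               mismatches = bm$mismatches)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(), genome_id = character(), start = integer(),
               end = integer(), strand = character(), seq = character(),
               mismatches = integer())
  rownames(out) <- NULL
  out
}

#' Write pac-candidates as BED6 and FASTA
#'
#' The BED score is `mismatches`; FASTA headers carry the site number,
#' strand and mismatch count.
#'
#' @param candidates Data.frame from [find_candidates()].
#' @param bed_path,fasta_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_candidates <- function(candidates, bed_path = NULL, fasta_path = NULL) {
  written <- character()
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(
      seqnames = if (nrow(candidates)) candidates$genome_id else character(),
      ranges = IRanges::IRanges(start = candidates$start + 1L,
                                end = candidates$end),
      strand = if (nrow(candidates)) candidates$strand else character()
    )
    gr$name <- if (nrow(candidates))
      paste0("candidate_", candidates$site) else character()
    gr$score <- if (nrow(candidates)) candidates$mismatches else numeric()
    rtracklayer::export(gr, bed_path, format = "BED")
    written <- c(written, bed_path)
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(candidates$seq)
    names(seqs) <- sprintf("candidate_%d strand=%s mismatches=%d",
                           candidates$site, candidates$strand,
                           candidates$mismatches)
    Biostrings::writeXStringSet(seqs, fasta_path)
    written <- c(written, fasta_path)
  }
  invisible(written)
}
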