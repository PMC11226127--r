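#' Configuration for the headful-packaging simulator
#'
#' The simulator emulates the coverage phenomenology of phage reads mapped
#' to a host genome: at each planted site, packaging initiates within a
#' jittered cut region and proceeds directionally, filling a geometric
#' number of fixed-size headfuls, which produces a sharp coverage jump
#' followed by stair-like decay; a low uniform Poisson background stands in
#' for residual host reads.
#'
#' @param genome_length Host genome length in bp (default 2e6).
#' @param n_sites Number of planted pseudo-pac sites (default 8).
#' @param site_pattern [degenerate_consensus()] the planted sequences are
#'   drawn from (default [pseudo_pac_pattern]`("final")`).
#' @param strands Per-site strand vector of `+`/`-`, or `"random"`.
#' @param headful Headful (capsid) size in bp (default 43000, a
#'   P22-scale constant).
#' @param series_mean Expected headfuls per initiation event; series length
#'   is geometric with this mean, truncated at `series_max` (default 5).
#' @param series_max Truncation of the series length (default 12).
#' @param events_per_site Initiation events per site (default 200).
#' @param cut_jitter Initiation cuts are offset uniformly within +/- this
#'   many bp of the site (default 60, i.e. a 120-bp cut region).
#' @param background_rate Mean Poisson background depth per bin (default 1).
#' @param binsize Coverage bin size in bp (default 25).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(genome_length = 2e6, n_sites = 8L,
                              site_pattern = pseudo_pac_pattern("final"),
                              strands = "random", headful = 43000L,
                              series_mean = 5, series_max = 12L,
                              events_per_site = 200L, cut_jitter = 60L,
                              background_rate = 1.0, binsize = 25L,
                              seed = NULL) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_sites = as.integer(n_sites), site_pattern = site_pattern,
              strands = strands, headful = as.integer(headful),
              series_mean = series_mean, series_max = as.integer(series_max),
              events_per_site = as.integer(events_per_site),
              cut_jitter = as.integer(cut_jitter),
              background_rate = background_rate,
              binsize = as.integer(binsize),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$genome_length >= 1L, cfg$n_sites >= 0L, cfg$headful > 0L,
            cfg$series_mean >= 1, cfg$series_max >= 1L,
            cfg$events_per_site >= 0L, cfg$cut_jitter >= 0L,
            cfg$background_rate >= 0, cfg$binsize >= 1L,
            inherits(cfg$site_pattern, "degenerate_consensus"))
  if (!identical(cfg$strands, "random")) {
    stopifnot(length(cfg$strands) == cfg$n_sites,
              all(cfg$strands %in% c("+", "-")))
  }
  structure(cfg, class = "sim_config")
}

# Truncated geometric series-length distribution on 1..max with the
# untruncated mean `mean` (P(L = k) proportional to (1-p)^(k-1) p, p = 1/mean).
.series_probs <- function(mean, max) {
  p <- 1 / mean
  q <- (1 - p)^(seq_len(max) - 1L) * p
  q / sum(q)
}

#' Draw one sequence matching a degenerate pattern
#'
#' One base per column, uniform over the column's set. Uses the current RNG
#' state.
#'
#' @param pattern A [degenerate_consensus()].
#' @return A nucleotide string that always matches `pattern`.
#' @export
draw_site_sequence <- function(pattern) {
  stopifnot(inherits(pattern, "degenerate_consensus"))
  paste(vapply(pattern$columns,
               function(col) col[sample.int(length(col), 1L)], ""),
        collapse = "")
}

#' Simulate a host genome with planted pseudo-pac sites
#'
#' The background is i.i.d. uniform over `{A,C,G,T}`. Sites are placed at
#' least `2 * headful` apart (and the same distance from the genome ends so
#' each site's coverage signature fits), each carrying a fresh draw from
#' `site_pattern`, implanted as its reverse complement for `-` sites.
#'
#' @param config A [simulation_config()]. `config$seed` (if set) seeds the
#'   RNG.
#' @return A list: `genome` (a [genome_sequence()] named `"sim"`) and
#'   `truth`, a data.frame of planted sites (`genome_id`, `start`, `end`,
#'   `strand`, `seq` with `seq` 5'->3' on the packaging strand).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length
  k <- length(config$site_pattern$columns)
  chars <- sample(.BASES, L, replace = TRUE)

  n <- config$n_sites
  truth <- data.frame(genome_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      seq = character())
  if (n > 0L) {
    sep <- 2L * config$headful
    lo <- sep
    hi <- L - sep - k
    if (hi < lo || (hi - lo) < (n - 1L) * sep) {
      stop("cannot place ", n, " sites >= ", sep, " bp apart in a ", L,
           " bp genome")
    }
    starts <- NULL
    for (try in seq_len(1000L)) {
      cand <- sort(sample(lo:hi, n))
      if (n == 1L || all(diff(cand) >= sep)) { starts <- cand; break }
    }
    if (is.null(starts)) {
      stop("failed to place ", n, " sites >= ", sep, " bp apart after ",
           "1000 attempts")
    }
    strands <- if (identical(config$strands, "random")) {
      sample(c("+", "-"), n, replace = TRUE)
    } else config$strands
    seqs <- vapply(seq_len(n), function(i) {
      draw_site_sequence(config$site_pattern)
    }, "")
    for (i in seq_len(n)) {
      implant <- if (strands[i] == "-") revcomp(seqs[i]) else seqs[i]
      chars[(starts[i] + 1L):(starts[i] + k)] <-
        strsplit(implant, "", fixed = TRUE)[[1]]
    }
    truth <- data.frame(genome_id = "sim", start = starts,
                        end = starts + k, strand = strands, seq = seqs)
  }
  list(genome = genome_sequence("sim", paste(chars, collapse = "")),
       truth = truth)
}

#' Simulate headful-packaging read coverage over planted sites
#'
#' For each planted site, `events_per_site` initiation events are drawn.
#' Each event starts at the site's oriented anchor (motif start for `+`,
#' motif end for `-`) offset by a uniform jitter within `+/- cut_jitter`
#' bp, and deposits one unit of depth over `series * headful` bp in the
#' packaging direction, where `series` is truncated-geometric. Intervals
#' are clipped at the genome ends. Per-bin Poisson background is added
#' after binning.
#'
#' @param genome The simulated [genome_sequence()] (only its length and id
#'   are used).
#' @param truth Planted-site data.frame from [simulate_genome()].
#' @param config The [simulation_config()]. If `config$seed` is set, the
#'   RNG is seeded with `config$seed + 1` so genome and coverage draws are
#'   independently reproducible.
#' @return A [coverage_track()] with attributes `event_mass` (total clipped
#'   event bp) and `background_draws` (the per-bin Poisson draws), useful
#'   for mass-conservation checks.
#' @export
simulate_packaging_coverage <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genome, "genome_sequence"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  L <- genome$length
  nb <- as.integer(ceiling(L / config$binsize))
  nev_site <- config$events_per_site
  nev <- nrow(truth) * nev_site

  depth <- numeric(L)
  event_mass <- 0
  if (nev > 0L) {
    anchors <- ifelse(truth$strand == "+", truth$start, truth$end)
    anchor <- rep(anchors, each = nev_site)
    dir <- rep(ifelse(truth$strand == "+", 1L, -1L), each = nev_site)
    u <- if (config$cut_jitter > 0L) {
      sample(seq.int(-config$cut_jitter, config$cut_jitter), nev,
             replace = TRUE)
    } else integer(nev)
    series <- sample.int(config$series_max, nev, replace = TRUE,
                         prob = .series_probs(config$series_mean,
                                              config$series_max))
    span <- series * config$headful
    cut <- anchor + u * dir
    s <- ifelse(dir == 1L, cut, cut - span)
    e <- ifelse(dir == 1L, cut + span, cut)
    s <- pmax(s, 0L)
    e <- pmin(e, L)
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    event_mass <- sum(as.numeric(e - s))
    d <- numeric(L + 1L)
    inc <- rowsum(c(rep(1, length(s)), rep(-1, length(e))),
                  c(s + 1L, e + 1L), reorder = FALSE)
    at <- as.integer(rownames(inc))
    keep2 <- at <= L
    d[at[keep2]] <- inc[keep2, 1L]
    depth <- cumsum(d)[seq_len(L)]
  }
  bg <- if (config$background_rate > 0) {
    stats::rpois(nb, config$background_rate)
  } else numeric(nb)
  values <- .bin_depth(depth, config$binsize, L) + bg
  track <- coverage_track(values, config$binsize, L, genome$id)
  attr(track, "event_mass") <- event_mass
  attr(track, "background_draws") <- bg
  track
}

#' Write a complete simulation to disk
#'
#' Writes the genome (FASTA), planted-site truth (BED6), coverage
#' (bedGraph) and a JSON echo of the configuration, so any pipeline stage
#' can be exercised from files.
#'
#' @param sim Output of [simulate_genome()].
#' @param track Output of [simulate_packaging_coverage()].
#' @param config The [simulation_config()] used.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_simulation <- function(sim, track, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             truth = file.path(dir, "truth.bed"),
             coverage = file.path(dir, "coverage.bedGraph"),
             config = file.path(dir, "config.json"))
  write_genome_fasta(sim$genome, paths[["genome"]])
  truth <- sim$truth
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(truth)) truth$genome_id else character(),
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = if (nrow(truth)) truth$strand else character()
  )
  gr$name <- if (nrow(truth)) truth$seq else character()
  gr$score <- if (nrow(truth)) rep(0, nrow(truth)) else numeric()
  rtracklayer::export(gr, paths[["truth"]], format = "BED")
  write_bedgraph(track, paths[["coverage"]])
  cfg <- config
  cfg$site_pattern <- emit_pattern(cfg$site_pattern)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}
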