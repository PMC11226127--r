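#' Construct a binned coverage track
#'
#' Mean read depth per bin along one genome. The number of bins is
#' `ceiling(genome_length / binsize)`; the final bin may be partial and its
#' value is the mean over its actual width.
#'
#' @param values Numeric vector of per-bin mean depths, all finite and >= 0.
#' @param binsize Bin width in bp (default 25).
#' @param genome_length Genome length in bp.
#' @param genome_id Name of the genome the track belongs to.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, binsize = 25L, genome_length,
                           genome_id = "genome") {
  binsize <- as.integer(binsize)
  genome_length <- as.integer(genome_length)
  stopifnot(binsize >= 1L, genome_length >= 1L, is.numeric(values))
  n_expect <- as.integer(ceiling(genome_length / binsize))
  if (length(values) != n_expect) {
    stop("expected ", n_expect, " bins for genome_length ", genome_length,
         " at binsize ", binsize, ", got ", length(values))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("coverage values must be finite and >= 0")
  }
  structure(list(genome_id = genome_id, binsize = binsize,
                 values = as.numeric(values), genome_length = genome_length),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$genome_id, ": ", length(x$values),
      " bins of ", x$binsize, " bp over ", x$genome_length,
      " bp; mean depth ", format(mean(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Bin widths of a coverage track
#'
#' All bins have width `binsize` except possibly the last.
#'
#' @param track A [coverage_track()].
#' @return Integer vector of bin widths in bp.
#' @export
bin_widths <- function(track) {
  n <- length(track$values)
  pmin(track$binsize, track$genome_length - (seq_len(n) - 1L) * track$binsize)
}

# Bin a per-base depth vector into mean depth per bin.
.bin_depth <- function(depth, binsize, genome_length) {
  idx <- (seq_len(genome_length) - 1L) %/% binsize
  sums <- rowsum(depth, idx, reorder = TRUE)[, 1L]
  n <- as.integer(ceiling(genome_length / binsize))
  widths <- pmin(binsize, genome_length - (seq_len(n) - 1L) * binsize)
  unname(sums / widths)
}

#' Read a depth file into a binned coverage track
#'
#' Accepts either a per-base depth TSV (`chrom`, 1-based position, depth —
#' the `samtools depth` layout) or a bedGraph (`chrom`, 0-based half-open
#' `start`/`end`, value). The dialect is auto-detected from the column count
#' (3 = per-base, 4 = bedGraph) and can be forced with `format`. Positions
#' absent from the file count as depth 0. Per-base depths are averaged
#' within consecutive bins; a final partial bin is averaged over its actual
#' width.
#'
#' @param path Path to the depth file.
#' @param binsize Bin width in bp (default 25).
#' @param genome_length Genome length in bp. If `NULL`, inferred from the
#'   largest position/interval end in the file (an empty file then errors).
#' @param genome_id Restrict to this chromosome. If `NULL` the file must
#'   contain a single chromosome.
#' @param format `"auto"`, `"perbase"` or `"bedgraph"`.
#' @return A [coverage_track()].
#' @export
read_depth <- function(path, binsize = 25L, genome_length = NULL,
                       genome_id = NULL, format = c("auto", "perbase",
                                                    "bedgraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("depth file not found: ", path)

  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (nzchar(ln) && !grepl("^(#|track|browser)", ln)) { first <- ln; break }
  }
  close(con); on.exit()

  if (!nzchar(first)) {
    # empty depth file: all-zero track, but only if we know the extent
    if (is.null(genome_length)) {
      stop("empty depth file '", path, "' and no genome_length given")
    }
    n <- as.integer(ceiling(genome_length / binsize))
    return(coverage_track(numeric(n), binsize, genome_length,
                          genome_id %||% "genome"))
  }
  nfields <- length(strsplit(first, "[\t ]+")[[1]])
  if (format == "auto") {
    format <- switch(as.character(nfields), "3" = "perbase", "4" = "bedgraph",
                     stop("cannot auto-detect depth dialect: ", nfields,
                          " columns in '", path, "'"))
  }

  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    starts <- GenomicRanges::start(gr) - 1L   # back to 0-based
    ends <- GenomicRanges::end(gr)
    vals <- as.numeric(gr$score)
  } else {
    df <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                     colClasses = c("character", "numeric", "character"))
    vals <- suppressWarnings(as.numeric(df[[3]]))
    if (any(is.na(vals))) stop("non-numeric depth value in '", path, "'")
    chrom <- df[[1]]
    pos <- df[[2]]
    if (any(pos != floor(pos)) || any(pos < 1)) {
      stop("per-base positions must be 1-based integers in '", path, "'")
    }
    starts <- as.integer(pos) - 1L
    ends <- as.integer(pos)
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("depth values must be finite and >= 0 in '", path, "'")
  }

  if (!is.null(genome_id)) {
    keep <- chrom == genome_id
    if (!any(keep) && length(chrom) > 0L) {
      stop("chromosome '", genome_id, "' not present in '", path, "'")
    }
    chrom <- chrom[keep]; starts <- starts[keep]; ends <- ends[keep]
    vals <- vals[keep]
  } else {
    if (length(unique(chrom)) > 1L) {
      stop("depth file '", path, "' mixes chromosomes (",
           paste(unique(chrom), collapse = ", "),
           "); pass genome_id to select one")
    }
    genome_id <- if (length(chrom)) chrom[1L] else "genome"
  }

  if (is.null(genome_length)) genome_length <- max(ends)
  genome_length <- as.integer(genome_length)
  if (length(ends) && max(ends) > genome_length) {
    stop("depth file '", path, "' has positions beyond genome_length ",
         genome_length)
  }

  # fast exact path: intervals already aligned to the requested bins (as
  # written by write_bedgraph) are taken verbatim, with no re-averaging
  n <- as.integer(ceiling(genome_length / binsize))
  if (length(starts) == n &&
      identical(as.integer(starts), (seq_len(n) - 1L) * as.integer(binsize)) &&
      identical(as.integer(ends),
                pmin(as.integer(starts) + as.integer(binsize),
                     genome_length))) {
    return(coverage_track(vals, binsize, genome_length, genome_id))
  }

  # accumulate per-base depth via a difference array (intervals may overlap)
  d <- numeric(genome_length + 1L)
  if (length(starts)) {
    inc <- rowsum(c(vals, -vals), c(starts + 1L, ends + 1L), reorder = FALSE)
    at <- as.integer(rownames(inc))
    keep <- at <= genome_length + 1L
    d[at[keep]] <- d[at[keep]] + inc[keep, 1L]
  }
  depth <- cumsum(d)[seq_len(genome_length)]
  coverage_track(.bin_depth(depth, binsize, genome_length), binsize,
                 genome_length, genome_id)
}

#' Write a coverage track as bedGraph
#'
#' One line per bin, 0-based half-open intervals. Values are written with
#' full double precision so that re-reading the file at the same bin size
#' reproduces the track exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$values)
  starts <- (seq_len(n) - 1L) * track$binsize
  ends <- pmin(starts + track$binsize, track$genome_length)
  lines <- sprintf("%s\t%d\t%d\t%.17g", track$genome_id, starts, ends,
                   track$values)
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
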