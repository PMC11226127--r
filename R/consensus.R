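#' The P22 pac seed consensus
#'
#' The 12-bp consensus pac site of phage P22, `5' AAGATTTATCTG 3'`, used as
#' the seed for windowed candidate search.
#'
#' @return A nucleotide string.
#' @export
pac_seed <- function() "AAGATTTATCTG"

#' P22 pseudo-pac consensus patterns
#'
#' The two degenerate consensus patterns for Salmonella pseudo-pac sites:
#' the pattern built from the aligned candidate sequences (`"initial"`), and
#' the pattern after relaxing the conserved G at position three to G or C
#' (`"final"`), which additionally recovers the extra 14028S site. Both span
#' 17 columns; the 12-bp pac seed matches columns 1-12, recorded as the
#' `seed_span`.
#'
#' @param which `"final"` (default) or `"initial"`.
#' @return A [degenerate_consensus()].
#' @examples
#' emit_pattern(pseudo_pac_pattern("initial"))
#' @export
pseudo_pac_pattern <- function(which = c("final", "initial")) {
  which <- match.arg(which)
  txt <- switch(which,
    initial = "AAG[AG][TC][AT][AT][ATC][TC][TC]T[GT][ACG][ACG][ACG]TC",
    final   = "AA[GC][AG][TC][AT][AT][ATC][TC][TC]T[GT][ACG][ACG][ACG]TC")
  parse_pattern(txt, seed_span = c(0L, 12L))
}

#' Construct a degenerate consensus
#'
#' A degenerate consensus is an ordered list of columns, each a nonempty
#' subset of `{A, C, G, T}`. It is written and parsed in bracket style
#' (`AAG[AG][TC]...`): singleton columns as bare letters, multi-base columns
#' bracketed, bases in A < C < G < T order. `seed_span` optionally marks the
#' region corresponding to the original seed consensus.
#'
#' @param columns List of character vectors, each a subset of `{A,C,G,T}`.
#' @param seed_span Optional 0-based half-open column interval `c(start,
#'   end)` marking the seed-consensus region.
#' @return An object of class `degenerate_consensus`.
#' @export
degenerate_consensus <- function(columns, seed_span = NULL) {
  stopifnot(is.list(columns), length(columns) >= 1L)
  columns <- lapply(columns, function(col) {
    col <- unique(toupper(col))
    if (length(col) < 1L || length(col) > 4L || any(!col %in% .BASES)) {
      stop("each consensus column must be a nonempty subset of {A,C,G,T}")
    }
    col[order(match(col, .BASES))]
  })
  if (!is.null(seed_span)) {
    seed_span <- as.integer(seed_span)
    stopifnot(length(seed_span) == 2L, seed_span[1] >= 0L,
              seed_span[1] < seed_span[2],
              seed_span[2] <= length(columns))
  }
  structure(list(columns = columns, seed_span = seed_span),
            class = "degenerate_consensus")
}

#' @export
print.degenerate_consensus <- function(x, ...) {
  cat("<degenerate_consensus> ", length(x$columns), " columns: ",
      emit_pattern(x), "\n", sep = "")
  if (!is.null(x$seed_span)) {
    cat("  seed span: columns ", x$seed_span[1] + 1L, "-", x$seed_span[2],
        " (1-based)\n", sep = "")
  }
  invisible(x)
}

#' @export
length.degenerate_consensus <- function(x) length(x$columns)

#' Parse a bracket-style pattern string
#'
#' Accepts a sequence of bare bases and bracketed base groups, e.g.
#' `"AAG[AG][TC]"`. Whitespace between tokens is tolerated (published
#' patterns are occasionally printed with a stray space). Empty brackets,
#' unbalanced brackets and characters outside `{A,C,G,T,[,]}` are errors.
#'
#' @param text Pattern string.
#' @param seed_span Optional seed region, as in [degenerate_consensus()].
#' @return A [degenerate_consensus()].
#' @export
parse_pattern <- function(text, seed_span = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("\\s+", "", toupper(text))
  if (!nzchar(clean)) stop("empty pattern")
  if (grepl("\\[\\]", clean)) stop("empty bracket group in pattern: ", text)
  toks <- regmatches(clean, gregexpr("\\[[ACGT]+\\]|[ACGT]", clean))[[1]]
  if (paste(toks, collapse = "") != clean) {
    stop("malformed pattern (illegal character or unbalanced bracket): ",
         text)
  }
  columns <- lapply(toks, function(t) {
    strsplit(gsub("[\\[\\]]", "", t, perl = TRUE), "", fixed = TRUE)[[1]]
  })
  degenerate_consensus(columns, seed_span = seed_span)
}

#' Emit the canonical bracket-style pattern string
#'
#' Singleton columns are written as bare letters, multi-base columns as
#' brackets with bases in A < C < G < T order. `emit_pattern(parse_pattern(p))`
#' is the canonical form of `p`.
#'
#' @param x A [degenerate_consensus()].
#' @return Pattern string.
#' @export
emit_pattern <- function(x) {
  stopifnot(inherits(x, "degenerate_consensus"))
  paste(vapply(x$columns, function(col) {
    if (length(col) == 1L) col else paste0("[", paste(col, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Replace one column of a consensus
#'
#' @param x A [degenerate_consensus()].
#' @param position 1-based column index.
#' @param new_set Character vector, a nonempty subset of `{A,C,G,T}`.
#' @return A new [degenerate_consensus()]; other columns are untouched.
#' @examples
#' # relaxing the conserved G at position 3 to G or C turns the initial
#' # pseudo-pac pattern into the final one
#' p <- edit_column(pseudo_pac_pattern("initial"), 3, c("G", "C"))
#' emit_pattern(p)
#' @export
edit_column <- function(x, position, new_set) {
  stopifnot(inherits(x, "degenerate_consensus"))
  position <- as.integer(position)
  if (position < 1L || position > length(x$columns)) {
    stop("column position ", position, " out of range 1..",
         length(x$columns))
  }
  cols <- x$columns
  cols[[position]] <- new_set
  degenerate_consensus(cols, seed_span = x$seed_span)
}

#' Number of distinct sequences matching a consensus
#'
#' The product of the column set sizes.
#'
#' @param x A [degenerate_consensus()].
#' @return A count.
#' @export
pattern_cardinality <- function(x) {
  stopifnot(inherits(x, "degenerate_consensus"))
  prod(lengths(x$columns))
}

#' Enumerate every sequence matching a consensus
#'
#' Mainly useful as a test oracle; refuses to enumerate more than
#' `max_n` sequences.
#'
#' @param x A [degenerate_consensus()].
#' @param max_n Enumeration guard (default 1e6).
#' @return Character vector of all matching sequences.
#' @export
enumerate_pattern <- function(x, max_n = 1e6) {
  stopifnot(inherits(x, "degenerate_consensus"))
  card <- pattern_cardinality(x)
  if (card > max_n) {
    stop("pattern matches ", card, " sequences; refusing to enumerate > ",
         max_n)
  }
  grid <- expand.grid(x$columns, stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

#' Positions at which two consensus patterns differ
#'
#' Comparison is set-based per column, so bracket ordering is irrelevant.
#'
#' @param a,b Two [degenerate_consensus()] objects of equal length.
#' @return Integer vector of 1-based column indices where the sets differ.
#' @export
diff_patterns <- function(a, b) {
  stopifnot(inherits(a, "degenerate_consensus"),
            inherits(b, "degenerate_consensus"))
  if (length(a$columns) != length(b$columns)) {
    stop("patterns have different lengths (", length(a$columns), " vs ",
         length(b$columns), ")")
  }
  which(!mapply(setequal, a$columns, b$columns))
}

#' Does a sequence match a consensus?
#'
#' Column-wise set membership; `N` matches nothing.
#'
#' @param seq Nucleotide string of the same length as the pattern.
#' @param x A [degenerate_consensus()].
#' @return Logical.
#' @export
matches_pattern <- function(seq, x) {
  stopifnot(inherits(x, "degenerate_consensus"))
  if (nchar(seq) != length(x$columns)) return(FALSE)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  all(mapply(`%in%`, chars, x$columns))
}

#' Stack candidate sequences with flanking genome sequence
#'
#' Candidates found by [find_candidates()] are fixed-length, indel-free
#' best-match hits, so multiple alignment reduces to anchored ungapped
#' stacking: each row is the oriented candidate extended by `flank` bp of
#' genome sequence on each side, and rows are stacked with candidate starts
#' vertically aligned. Rows running past a genome end are N-padded so all
#' rows keep equal length.
#'
#' @param candidates Data.frame from [find_candidates()]; rows may come from
#'   several genomes.
#' @param genomes A [genome_sequence()] or a named list of them (names =
#'   `genome_id`).
#' @param flank Flanking bp on each side (default 20).
#' @return An object of class `aligned_candidates`: list with `rows`
#'   (equal-length oriented strings), `anchor_col` (0-based column where the
#'   candidates start) and `anchor_len` (candidate length).
#' @export
align_candidates <- function(candidates, genomes, flank = 20L) {
  if (nrow(candidates) < 2L) {
    stop("need at least 2 candidates to align (got ", nrow(candidates), ")")
  }
  if (inherits(genomes, "genome_sequence")) {
    genomes <- stats::setNames(list(genomes), genomes$id)
  }
  flank <- as.integer(flank)
  k <- unique(candidates$end - candidates$start)
  if (length(k) != 1L) stop("candidates have unequal lengths")
  rows <- vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    g <- genomes[[cand$genome_id]]
    if (is.null(g)) stop("no genome supplied for id '", cand$genome_id, "'")
    s0 <- cand$start - flank
    e0 <- cand$end + flank
    lpad <- max(0L, -s0)
    rpad <- max(0L, e0 - g$length)
    row <- paste0(strrep("N", lpad), .slice(g, max(s0, 0L), min(e0, g$length)),
                  strrep("N", rpad))
    if (cand$strand == "-") revcomp(row) else row
  }, "")
  structure(list(rows = rows, anchor_col = flank, anchor_len = k),
            class = "aligned_candidates")
}

#' Construct aligned candidate rows directly
#'
#' Escape hatch for building an [align_candidates()]-style stack from raw
#' equal-length oriented strings (e.g. sampled from a known pattern).
#'
#' @param rows Equal-length nucleotide strings, 5'->3' on the packaging
#'   strand.
#' @param anchor_col 0-based column index where the candidate region starts.
#' @param anchor_len Candidate region length; defaults to the row length
#'   minus `anchor_col`.
#' @return An `aligned_candidates` object.
#' @export
aligned_candidates <- function(rows, anchor_col = 0L,
                               anchor_len = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  widths <- unique(nchar(rows))
  if (length(widths) != 1L) stop("aligned rows must have equal length")
  anchor_col <- as.integer(anchor_col)
  if (is.null(anchor_len)) anchor_len <- widths - anchor_col
  anchor_len <- as.integer(anchor_len)
  stopifnot(anchor_col >= 0L, anchor_len >= 1L,
            anchor_col + anchor_len <= widths)
  structure(list(rows = toupper(rows), anchor_col = anchor_col,
                 anchor_len = anchor_len),
            class = "aligned_candidates")
}

#' Build a degenerate consensus from aligned candidates
#'
#' Per column the allowed set is the set of bases observed across rows (`N`
#' ignored). A column is conserved iff its set has at most `max_variants`
#' distinct bases. The consensus is the maximal contiguous run of conserved
#' columns containing the anchored seed region, mirroring the practice of
#' extending a consensus to cover all strongly conserved alignment columns.
#'
#' `min_rows_fraction` relaxes the observed-base rule: per column, bases are
#' ranked by frequency (ties in A < C < G < T order) and the smallest set
#' covering at least that fraction of rows is kept. The default 1.0 keeps
#' every observed base.
#'
#' @param aligned An [align_candidates()] / [aligned_candidates()] object
#'   with at least 2 rows.
#' @param max_variants Maximum distinct bases for a conserved column
#'   (default 3).
#' @param min_rows_fraction Fraction of rows a column's kept bases must
#'   cover (default 1.0 = all observed bases).
#' @return A [degenerate_consensus()] with `seed_span` marking the anchored
#'   seed region within the returned columns.
#' @export
build_consensus <- function(aligned, max_variants = 3L,
                            min_rows_fraction = 1.0) {
  stopifnot(inherits(aligned, "aligned_candidates"))
  if (length(aligned$rows) < 2L) {
    stop("need at least 2 aligned rows to build a consensus")
  }
  stopifnot(max_variants >= 1L, min_rows_fraction > 0,
            min_rows_fraction <= 1)
  mat <- do.call(rbind, strsplit(aligned$rows, "", fixed = TRUE))
  ncols <- ncol(mat)
  sets <- vector("list", ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (!length(col)) { sets[[j]] <- character(0); next }
    counts <- table(factor(col, levels = .BASES))
    counts <- counts[counts > 0]
    ord <- order(-counts, match(names(counts), .BASES))
    counts <- counts[ord]
    need <- min_rows_fraction * length(col)
    keep <- which(cumsum(counts) >= need)[1]
    sets[[j]] <- names(counts)[seq_len(keep)]
  }
  conserved <- lengths(sets) >= 1L & lengths(sets) <= max_variants
  seed_cols <- (aligned$anchor_col + 1L):(aligned$anchor_col +
                                            aligned$anchor_len)
  if (!all(conserved[seed_cols])) {
    bad <- seed_cols[!conserved[seed_cols]]
    stop("no conserved run covers the seed region: column(s) ",
         paste(bad, collapse = ", "), " exceed max_variants = ",
         max_variants)
  }
  lo <- seed_cols[1]
  while (lo > 1L && conserved[lo - 1L]) lo <- lo - 1L
  hi <- seed_cols[length(seed_cols)]
  while (hi < ncols && conserved[hi + 1L]) hi <- hi + 1L
  degenerate_consensus(sets[lo:hi],
                       seed_span = c(seed_cols[1] - lo,
                                     seed_cols[length(seed_cols)] - lo + 1L))
}

# Reverse complement of a consensus: reversed column order, complemented
# sets. Used to scan the reverse strand by scanning the forward string.
.revcomp_pattern <- function(x) {
  cols <- rev(lapply(x$columns, function(col) unname(.COMPLEMENT[col])))
  degenerate_consensus(cols)
}
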