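test_that("patterns parse, canonicalize, and round-trip", {
  p <- parse_pattern("AAG[AG]")
  expect_equal(length(p), 4L)
  expect_equal(p$columns[[4]], c("A", "G"))
  # whitespace between tokens is tolerated (patterns are sometimes printed
  # with a stray space)
  expect_equal(emit_pattern(parse_pattern("AAG [AG]\t[TC]")),
               "AAG[AG][CT]")
  # bracket content is canonicalized to A<C<G<T order
  expect_equal(emit_pattern(parse_pattern("AA[GC]")), "AA[CG]")
  expect_equal(emit_pattern(degenerate_consensus(list("A", "A", "G"))),
               "AAG")

  set.seed(21)
  for (i in 1:40) {
    cols <- rand_columns(sample(2:10, 1), max_set = 4)
    p <- degenerate_consensus(cols)
    expect_equal(parse_pattern(emit_pattern(p))$columns, p$columns)
  }
})

test_that("malformed patterns are rejected", {
  expect_error(parse_pattern("A[]G"), "empty bracket")
  expect_error(parse_pattern(""), "empty pattern")
  expect_error(parse_pattern("A[XY]G"), "malformed")
  expect_error(parse_pattern("A[AG"), "malformed")
  expect_error(parse_pattern("AQG"), "malformed")
  expect_error(degenerate_consensus(list(character(0))))
})

test_that("pattern algebra: cardinality, diff, and column edits", {
  p <- parse_pattern("AAG[AG][TC]")
  expect_equal(pattern_cardinality(p), 4)
  seqs <- enumerate_pattern(p)
  expect_equal(length(unique(seqs)), 4)
  expect_true(all(vapply(seqs, matches_pattern, TRUE, x = p)))
  expect_equal(pattern_cardinality(parse_pattern("ACGT")), 1)

  expect_equal(diff_patterns(p, p), integer(0))
  q <- edit_column(p, 2, c("A", "T"))
  expect_equal(diff_patterns(p, q), 2L)
  expect_equal(emit_pattern(edit_column(p, 2, "A")), emit_pattern(p))
  expect_error(edit_column(p, 0, "A"), "out of range")
  expect_error(edit_column(p, 6, "A"), "out of range")
  expect_error(diff_patterns(p, parse_pattern("AAG")), "different lengths")

  set.seed(31)
  for (i in 1:20) {
    cols <- rand_columns(8)
    base <- degenerate_consensus(cols)
    j <- sample(8, 1)
    new_set <- sort(sample(BASES, sample(1:3, 1)))
    pert <- edit_column(base, j, new_set)
    expect_equal(diff_patterns(base, pert),
                 if (setequal(cols[[j]], new_set)) integer(0) else j)
  }
})

test_that("observed bases form columns; conservation trims the run", {
  al <- aligned_candidates(c("AAGA", "AAGG"), anchor_col = 0)
  cons <- build_consensus(al)
  expect_equal(emit_pattern(cons), "AAG[AG]")
  expect_equal(cons$seed_span, c(0L, 4L))

  # a 4-variant column terminates the conserved run outside the seed span
  rows <- c("AAAGAT", "CAAGAT", "GAAGAT", "TAAGAT")
  cons2 <- build_consensus(aligned_candidates(rows, anchor_col = 1,
                                              anchor_len = 5))
  expect_equal(emit_pattern(cons2), "AAGAT")
  expect_equal(cons2$seed_span, c(0L, 5L))

  # ... but inside the seed span it is an error
  bad <- c("AAAGAT", "CAAGAT", "GAAGAT", "TAAGAT")
  expect_error(build_consensus(aligned_candidates(bad, anchor_col = 0)),
               "no conserved run")
  expect_error(build_consensus(aligned_candidates("ACGT", 0)), "at least 2")
})

test_that("N-padded columns are ignored and can terminate the run", {
  # leading column is all-N (edge padding): excluded from the consensus
  rows <- c("NACGT", "NACGT")
  cons <- build_consensus(aligned_candidates(rows, anchor_col = 1,
                                             anchor_len = 4))
  expect_equal(emit_pattern(cons), "ACGT")
  # N inside a column is ignored for the observed set
  rows2 <- c("AANGT", "AACGT")
  cons2 <- build_consensus(aligned_candidates(rows2, anchor_col = 0))
  expect_equal(emit_pattern(cons2), "AACGT")
})

test_that("min_rows_fraction drops rare bases", {
  rows <- c(rep("A", 9), "G")
  al <- aligned_candidates(rows, anchor_col = 0)
  expect_equal(build_consensus(al)$columns[[1]], c("A", "G"))
  expect_equal(build_consensus(al, min_rows_fraction = 0.9)$columns[[1]],
               "A")
})

test_that("consensus building is order-invariant and sound", {
  set.seed(41)
  pat <- pseudo_pac_pattern("final")
  rows <- vapply(1:8, function(i) draw_site_sequence(pat), "")
  al <- aligned_candidates(rows, anchor_col = 0)
  cons <- build_consensus(al, max_variants = 4)
  al2 <- aligned_candidates(rev(rows), anchor_col = 0)
  expect_equal(build_consensus(al2, max_variants = 4)$columns,
               cons$columns)
  # soundness: every row matches the consensus over the seed span
  lo <- cons$seed_span[1]
  for (r in rows) {
    expect_true(matches_pattern(substr(r, lo + 1, lo + length(cons)), cons))
  }
})

test_that("sampled rows recover the generative columns as rows grow", {
  set.seed(51)
  pat <- pseudo_pac_pattern("final")
  draw_rows <- function(n) vapply(seq_len(n), function(i)
    draw_site_sequence(pat), "")
  few <- build_consensus(aligned_candidates(draw_rows(8), 0),
                         max_variants = 4)
  expect_true(all(mapply(function(got, want) all(got %in% want),
                         few$columns, pat$columns)))
  many <- build_consensus(aligned_candidates(draw_rows(200), 0),
                          max_variants = 4)
  expect_equal(many$columns, pat$columns)
})

test_that("alignment stacks oriented candidates with N edge padding", {
  g <- genome_sequence("g", strrep("A", 10) %+% "CCGG" %+% strrep("T", 10))
  cand <- data.frame(site = 1:2, genome_id = "g", start = c(10, 10),
                     end = c(14, 14), strand = c("+", "+"),
                     seq = c("CCGG", "CCGG"), mismatches = 0L)
  al <- align_candidates(cand, g, flank = 12)
  expect_equal(nchar(al$rows[1]), 4 + 24)
  expect_true(startsWith(al$rows[1], "NN"))   # clamped at the genome start
  expect_true(endsWith(al$rows[1], "NN"))
  expect_equal(al$anchor_col, 12L)

  # a minus candidate contributes its packaging-strand sequence
  cand2 <- data.frame(site = 1:2, genome_id = "g", start = c(10, 10),
                      end = c(14, 14), strand = c("-", "-"),
                      seq = "CCGG", mismatches = 0L)
  al2 <- align_candidates(cand2, g, flank = 2)
  expect_equal(substr(al2$rows[1], 3, 6), revcomp("CCGG"))
})
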