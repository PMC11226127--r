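test_that("planted pattern instances are found on both strands", {
  set.seed(61)
  pat <- pseudo_pac_pattern("final")
  inst <- draw_site_sequence(pat)
  g <- genome_sequence("g", strrep("T", 100) %+% inst %+% strrep("T", 100))
  hits <- scan_genome(g, pat)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 100)
  expect_equal(hits$strand, "+")
  expect_equal(hits$seq, inst)

  grc <- genome_sequence("g", revcomp(g$seq))
  hits2 <- scan_genome(grc, pat)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, g$length - 100 - length(pat))
  expect_equal(hits2$seq, inst)
})

test_that("overlapping and palindromic matches are all reported", {
  pat <- parse_pattern("AT")
  g <- genome_sequence("g", "ATAT")
  hits <- scan_genome(g, pat)
  # AT at 0 and 2 on both strands: palindromic hits give + and - records
  expect_equal(nrow(hits), 4L)
  expect_equal(hits$start, c(0, 0, 2, 2))
  expect_equal(hits$strand, c("+", "-", "+", "-"))

  # cmd-style single match: AAG[AG] over genome AAGA
  one <- scan_genome(genome_sequence("g", "AAGA"), parse_pattern("AAG[AG]"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$strand, "+")

  expect_error(scan_genome(genome_sequence("g", "AC"),
                           parse_pattern("ACGT")), "longer than genome")
})

test_that("N matches no consensus column", {
  pat <- parse_pattern("A[AC]G")
  g <- genome_sequence("g", "ANGTTT")
  expect_equal(nrow(scan_genome(g, pat)), 0L)
})

test_that("scanning agrees with brute force and with an IUPAC matcher", {
  set.seed(71)
  for (i in 1:30) {
    g <- genome_sequence("g", rand_seq(sample(150:400, 1)))
    pat <- degenerate_consensus(rand_columns(sample(3:7, 1)))
    got <- scan_genome(g, pat)
    want <- bf_scan(g$seq, pat$columns)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$seq, want$seq)
  }

  # independent cross-check via Biostrings ambiguity matching
  g <- genome_sequence("g", rand_seq(20000))
  pat <- pseudo_pac_pattern("final")
  got <- scan_genome(g, pat)
  iupac <- paste(vapply(pat$columns, function(col)
    Biostrings::mergeIUPACLetters(paste(col, collapse = "")), ""),
    collapse = "")
  subj <- Biostrings::DNAString(g$seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(iupac, subj,
                                                    fixed = FALSE)) - 1L
  rev_ <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(iupac)), subj,
    fixed = FALSE)) - 1L
  expect_equal(sort(got$start[got$strand == "+"]), sort(fwd))
  expect_equal(sort(got$start[got$strand == "-"]), sort(rev_))
})

test_that("scanning is strand-closed under genome reverse complement", {
  set.seed(81)
  g <- genome_sequence("g", rand_seq(3000))
  pat <- degenerate_consensus(rand_columns(5))
  a <- scan_genome(g, pat)
  b <- scan_genome(genome_sequence("g", revcomp(g$seq)), pat)
  expect_equal(nrow(a), nrow(b))
  mirrored <- data.frame(start = g$length - b$end, end = g$length - b$start,
                         strand = ifelse(b$strand == "+", "-", "+"),
                         seq = b$seq)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(mirrored$start, a$start)
  expect_equal(mirrored$strand, a$strand)
  expect_equal(mirrored$seq, a$seq)
})

test_that("widening a column never removes matches", {
  set.seed(91)
  g <- genome_sequence("g", rand_seq(30000))
  narrow <- pseudo_pac_pattern("initial")
  wide <- pseudo_pac_pattern("final")   # column 3 widened G -> GC
  a <- scan_genome(g, narrow)
  b <- scan_genome(g, wide)
  expect_true(all(paste(a$start, a$strand) %in% paste(b$start, b$strand)))
})

test_that("count_matches is consistent and near the analytic expectation", {
  set.seed(101)
  pat <- pseudo_pac_pattern("final")
  inst <- draw_site_sequence(pat)
  g <- genome_sequence("g", strrep("T", 50) %+% inst %+% strrep("T", 50) %+%
                         inst %+% strrep("T", 50))
  cm <- count_matches(g, pat)
  expect_equal(unname(cm["total"]), 2)
  expect_equal(unname(cm["forward"]), 2)
  expect_equal(unname(cm["total"]), nrow(scan_genome(g, pat)))
  expect_equal(unname(count_matches(genome_sequence("g", strrep("T", 100)),
                                    pat)), c(0, 0, 0))

  # expected matches in iid uniform sequence: 2*(L-k+1)*card/4^k
  cols6 <- lapply(1:6, function(i) c("A", "C"))
  pat6 <- degenerate_consensus(cols6)
  L <- 2000
  n_rep <- 50
  counts <- vapply(seq_len(n_rep), function(i) {
    unname(count_matches(genome_sequence("g", rand_seq(L)), pat6)["total"])
  }, 0)
  expected <- 2 * (L - 6 + 1) * 64 / 4^6
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})
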