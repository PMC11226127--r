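test_that("site draws always match the pattern and cover its space", {
  single <- parse_pattern("ACGT")
  expect_equal(draw_site_sequence(single), "ACGT")

  init <- pseudo_pac_pattern("initial")
  # taking each column's first base (canonical or printed order) gives a
  # valid instance
  first <- paste(vapply(init$columns, `[`, "", 1L), collapse = "")
  expect_true(matches_pattern(first, init))
  expect_true(matches_pattern("AAGATAAATTTGAAATC", init))

  set.seed(111)
  draws <- vapply(1:3000, function(i) draw_site_sequence(init), "")
  expect_true(all(vapply(draws, matches_pattern, TRUE, x = init)))
  # uniform over the 10368 instances: distinct count near its expectation
  expect_gt(length(unique(draws)), 2400)
  expect_lt(length(unique(draws)), 2800)
})

test_that("genomes plant oriented site sequences with required separation", {
  cfg <- small_sim_config(seed = 12, n_sites = 4L)
  sim <- simulate_genome(cfg)
  truth <- sim$truth
  expect_equal(nrow(truth), 4L)
  expect_true(all(diff(truth$start) >= 2 * cfg$headful))
  for (i in seq_len(nrow(truth))) {
    fwd <- substr(sim$genome$seq, truth$start[i] + 1, truth$end[i])
    planted <- if (truth$strand[i] == "-") revcomp(truth$seq[i]) else
      truth$seq[i]
    expect_equal(fwd, planted)
    expect_true(matches_pattern(truth$seq[i], cfg$site_pattern))
  }
  # the scanner recovers every planted locus
  hits <- scan_genome(sim$genome, cfg$site_pattern)
  for (i in seq_len(nrow(truth))) {
    expect_true(any(hits$start == truth$start[i] &
                      hits$strand == truth$strand[i]))
  }

  empty <- simulate_genome(simulation_config(genome_length = 1e5,
                                             n_sites = 0L, seed = 1))
  expect_equal(nrow(empty$truth), 0L)

  expect_error(simulate_genome(simulation_config(genome_length = 1e5,
                                                 n_sites = 8L, seed = 1)),
               "cannot place")
})

test_that("a degenerate configuration yields exact coverage", {
  cfg <- simulation_config(genome_length = 2e5, n_sites = 1L,
                           site_pattern = parse_pattern(pac_seed()),
                           strands = "+", headful = 10000L,
                           series_mean = 1, series_max = 1L,
                           events_per_site = 50L, cut_jitter = 0L,
                           background_rate = 0, seed = 5)
  sim <- simulate_genome(cfg)
  track <- simulate_packaging_coverage(sim$genome, sim$truth, cfg)
  s <- sim$truth$start[1]
  expect_equal(s %% 1, 0)
  v <- track$values
  covered <- which(v > 0)
  # depth is exactly events_per_site over [site, site + headful)
  first_bin <- floor(s / 25)
  expect_equal(min(covered) - 1, first_bin)
  inner <- (first_bin + 2):(floor((s + 10000) / 25) - 1)
  expect_true(all(v[inner] == 50))
  expect_equal(attr(track, "event_mass"), 50 * 10000)
  # mass conservation through binning
  expect_equal(sum(v * bin_widths(track)), 50 * 10000, tolerance = 1e-9)
})

test_that("zero events leave pure Poisson background", {
  cfg <- simulation_config(genome_length = 2e5, n_sites = 0L,
                           events_per_site = 0L, background_rate = 2,
                           seed = 6)
  sim <- simulate_genome(cfg)
  track <- simulate_packaging_coverage(sim$genome, sim$truth, cfg)
  expect_equal(attr(track, "event_mass"), 0)
  nb <- length(track$values)
  se <- sqrt(2 / nb)
  expect_lt(abs(mean(track$values) - 2), 3 * se)
  expect_identical(track$values - attr(track, "background_draws"),
                   rep(0, nb))
})

test_that("downstream depth follows the truncated-geometric tail", {
  cfg <- simulation_config(genome_length = 3e5, n_sites = 1L,
                           site_pattern = parse_pattern(pac_seed()),
                           strands = "+", headful = 5000L, series_mean = 5,
                           series_max = 12L, events_per_site = 400L,
                           cut_jitter = 0L, background_rate = 0, seed = 7)
  sim <- simulate_genome(cfg)
  track <- simulate_packaging_coverage(sim$genome, sim$truth, cfg)
  s <- sim$truth$start[1]
  p <- 1 / 5
  probs <- (1 - p)^(0:11) * p
  probs <- probs / sum(probs)
  tail_p <- function(m) sum(probs[(m + 1):12])   # P(series > m headfuls)
  for (m in c(0, 1, 3, 6, 10)) {
    d <- m * 5000 + 2500                         # mid-headful distance
    bin <- floor((s + d) / 25) + 1
    want <- 400 * tail_p(m)
    se <- sqrt(400 * tail_p(m) * (1 - tail_p(m)))
    expect_lt(abs(track$values[bin] - want), 3 * se + 1e-9)
  }
})

test_that("mirrored truth with the same seed mirrors the coverage", {
  L <- 4e5
  cfg <- simulation_config(genome_length = L, n_sites = 1L, strands = "+",
                           headful = 20000L, events_per_site = 100L,
                           seed = 8)
  g <- genome_sequence("sim", strrep("A", L))
  truth_f <- data.frame(genome_id = "sim", start = 150000L,
                        end = 150017L, strand = "+", seq = "x")
  truth_r <- data.frame(genome_id = "sim", start = L - 150017L,
                        end = L - 150000L, strand = "-", seq = "x")
  cfg0 <- cfg; cfg0$background_rate <- 0
  a <- simulate_packaging_coverage(g, truth_f, cfg0)
  b <- simulate_packaging_coverage(g, truth_r, cfg0)
  expect_equal(rev(b$values), a$values)
})

test_that("write_simulation emits re-readable files", {
  cfg <- small_sim_config(seed = 13, n_sites = 2L)
  sim <- simulate_genome(cfg)
  track <- simulate_packaging_coverage(sim$genome, sim$truth, cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, track, cfg, dir)
  expect_true(all(file.exists(paths)))

  g2 <- read_genome_fasta(paths[["genome"]])[[1]]
  expect_equal(g2$seq, sim$genome$seq)
  tr2 <- read_depth(paths[["coverage"]], binsize = cfg$binsize,
                    genome_length = cfg$genome_length)
  expect_identical(tr2$values, track$values)
  bed <- rtracklayer::import(paths[["truth"]], format = "BED")
  expect_equal(GenomicRanges::start(bed) - 1L, sim$truth$start)
  expect_equal(as.character(GenomicRanges::strand(bed)), sim$truth$strand)
  expect_equal(bed$name, sim$truth$seq)
  cfg_echo <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg_echo$genome_length, cfg$genome_length)
  expect_equal(cfg_echo$site_pattern, emit_pattern(cfg$site_pattern))
})
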