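# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and share no code with the package internals.

BASES <- c("A", "C", "G", "T")

`%+%` <- function(a, b) paste0(a, b)

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Independent reverse complement (chartr + explicit reversal).
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Exhaustive best-match: every offset, character-by-character Hamming
# distance, first minimum wins.
bf_best_match <- function(window, seed) {
  k <- nchar(seed)
  best <- NULL
  for (off in 0:(nchar(window) - k)) {
    sub <- substr(window, off + 1, off + k)
    d <- sum(strsplit(sub, "")[[1]] != strsplit(seed, "")[[1]])
    if (is.null(best) || d < best$mismatches) {
      best <- list(offset = off, seq = sub, mismatches = d)
    }
  }
  best
}

# Exhaustive dual-strand scan over a list of column sets.
bf_scan <- function(seq, columns) {
  k <- length(columns)
  L <- nchar(seq)
  hits <- list()
  ok <- function(s, cols) {
    ch <- strsplit(s, "")[[1]]
    all(vapply(seq_len(k), function(j) ch[j] %in% cols[[j]], TRUE))
  }
  for (start in 0:(L - k)) {
    sub <- substr(seq, start + 1, start + k)
    if (ok(sub, columns)) {
      hits[[length(hits) + 1]] <- data.frame(start = start, strand = "+",
                                             seq = sub)
    }
    rcsub <- rc_oracle(sub)
    if (ok(rcsub, columns)) {
      hits[[length(hits) + 1]] <- data.frame(start = start, strand = "-",
                                             seq = rcsub)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), strand = character(),
                      seq = character()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random degenerate pattern as a column list.
rand_columns <- function(ncol, max_set = 3) {
  lapply(seq_len(ncol), function(i) {
    sort(sample(BASES, sample.int(max_set, 1)))
  })
}

# A step-and-linear-decay bin vector: `pre` background bins, a step to
# `high` decaying linearly back to `bg` over `decay` bins, then `post`
# background bins.
step_decay_values <- function(pre = 100, high = 100, bg = 2, decay = 400,
                              post = 100) {
  c(rep(bg, pre), seq(high, bg, length.out = decay), rep(bg, post))
}

# Small, fast simulator configuration used by several tests.
small_sim_config <- function(seed, n_sites = 3L, ...) {
  simulation_config(genome_length = 6e5, n_sites = n_sites,
                    headful = 20000L, events_per_site = 150L,
                    seed = seed, ...)
}
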