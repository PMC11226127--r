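---
title: "Discovering pseudo-pac sites from phage read coverage"
author: "pacsites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering pseudo-pac sites from phage read coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacsites)
```

## The biological signal

Headful-packaging phages such as P22 begin DNA packaging where their small
terminase recognizes a short sequence, the *pac* site, and then fill a
series of capsids processively along a DNA concatemer, each capsid taking
one fixed-size "headful". When the terminase instead recognizes a similar
sequence on the host chromosome — a *pseudo-pac* site — host DNA is
packaged and generalized transduction follows. In coverage of phage-derived
reads mapped to the host genome this leaves an unmistakable footprint: a
sudden, sharp increase in depth at the initiation site, followed by a
stair-like, strand-directional decay over hundreds of kilobases as fewer
and fewer packaging series reach farther headfuls.

`pacsites` turns that footprint into an explicit, testable pipeline:

1. **Detection** — find coverage boundaries with the jump-then-decay
   signature in a binned depth track (`detect_initiation_sites()`).
2. **Candidate search** — around each boundary, extract an oriented window
   and locate the best ungapped match to the 12-bp P22 pac consensus
   `AAGATTTATCTG` (`find_candidates()`).
3. **Consensus** — stack the candidates with flanking sequence and build a
   degenerate bracket pattern such as `AAG[AG][CT]…`
   (`build_consensus()`), with column-editing and algebra utilities
   (`edit_column()`, `pattern_cardinality()`, `diff_patterns()`).
4. **Scan** — search both strands of any genome for pattern matches
   (`scan_genome()`).
5. **Evidence** — classify each match by whether local coverage shows the
   initiation signature (`classify_matches()`, `summarize_sites()`).

A headful-packaging simulator (`simulate_genome()`,
`simulate_packaging_coverage()`) generates genomes with planted sites and
coverage with exactly this phenomenology, so every stage is tested against
known truth.

## The detection statistic

Visual identification of initiation sites is replaced by the simplest
statistic that captures "sharp increase followed by sloping decrease". For
every boundary between coverage bins (default bin size 25 bp), let `U` be
the mean of the `flank_bins` bins upstream and `D` the mean downstream
(default 20 bins each, i.e. 500 bp flanks). A `+` (rightward-packaging)
site is called when

* `D / (U + 0.5) >= min_jump_ratio` (default 3) — the half-unit offset
  tolerates a zero background without masking true jumps;
* `D - U >= min_abs_jump` (default 5 depth units);
* over the next `decay_span_bins` bins (default 400, i.e. 10 kb), at least
  `min_decay_fraction` (default 0.6) of adjacent bin pairs are
  non-increasing.

`-` sites are found by running the identical computation on the reversed
track, which makes detection *exactly* equivariant under coverage reversal
— a property the test suite asserts rather than assumes. Calls within
`min_separation` (default 50 kb) collapse to the single highest-ratio
call, ties resolved by larger absolute jump, then leftmost; the output is
therefore deterministic.

Two behaviors of this statistic are worth knowing:

* **Masking.** Packaging series are long (up to `series_max` headfuls,
  ~0.5 Mb at P22 scale), so the decay from one site frequently overlays a
  neighboring site. The overlaid site still shows a large absolute jump
  but its *ratio* to the elevated upstream flank can fall below 3, and it
  is then not called. This mirrors what is seen on real data, where some
  pattern matches show no apparent jump because more prominent packaging
  patterns cover them. The recovery harness therefore reports recall both
  over all planted sites and over *detectable* sites (those whose realized
  coverage passes the thresholds somewhere in their cut region).
* **Edge bias.** Initiation cuts are scattered over a ~120-bp region, so
  the coverage "step" is really a ramp. The highest-ratio boundary sits at
  the upstream edge of that ramp, not its center: detected positions are
  systematically offset from the motif by roughly the cut jitter. Truth
  matching in the recovery harness accordingly scores a site as recovered
  when the call falls within the planted cut region ± 2 bins.

## Candidate windows and the seed consensus

The packaging machinery cuts within a ~120-bp region around the pac site,
so a 120-bp window around each detected boundary is searched for the
best match to the seed consensus by minimizing Hamming distance (ungapped;
no indel model is warranted for a fixed-length consensus), ties to the
leftmost offset, `N` counting as a mismatch. An exhaustive brute-force
implementation serves as the oracle in tests.

Because of the edge bias above, the window is centered on the detected
boundary but can be shifted in the packaging direction with
`search_params(offset = )`. With jittered cuts, `offset` equal to the
expected jitter (60 bp) re-centers the window over the motif; the default
remains 0 (symmetric).

A caution that the simulator makes quantifiable: a 120-bp window of random
sequence often contains a 12-mer at Hamming distance 4–5 from the seed.
When the true site is itself highly degenerate (drawn from the final
17-column pattern, its seed-span bases average distance ~4 from the seed),
the best match is not always the planted locus. `run_recovery_experiment()`
reports this as `candidate_accuracy`, and reports consensus containment
both for the as-run candidates and for truth-anchored candidates, so the
consensus stage can be judged separately from best-match specificity. In
the zero-entropy limit (planted sites identical to the seed, no jitter)
candidate recovery is exact, which the acceptance tests assert.

## Consensus construction

Candidates found this way are equal-length, indel-free hits, so a multiple
sequence alignment reduces to *anchored ungapped stacking*: each candidate
is extended by `flank` bp (default 20) of genome sequence on each side,
oriented 5'→3' on its packaging strand, and rows are stacked with
candidate starts aligned; genome ends are `N`-padded. Per column, the
allowed set is the set of bases observed across rows (`N` ignored). A
column is *conserved* when it has at most `max_variants` (default 3)
distinct bases — consistent with published bracket patterns containing at
most three-base groups — and the consensus is the maximal run of conserved
columns containing the seed region, which reproduces the practice of
widening a consensus to cover all strongly conserved alignment columns.

`min_rows_fraction` relaxes the observed-base rule coherently: bases in a
column are ranked by frequency and the smallest set covering at least that
fraction of rows is kept. The default 1.0 keeps every observed base;
0.9 would drop bases seen in fewer than 10% of rows. Patterns are emitted
in canonical bracket style (bases in `A<C<G<T` order) and all pattern
comparisons are set-based, so `[GC]` and `[CG]` are the same column.

The package ships the two published P22 pseudo-pac patterns
(`pseudo_pac_pattern("initial")` and `"final"`, differing only at position
three, `G` versus `[GC]`) with the 12-bp pac seed matching columns 1–12;
the test suite verifies their column counts, enumerated cardinalities
(10368 and 20736), and the position-3 edit by exhaustive enumeration.

## Scanning and evidence

`scan_genome()` matches column sets directly rather than delegating to a
general regular-expression engine: the reverse strand is scanned by
sliding the reverse-complemented pattern along the forward string, so
strand symmetry is provable (and asserted exactly in tests, alongside a
brute-force oracle and an independent IUPAC ambiguity matcher as
cross-checks). All overlapping matches are reported; a palindromic hit
yields one `+` and one `-` record; `N` matches nothing. Widening any
column never removes a match — the monotonicity that lets a relaxed
pattern reveal additional sites.

Each match is then scored with the *same* jump-then-decay statistic used
for detection, evaluated at the match position in the orientation implied
by its strand (best boundary within a fixed 3-bin slack, accommodating the
cut-region width). A match is `supported` when both the jump ratio and
decay fraction reach the detection thresholds. `summarize_sites()` numbers
coverage-detected sites first, then supported scan-only sites, mirroring
how sites found by eye precede sites found by pattern search.

## The simulator

`simulation_config()` defaults describe the study conditions end to end: a
2 Mb host genome with 8 planted sites drawn from the final pattern
(placed ≥ 2 headfuls apart), headful size 43 kb (a plausible P22-scale
constant, exposed as configuration), 200 initiation events per site, cut
positions jittered uniformly within ±60 bp (the 120-bp cut region), series
lengths geometric with mean 5 truncated at 12 (memoryless capsid-series
termination — the minimal mechanism that produces the observed stair-like
decay), Poisson background of mean 1 per 25-bp bin. Reads are not
simulated individually; depth increments stand in for pileups, since every
downstream stage consumes depth.

What the simulator does *not* emulate: sequencing error, mapping
ambiguity, read-length effects, GC bias, or any sequence preference in
where series terminate. Passing recovery tests therefore demonstrate the
pipeline's correctness against the modeled phenomenology, not performance
on real libraries. One modeling artifact is worth noting: truncating the
geometric series at 12 headfuls creates a small genuine step exactly
12 headfuls from a site, which detection occasionally (correctly) flags as
a weak initiation-like signal; the tests verify that any extra call sits
at such a truncation edge.

Mass conservation (total binned depth × width = clipped event bases +
background draws), mirrored-configuration symmetry, and the closed-form
truncated-geometric depth profile are all asserted in the test suite.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based only in the
  human-facing site table (the TSV header says so). BED and bedGraph
  follow their standards.
* Depth files may be per-base TSV (chrom, 1-based position, depth) or
  bedGraph; the dialect is auto-detected from the column count (3 versus
  4) and can be forced. Absent positions are depth 0; a final partial bin
  averages over its actual width.
* `write_bedgraph()` writes scores with 17 significant digits so a track
  re-read at its own bin size is bit-identical; bin-aligned bedGraph input
  is taken verbatim without re-averaging.
* Empty depth files yield an all-zero track (length must then be given);
  an all-zero track yields zero sites and an empty site table, cleanly.
* Windows running past a genome end are clamped with a warning, never
  silently; a genome shorter than the window is an error.
* Tie-breaks everywhere are deterministic (leftmost offset, largest jump,
  then leftmost position), so identical configuration and seed give
  byte-identical outputs.

## Problem sizes used in the checks

The recovery experiments in the test suite and the acceptance script run
the full pipeline on 2 Mb genomes with 8 planted sites (ten replicate
seeds, a few seconds each); module-level property tests use 0.6 Mb
genomes and small random instances (hundreds of windows and genomes per
oracle comparison). These sizes give stable statistics for every asserted
property while keeping a full run fast on a single CPU.

## Known limitations

* The detection thresholds operationalize a judgment that was originally
  visual; they are calibrated against the simulator's phenomenology, not
  against any particular sequencing library.
* The ratio test cannot call a site whose upstream flank is strongly
  elevated by a neighboring site's packaging series (masking); such sites
  are still usually recovered by the pattern scan and classified by the
  evidence module, which is exactly the role the scan plays on real data.
* Best-match candidate search against a short seed has limited
  specificity in 120-bp windows; treat candidate sequences from weakly
  conserved sites with care, and prefer the consensus/scan/evidence loop
  for final calls.
* Approximate (mismatch-tolerant) pattern scanning and position-weight
  matrices are out of scope; patterns are exact per-column sets.
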