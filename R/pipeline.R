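#' Read a pipeline configuration file
#'
#' YAML with top-level keys `genome_fasta`, `depth_file`, `out_dir`,
#' `binsize`, `seed`, `pattern` (optional bracket-style scan override) and
#' nested sections `detection`, `search`, `consensus` whose entries override
#' the defaults of [detection_params()], [search_params()] and the
#' consensus options (`flank`, `max_variants`).
#'
#' @param path Path to a YAML file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.merge_params <- function(constructor, overrides) {
  do.call(constructor, as.list(overrides %||% list()))
}

#' Run the full pseudo-pac discovery pipeline
#'
#' detect -> window search -> consensus -> dual-strand scan -> coverage
#' evidence, writing each stage's standard files into `out_dir`:
#' `sites.bed`, `candidates.bed`, `candidates.fasta`, `consensus.txt`,
#' `matches.bed`, `site_table.tsv` and `run_log.json` (parameters, seed and
#' input checksums). Each file is written to a temporary name and renamed on
#' success, so a failed stage leaves no partial output.
#'
#' @param config A list as returned by [read_pipeline_config()], or a path
#'   to a YAML config.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (key in c("genome_fasta", "depth_file", "out_dir")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  }
  if (!file.exists(config$genome_fasta)) {
    stop("genome FASTA not found: ", config$genome_fasta)
  }
  if (!file.exists(config$depth_file)) {
    stop("depth file not found: ", config$depth_file)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  detection <- .merge_params(detection_params, config$detection)
  search <- .merge_params(search_params, config$search)
  flank <- config$consensus$flank %||% 20L
  max_variants <- config$consensus$max_variants %||% 3L
  binsize <- config$binsize %||% 25L

  genomes <- read_genome_fasta(config$genome_fasta)
  genome <- genomes[[1L]]
  if (length(genomes) > 1L) {
    message("using first FASTA record '", genome$id, "' of ",
            length(genomes))
  }
  track <- read_depth(config$depth_file, binsize = binsize,
                      genome_length = genome$length, genome_id = genome$id)

  commit <- function(write_fun, name) {
    final <- file.path(config$out_dir, name)
    tmp <- paste0(final, ".tmp")
    write_fun(tmp)
    file.rename(tmp, final)
    final
  }

  sites <- detect_initiation_sites(track, detection)
  paths <- list(sites = commit(function(p) write_sites_bed(sites, p),
                               "sites.bed"))

  candidates <- find_candidates(genome, sites, search)
  paths$candidates_bed <- commit(function(p)
    write_candidates(candidates, bed_path = p), "candidates.bed")
  paths$candidates_fasta <- commit(function(p)
    write_candidates(candidates, fasta_path = p), "candidates.fasta")

  consensus <- NULL
  if (!is.null(config$pattern)) {
    consensus <- parse_pattern(config$pattern)
  } else if (nrow(candidates) >= 2L) {
    consensus <- tryCatch(
      build_consensus(align_candidates(candidates, genome, flank),
                      max_variants = max_variants),
      error = function(e) {
        message("consensus building failed: ", conditionMessage(e))
        NULL
      })
  }
  if (!is.null(consensus)) {
    paths$consensus <- commit(function(p)
      writeLines(emit_pattern(consensus), p), "consensus.txt")
    matches <- classify_matches(scan_genome(genome, consensus), track,
                                detection)
    paths$matches <- commit(function(p)
      write_matches_bed(matches, p), "matches.bed")
  } else {
    matches <- data.frame(genome_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          seq = character(), local_jump_ratio = numeric(),
                          decay_fraction = numeric(),
                          classification = character())
  }
  site_table <- summarize_sites(matches, candidates)
  paths$site_table <- commit(function(p)
    write_site_table(site_table, p), "site_table.tsv")

  log <- list(
    package_version = as.character(utils::packageVersion("pacsites")),
    seed = config$seed,
    binsize = binsize,
    detection = unclass(detection),
    search = unclass(search),
    consensus_options = list(flank = flank, max_variants = max_variants),
    pattern_override = config$pattern,
    inputs = list(
      genome_fasta = unname(tools::md5sum(config$genome_fasta)),
      depth_file = unname(tools::md5sum(config$depth_file))
    ),
    n_sites = nrow(sites),
    n_matches = nrow(matches),
    n_table_rows = nrow(site_table)
  )
  paths$log <- commit(function(p)
    jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE,
                         null = "null"), "run_log.json")

  invisible(list(genome = genome, track = track, sites = sites,
                 candidates = candidates, consensus = consensus,
                 matches = matches, site_table = site_table,
                 paths = paths))
}

#' Run the simulator as a pipeline stage
#'
#' Generates a simulated genome and coverage track and writes them (plus the
#' planted truth and a config echo) into `out_dir` via [write_simulation()].
#'
#' @param config A [simulation_config()] or a list of overrides for one.
#' @param out_dir Output directory.
#' @return Invisibly, the list of files written.
#' @export
run_simulation <- function(config = simulation_config(), out_dir) {
  if (!inherits(config, "sim_config")) {
    if (!is.null(config$site_pattern) &&
        is.character(config$site_pattern)) {
      config$site_pattern <- parse_pattern(config$site_pattern)
    }
    config <- do.call(simulation_config, as.list(config))
  }
  sim <- simulate_genome(config)
  track <- simulate_packaging_coverage(sim$genome, sim$truth, config)
  write_simulation(sim, track, config, out_dir)
}
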