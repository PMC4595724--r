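#' Assemble a full pipeline configuration
#'
#' Collects every tunable parameter of the simulate -> MFA -> peak-call ->
#' origin-predict pipeline in one nested list that serializes losslessly to
#' YAML. Defaults describe the wild-type study condition: a circular 2.9-Mb
#' chromosome carrying three active origins of unequal efficiency and one
#' strictly dormant origin, an asynchronous culture with half the cells
#' cycling, 34 probes per kb, and per-channel log-normal noise of 0.07.
#'
#' @param seed Integer master seed.
#' @param chromosome List with `name`, `length`, `circular`.
#' @param origins Data frame with `id`, `position`, `efficiency`.
#' @param mutant_origins Optional second origin table (same positions,
#'   different efficiencies) describing a deletion/activation strain; when
#'   present the pipeline also simulates it and calls activation events.
#' @param replication List with `fork_speed` (bp/min), `doubling_time`
#'   (min), `cycling_fraction`.
#' @param probe List with `density` (probes/kb) and `probe_length`.
#' @param noise List with `channel_log_sd`.
#' @param mfa List of MFA processing parameters: `outlier_lower`,
#'   `outlier_upper`, `bin_size`, `smooth_window`, `smooth_slide`,
#'   `read_window`.
#' @param caller List with `min_prominence` (`NULL` for the adaptive
#'   default), `min_separation`, `match_tolerance`.
#' @param orb List of sequence-prediction parameters: `min_len`, `max_len`,
#'   `max_mismatch`, `g_run`, `identity_threshold`, `max_span`.
#' @param genome List with `generate` (logical), `orb_consensus`,
#'   `orb_spacing`; when `generate` is true a synthetic genome with a cdc6
#'   locus at each origin is built and assessed by the sequence predictor.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    seed = 1,
    chromosome = list(name = "chr", length = 2.9e6, circular = TRUE),
    origins = data.frame(
      id = c("oriC1", "oriC2", "oriC3", "oriC4"),
      position = c(3e5, 1.3e6, 2.2e6, 2.7e6),
      efficiency = c(0.9, 0.5, 0.3, 0)),
    mutant_origins = NULL,
    replication = list(fork_speed = 10000, doubling_time = 180,
                       cycling_fraction = 0.5),
    probe = list(density = 34, probe_length = 50),
    noise = list(channel_log_sd = 0.07),
    mfa = list(outlier_lower = 0.5, outlier_upper = 2, bin_size = 30,
               smooth_window = 5, smooth_slide = 1, read_window = 1000),
    caller = list(min_prominence = NULL, min_separation = 1e5,
                  match_tolerance = 2e4),
    orb = list(min_len = 18, max_len = 35, max_mismatch = 3, g_run = 4,
               identity_threshold = 80, max_span = 2000),
    genome = list(generate = FALSE,
                  orb_consensus = "TTCACGGGGGTCCACTGGAAACGTACACGT",
                  orb_spacing = 30)) {
  cfg <- list(seed = seed, chromosome = chromosome,
              origins = as.data.frame(origins),
              mutant_origins = if (!is.null(mutant_origins))
                as.data.frame(mutant_origins),
              replication = replication, probe = probe, noise = noise,
              mfa = mfa, caller = caller, orb = orb, genome = genome)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks that every numeric parameter lies in its documented domain;
#' called by [pipeline_config()], [read_config()] and [run_pipeline()].
#'
#' @param config A configuration list.
#' @return The config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(config$chromosome$length > 0, "chromosome length must be > 0")
  ori <- config$origins
  chk(all(ori$position >= 0 & ori$position < config$chromosome$length),
      "origin positions must lie in [0, chromosome length)")
  chk(all(ori$efficiency >= 0 & ori$efficiency <= 1),
      "origin efficiencies must lie in [0, 1]")
  chk(config$replication$fork_speed > 0, "fork_speed must be > 0")
  chk(config$replication$doubling_time > 0, "doubling_time must be > 0")
  f <- config$replication$cycling_fraction
  chk(f >= 0 && f <= 1, "cycling_fraction must lie in [0, 1]")
  chk(config$probe$density > 0, "probe density must be > 0")
  chk(config$noise$channel_log_sd >= 0, "channel_log_sd must be >= 0")
  chk(config$mfa$outlier_lower < config$mfa$outlier_upper,
      "outlier_lower must be below outlier_upper")
  chk(config$mfa$bin_size >= 2, "bin_size must be >= 2")
  chk(config$mfa$smooth_window %% 2 == 1 && config$mfa$smooth_window >= 3,
      "smooth_window must be odd and >= 3")
  chk(config$mfa$smooth_slide == 1, "smooth_slide must be 1")
  chk(config$mfa$read_window > 0, "read_window must be > 0")
  chk(config$caller$min_separation > 0, "min_separation must be > 0")
  chk(config$caller$match_tolerance > 0, "match_tolerance must be > 0")
  chk(config$orb$min_len >= 2 && config$orb$max_len >= config$orb$min_len,
      "motif length bounds are inconsistent")
  chk(config$orb$max_mismatch >= 0, "max_mismatch must be >= 0")
  chk(config$orb$g_run >= 1, "g_run must be >= 1")
  invisible(config)
}

#' Read and write pipeline configurations as YAML
#'
#' Serialization round-trips losslessly: `read_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  ser$origins <- as.list(as.data.frame(ser$origins))
  if (!is.null(ser$mutant_origins))
    ser$mutant_origins <- as.list(as.data.frame(ser$mutant_origins))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$origins <- as.data.frame(raw$origins, stringsAsFactors = FALSE)
  if (!is.null(raw$mutant_origins))
    raw$mutant_origins <- as.data.frame(raw$mutant_origins,
                                        stringsAsFactors = FALSE)
  cfg <- structure(raw, class = "pipeline_config")
  validate_config(cfg)
  cfg
}

# Deterministic polynomial hash of the config's YAML serialization, used
# to stamp outputs with their provenance.
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the end-to-end replication-profiling pipeline
#'
#' Executes simulate -> MFA processing -> peak calling -> (optionally)
#' parent/mutant activation comparison -> (optionally) sequence-based
#' origin prediction and active/dormant classification, under a single
#' configuration and seed. All stages are deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, the genome FASTA
#'   and GFF3 (if generated), probe table TSV, binned and smoothed
#'   bedGraph tracks, peak BED6 (+ JSON sidecar) and the JSON report are
#'   written there, each stamped with the config hash and seed.
#' @return A result bundle: list with `chromosome`, `profiles`, `peaks`,
#'   `activation` (or `NULL`), `predictions`, `classification`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  validate_config(config)
  seed <- config$seed
  chrom_cfg <- config$chromosome
  origins <- origin_set(config$origins$id, config$origins$position,
                        config$origins$efficiency)
  params <- replication_params(config$replication$fork_speed,
                               config$replication$doubling_time,
                               config$replication$cycling_fraction)
  design <- probe_design(chrom_cfg$length, config$probe$density,
                         config$probe$probe_length)
  noise <- noise_model(config$noise$channel_log_sd)

  genome <- NULL
  if (isTRUE(config$genome$generate)) {
    loci <- data.frame(position = origins$position, strand = "+",
                       id = origins$id)
    genome <- generate_genome(chrom_cfg$length, loci,
                              config$genome$orb_consensus,
                              config$genome$orb_spacing, seed = seed)
    chrom <- genome$chromosome
    chrom$name <- chrom_cfg$name
  } else {
    chrom <- chromosome(chrom_cfg$name, chrom_cfg$length,
                        isTRUE(chrom_cfg$circular))
  }

  process <- function(ori_tab, stage_seed) {
    tab <- simulate_microarray(chrom, ori_tab, params, design, noise,
                               seed = stage_seed)
    tab <- filter_outliers(tab, config$mfa$outlier_lower,
                           config$mfa$outlier_upper)
    prof <- smooth_profile(bin_probes(tab, config$mfa$bin_size),
                           config$mfa$smooth_window,
                           config$mfa$smooth_slide)
    pk <- call_peaks(prof, config$caller$min_prominence,
                     config$caller$min_separation)
    if (nrow(pk)) pk <- estimate_efficiency(pk, prof)
    list(table = tab, profile = prof, peaks = pk)
  }

  wt <- process(origins, seed)
  activation <- NULL
  mut <- NULL
  if (!is.null(config$mutant_origins)) {
    mutant <- origin_set(config$mutant_origins$id,
                         config$mutant_origins$position,
                         config$mutant_origins$efficiency)
    mut <- process(mutant, seed + 1)
    activation <- compare_profiles(wt$peaks, mut$peaks,
                                   config$origins[, c("id", "position")],
                                   config$caller$match_tolerance)
  }

  predictions <- NULL
  classification <- NULL
  if (!is.null(genome)) {
    predictions <- predict_origins(genome$chromosome, genome$annotation,
                                   origins$id,
                                   max_span = config$orb$max_span,
                                   min_len = config$orb$min_len,
                                   max_len = config$orb$max_len,
                                   max_mismatch = config$orb$max_mismatch,
                                   g_run = config$orb$g_run)
    if (length(predictions$predictions))
      classification <- classify_predicted_origins(
        predictions, wt$peaks, config$caller$match_tolerance)
  }

  report <- list(
    config_hash = config_hash(config),
    seed = seed,
    n_probes = nrow(wt$table),
    excluded_fraction = attr(wt$table, "excluded_fraction"),
    n_profile_points = nrow(wt$profile),
    n_peaks = nrow(wt$peaks),
    peaks = as.data.frame(wt$peaks),
    activation = if (!is.null(activation)) as.data.frame(activation),
    n_predictions = if (!is.null(predictions))
      length(predictions$predictions),
    classification = classification,
    parameters = unclass(config))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stamp <- paste0(report$config_hash, "_seed", seed)
    if (!is.null(genome)) {
      write_genome_fasta(genome$chromosome,
                         file.path(outdir, paste0(stamp, "_genome.fasta")))
      write_annotation_gff3(genome$annotation,
                            file.path(outdir, paste0(stamp, ".gff3")))
    }
    write_probe_table(wt$table,
                      file.path(outdir, paste0(stamp, "_probes.tsv")))
    write_profile_bedgraph(wt$profile,
                           file.path(outdir,
                                     paste0(stamp, "_profile.bedGraph")))
    if (nrow(wt$peaks))
      write_peaks_bed(wt$peaks,
                      file.path(outdir, paste0(stamp, "_peaks.bed")))
    jsonlite::write_json(report,
                         file.path(outdir, paste0(stamp, "_report.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  list(chromosome = chrom, genome = genome,
       profiles = list(wt = wt$profile,
                       mutant = if (!is.null(mut)) mut$profile),
       peaks = list(wt = wt$peaks,
                    mutant = if (!is.null(mut)) mut$peaks),
       activation = activation, predictions = predictions,
       classification = classification, report = report)
}
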