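#' Describe a (circular) chromosome
#'
#' Lightweight container for the replicon under study. Coordinates are
#' 0-based and half-open throughout the package; GFF3 output is converted at
#' the boundary.
#'
#' @param name Chromosome name used in all genomic output.
#' @param length Chromosome length in base pairs.
#' @param circular Is the replicon circular? Haloarchaeal chromosomes are.
#' @param sequence Optional nucleotide sequence (character scalar over
#'   A/C/G/T) of exactly `length` bases.
#' @return An object of class `chromosome`.
#' @examples
#' chromosome("chr", 2900000)
#' @export
chromosome <- function(name, length, circular = TRUE, sequence = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0)
    stop("chromosome length must be a positive number of base pairs")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match declared chromosome length (", length, ")")
    if (grepl("[^ACGT]", sequence))
      stop("sequence contains characters outside the A/C/G/T alphabet")
  }
  structure(list(name = name, length = length, circular = isTRUE(circular),
                 sequence = sequence),
            class = "chromosome")
}

#' Define a set of replication origins
#'
#' Each origin has a chromosomal position and a firing efficiency: the
#' probability that it initiates replication in a given replication round of
#' a single cell. An efficiency of 0 encodes a strictly dormant origin that
#' is only ever replicated passively by forks from other origins.
#'
#' @param id Character vector of origin identifiers (unique).
#' @param position Numeric vector of origin positions (bp, 0-based).
#' @param efficiency Numeric vector of per-round firing probabilities in
#'   \[0, 1\].
#' @return A `data.frame` of class `origin_set` with columns `id`,
#'   `position`, `efficiency`.
#' @examples
#' origin_set(c("oriC1", "oriC2"), c(3e5, 1.3e6), c(0.9, 0.5))
#' @export
origin_set <- function(id, position, efficiency) {
  if (anyDuplicated(id)) stop("duplicate origin ids")
  if (length(id) != length(position) || length(id) != length(efficiency))
    stop("id, position and efficiency must have equal length")
  position <- as.numeric(position)
  efficiency <- as.numeric(efficiency)
  if (any(!is.finite(position)) || any(position < 0))
    stop("origin positions must be non-negative finite numbers")
  if (any(!is.finite(efficiency)) || any(efficiency < 0 | efficiency > 1))
    stop("origin efficiencies must lie in [0, 1]")
  structure(data.frame(id = as.character(id), position = position,
                       efficiency = efficiency, stringsAsFactors = FALSE),
            class = c("origin_set", "data.frame"))
}

#' Replication kinetics of the cell population
#'
#' Parameters of the asynchronous-population replication model: constant
#' bidirectional fork speed, culture doubling time, and the fraction of
#' cells that are actively replicating (cycling). The replication (C) period
#' implied by any reachable firing configuration must fit within one
#' doubling time; this is validated when marker frequencies are computed.
#'
#' @param fork_speed Replication fork speed in bp per minute.
#' @param doubling_time Culture doubling time in minutes.
#' @param cycling_fraction Fraction of cells in the replicating
#'   subpopulation, in \[0, 1\]. Stationary-phase cultures approach 0.
#' @return An object of class `replication_params`.
#' @examples
#' replication_params(fork_speed = 10000, doubling_time = 180)
#' @export
replication_params <- function(fork_speed, doubling_time,
                               cycling_fraction = 0.5) {
  fork_speed <- as.numeric(fork_speed)
  doubling_time <- as.numeric(doubling_time)
  cycling_fraction <- as.numeric(cycling_fraction)
  if (!is.finite(fork_speed) || fork_speed <= 0)
    stop("fork_speed must be > 0 (bp/min)")
  if (!is.finite(doubling_time) || doubling_time <= 0)
    stop("doubling_time must be > 0 (min)")
  if (!is.finite(cycling_fraction) || cycling_fraction < 0 ||
      cycling_fraction > 1)
    stop("cycling_fraction must lie in [0, 1]")
  structure(list(fork_speed = fork_speed, doubling_time = doubling_time,
                 cycling_fraction = cycling_fraction),
            class = "replication_params")
}

#' Tiling microarray probe design
#'
#' Evenly spaced probe start positions over the chromosome at a nominal
#' density (the arrays emulated here tile roughly 34 50-mer probes per kb).
#' The realized density is validated to be within 5% of the nominal one.
#'
#' @param chromosome_length Length of the chromosome to tile (bp).
#' @param density Nominal probe density in probes per kb.
#' @param probe_length Probe length in bp (metadata only).
#' @return An object of class `probe_design` with elements `positions`
#'   (strictly increasing 0-based starts), `probe_length` and `density`.
#' @examples
#' design <- probe_design(2.9e6)
#' length(design$positions) / 2.9e6 * 1000  # realized probes per kb
#' @export
probe_design <- function(chromosome_length, density = 34, probe_length = 50) {
  chromosome_length <- as.numeric(chromosome_length)
  if (!is.finite(chromosome_length) || chromosome_length <= 0)
    stop("chromosome_length must be > 0")
  if (density <= 0) stop("density must be > 0 probes/kb")
  spacing <- 1000 / density
  positions <- round(seq(0, chromosome_length - 1, by = spacing))
  positions <- unique(positions)
  realized <- length(positions) / chromosome_length * 1000
  if (abs(realized - density) / density > 0.05)
    stop("realized probe density (", signif(realized, 4),
         "/kb) deviates more than 5% from nominal (", density, "/kb)")
  structure(list(positions = positions, probe_length = probe_length,
                 density = density),
            class = "probe_design")
}

#' Measurement noise model for the two-channel array simulator
#'
#' Each channel intensity is perturbed by multiplicative log-normal noise
#' with the given standard deviation on the natural-log scale.
#'
#' @param channel_log_sd Per-channel log-scale standard deviation (>= 0).
#' @param seed Optional integer seed carried with the model.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(channel_log_sd = 0.07, seed = NULL) {
  channel_log_sd <- as.numeric(channel_log_sd)
  if (!is.finite(channel_log_sd) || channel_log_sd < 0)
    stop("channel_log_sd must be >= 0")
  structure(list(channel_log_sd = channel_log_sd, seed = seed),
            class = "noise_model")
}

# Shortest-arc distance between coordinates on a circular replicon.
circular_distance <- function(a, b, length) {
  d <- abs(a - b) %% length
  pmin(d, length - d)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Reverse complement of a plain character DNA string.
rev_comp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
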