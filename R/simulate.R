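#' Simulate a two-channel marker-frequency microarray experiment
#'
#' Generates per-probe hybridization signals for an exponential-phase sample
#' (channel intensity proportional to locus copy number under the forward
#' model of [expected_marker_frequency()]) against a fully non-replicating
#' stationary-phase reference (copy number 1). Each channel is perturbed by
#' independent multiplicative log-normal noise.
#'
#' @param chromosome A [chromosome()] object.
#' @param origins An [origin_set()].
#' @param params A [replication_params()] object.
#' @param design A [probe_design()] covering the chromosome.
#' @param noise A [noise_model()]; `channel_log_sd = 0` gives the noiseless
#'   limit in which every ratio equals the model marker frequency exactly.
#' @param seed Integer seed; defaults to the seed stored in `noise`.
#' @return A probe ratio table (see [compute_ratios()]) with columns
#'   `probe_pos`, `exp_signal`, `stat_signal`, `ratio`, `retained`.
#' @export
simulate_microarray <- function(chromosome, origins, params, design,
                                noise = noise_model(), seed = noise$seed) {
  stopifnot(inherits(design, "probe_design"), inherits(noise, "noise_model"))
  pos <- design$positions
  if (max(pos) >= chromosome$length || min(pos) < 0)
    stop("probe design does not fit the chromosome")
  mf <- expected_marker_frequency(chromosome, origins, params, pos)
  n <- length(pos)
  sdlog <- noise$channel_log_sd
  sig <- with_seed(seed, {
    list(exp = mf * exp(stats::rnorm(n, 0, sdlog)),
         stat = exp(stats::rnorm(n, 0, sdlog)))
  })
  tab <- compute_ratios(sig$exp, sig$stat, pos)
  attr(tab, "chrom") <- chromosome$name
  attr(tab, "chrom_length") <- chromosome$length
  attr(tab, "circular") <- chromosome$circular
  tab
}

#' Simulate sequencing read starts with depth proportional to copy number
#'
#' Read start positions are drawn independently with density proportional to
#' the marker frequency `MF(x)`, emulating whole-genome sequencing of an
#' asynchronous replicating culture. The marker-frequency density is
#' evaluated on a 500-bp grid (the profile varies on a megabase scale, so
#' this grid is effectively exact) and starts are placed uniformly within
#' grid cells.
#'
#' @inheritParams simulate_microarray
#' @param n_reads Number of reads to draw (> 0).
#' @param read_length Read length in bp; reads are clipped at the
#'   chromosome end rather than wrapped.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open, sorted by start), ready for [write_bed()].
#' @export
simulate_reads <- function(chromosome, origins, params, n_reads,
                           read_length = 100, seed = NULL) {
  n_reads <- as.numeric(n_reads)
  if (!is.finite(n_reads) || n_reads <= 0)
    stop("n_reads must be > 0")
  L <- chromosome$length
  cell <- 500
  edges <- seq(0, L, by = cell)
  if (edges[length(edges)] < L) edges <- c(edges, L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  dens <- expected_marker_frequency(chromosome, origins, params, mids)
  prob <- dens * widths
  starts <- with_seed(seed, {
    i <- sample.int(length(mids), n_reads, replace = TRUE, prob = prob)
    floor(edges[i] + stats::runif(n_reads) * widths[i])
  })
  starts <- sort(pmin(starts, L - 1))
  data.frame(chrom = chromosome$name, start = starts,
             end = pmin(starts + read_length, L),
             stringsAsFactors = FALSE)
}
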