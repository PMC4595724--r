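#' Per-probe exponential/stationary signal ratios
#'
#' Builds the raw marker-frequency substrate: one row per probe with both
#' channel intensities and their ratio (exponential-phase signal divided by
#' stationary-phase signal). All rows start out retained; see
#' [filter_outliers()] for the exclusion step.
#'
#' @param exp_signals Exponential-phase channel intensities.
#' @param stat_signals Stationary-phase channel intensities (> 0).
#' @param positions Probe positions in bp, strictly increasing, aligned with
#'   the two channel vectors.
#' @return A `data.frame` of class `probe_ratio_table` with columns
#'   `probe_pos`, `exp_signal`, `stat_signal`, `ratio` and the provenance
#'   flag `retained`.
#' @examples
#' compute_ratios(c(2, 1), c(1, 1), c(0, 100))
#' @export
compute_ratios <- function(exp_signals, stat_signals, positions) {
  n <- length(positions)
  if (length(exp_signals) != n || length(stat_signals) != n)
    stop("misaligned inputs: exp_signals, stat_signals and positions ",
         "must have equal length")
  if (n == 0) stop("empty probe set")
  bad <- which(stat_signals <= 0)
  if (length(bad))
    stop("non-positive stationary signal at probe ", bad[1],
         " (position ", positions[bad[1]], ")")
  if (any(diff(positions) <= 0))
    stop("probe positions must be strictly increasing")
  structure(data.frame(probe_pos = as.numeric(positions),
                       exp_signal = as.numeric(exp_signals),
                       stat_signal = as.numeric(stat_signals),
                       ratio = as.numeric(exp_signals) /
                         as.numeric(stat_signals),
                       retained = TRUE,
                       stringsAsFactors = FALSE),
            class = c("probe_ratio_table", "data.frame"))
}

#' Exclude outlier probes by the fixed ratio bounds
#'
#' Probes with ratio strictly greater than `upper` or strictly less than
#' `lower` are flagged as excluded; probes exactly at a bound are retained
#' (the rule is a strict inequality). The operation is idempotent: the
#' `retained` flag is recomputed from the ratios, so applying the filter
#' twice gives an identical table.
#'
#' @param table A probe ratio table from [compute_ratios()].
#' @param lower,upper Exclusion bounds on the ratio (defaults 0.5 and 2).
#' @return The table with `retained` set; the excluded fraction is stored in
#'   `attr(, "excluded_fraction")`.
#' @export
filter_outliers <- function(table, lower = 0.5, upper = 2) {
  stopifnot(inherits(table, "probe_ratio_table"))
  excluded <- table$ratio > upper | table$ratio < lower
  table$retained <- !excluded
  attr(table, "excluded_fraction") <- mean(excluded)
  attr(table, "outlier_bounds") <- c(lower = lower, upper = upper)
  table
}

# Internal constructor for profile tracks.
mfa_profile <- function(position, value, chrom = "chr", chrom_length = NA,
                        circular = TRUE, source = "array", smoothed = FALSE,
                        ...) {
  structure(data.frame(position = as.numeric(position),
                       value = as.numeric(value), stringsAsFactors = FALSE),
            chrom = chrom, chrom_length = chrom_length, circular = circular,
            source = source, smoothed = smoothed, ...,
            class = c("mfa_profile", "data.frame"))
}

#' Average retained probe ratios into fixed-size bins
#'
#' Consecutive groups of `bin_size` retained probes are averaged
#' (arithmetic mean of ratios) into one profile point located at the first
#' probe of the group. A final partial group is kept if it holds at least
#' `bin_size / 2` probes and dropped otherwise.
#'
#' @param table A probe ratio table; excluded rows are ignored.
#' @param bin_size Number of probes per bin (default 30).
#' @return An unsmoothed `mfa_profile` (columns `position`, `value`).
#' @export
bin_probes <- function(table, bin_size = 30) {
  stopifnot(inherits(table, "probe_ratio_table"))
  rows <- table[table$retained, , drop = FALSE]
  n <- nrow(rows)
  if (n < bin_size / 2)
    stop("fewer retained probes (", n, ") than half a bin (", bin_size / 2,
         "): profile undefined")
  group <- (seq_len(n) - 1L) %/% bin_size + 1L
  rem <- n %% bin_size
  if (rem > 0 && rem < bin_size / 2) {
    keep <- group <= n %/% bin_size
    rows <- rows[keep, , drop = FALSE]
    group <- group[keep]
  }
  pos <- tapply(rows$probe_pos, group, function(p) p[1])
  val <- tapply(rows$ratio, group, mean)
  mfa_profile(as.numeric(pos), as.numeric(val),
              chrom = attr(table, "chrom") %||% "chr",
              chrom_length = attr(table, "chrom_length") %||% NA,
              circular = attr(table, "circular") %||% TRUE,
              source = "array", smoothed = FALSE, bin_size = bin_size)
}

#' Sliding-window smoothing of a profile
#'
#' Centered moving average with a 1-point slide: each output point is the
#' mean of the `window` profile points centered on it, so the point count is
#' preserved. On circular chromosomes the window wraps around the origin of
#' the coordinate system; in linear mode edge windows shrink symmetrically
#' (the window never pads).
#'
#' @param profile An unsmoothed `mfa_profile` with at least `window` points.
#' @param window Odd window size >= 3 (default 5 points).
#' @param slide Slide in points; only the cardinality-preserving 1-point
#'   slide is supported.
#' @param circular Override the profile's circular flag.
#' @return The smoothed `mfa_profile`.
#' @export
smooth_profile <- function(profile, window = 5, slide = 1,
                           circular = attr(profile, "circular")) {
  stopifnot(inherits(profile, "mfa_profile"))
  if (slide != 1) stop("only a 1-point slide is supported")
  if (window %% 2 == 0 || window < 3)
    stop("window must be an odd number >= 3")
  if (isTRUE(attr(profile, "smoothed")))
    stop("profile is already smoothed")
  v <- profile$value
  n <- length(v)
  if (n < window) stop("profile has fewer points than the window")
  h <- (window - 1) / 2
  if (isTRUE(circular)) {
    padded <- c(v[(n - h + 1):n], v, v[1:h])
    out <- as.numeric(stats::filter(padded, rep(1 / window, window),
                                    sides = 2))[(h + 1):(h + n)]
  } else {
    out <- vapply(seq_len(n), function(i) {
      hi <- min(h, i - 1, n - i)
      mean(v[(i - hi):(i + hi)])
    }, numeric(1))
  }
  res <- profile
  res$value <- out
  attr(res, "smoothed") <- TRUE
  attr(res, "smooth_window") <- window
  attr(res, "circular") <- isTRUE(circular)
  res
}

#' Count read starts in fixed windows along the chromosome
#'
#' Counts of read start positions per non-overlapping window (default
#' 1 kb), each profile point located at the window start. A final short
#' window at the chromosome end is kept with its raw count.
#'
#' @param reads A `data.frame` of reads with columns `start` (0-based) and
#'   optionally `end`, e.g. from [simulate_reads()] or [read_bed()].
#' @param chromosome A [chromosome()] object.
#' @param window Window size in bp (default 1000).
#' @return An unsmoothed `mfa_profile` of window counts.
#' @export
window_read_counts <- function(reads, chromosome, window = 1000) {
  stopifnot(inherits(chromosome, "chromosome"))
  if (!is.data.frame(reads) || is.null(reads$start))
    stop("reads must be a data.frame with a 'start' column")
  L <- chromosome$length
  starts <- as.numeric(reads$start)
  if (length(starts) && (any(!is.finite(starts)) ||
                         any(starts < 0 | starts >= L)))
    stop("read starts must lie within [0, chromosome length)")
  m <- ceiling(L / window)
  counts <- tabulate(starts %/% window + 1L, nbins = m)
  mfa_profile((seq_len(m) - 1L) * window, counts,
              chrom = chromosome$name, chrom_length = L,
              circular = chromosome$circular, source = "sequencing",
              smoothed = FALSE, window_bp = window)
}
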