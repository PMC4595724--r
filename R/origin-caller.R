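#' Call origin peaks on a smoothed MFA profile
#'
#' Detects local maxima on the (circular) profile, scores each by its
#' prominence (height minus the higher of the two flanking valleys, the
#' valley being the minimum value between this peak and the neighbouring
#' one), keeps peaks with prominence at least `min_prominence`, and greedily
#' removes calls closer than `min_separation` to a higher call.
#'
#' Because the replication-profile peak of an origin is a broad cusp
#' (piecewise linear in circular distance on the exponent scale) whose
#' apex is easily displaced by measurement noise, the reported position is
#' by default refined by a broken-stick fit: over a window of three times
#' `min_separation` around the detected apex, the profile is regressed on
#' an intercept, a linear trend and a kink term `|offset - b|`, and the
#' breakpoint `b` with the best fit (and a negative kink, i.e. a peak) is
#' reported. The breakpoint of a cusp is invariant under the symmetric
#' smoothing applied upstream, so the estimate is unbiased where a
#' centroid or parabola vertex is pulled toward the shallower flank of an
#' asymmetric peak. The reported position is always an observed profile
#' point; set `refine = FALSE` to report the raw detection apex.
#'
#' @param profile A smoothed `mfa_profile`.
#' @param min_prominence Minimum peak prominence; the default is 5 times a
#'   robust estimate of the detection track's amplitude noise (the MAD of
#'   the input's high-pass residual, corrected for the input's
#'   autocorrelation length and the detection window), floored at 0.1% of
#'   the profile range. On a profile scanned without detection smoothing
#'   it is 5 times the MAD of successive-point differences.
#' @param min_separation Minimum distance between calls in bp (default
#'   100 kb); of two calls closer than this, the higher is kept.
#' @param refine Refine peak positions by the broken-stick fit (default
#'   `TRUE`).
#' @param detect_window Extra centered moving-average window (profile
#'   points, odd) applied internally before maxima detection, so that
#'   point-scale noise does not fragment the megabase-scale peaks of a
#'   replication profile. The default spans roughly half of
#'   `min_separation` (capped at a tenth of the profile); profiles too
#'   short for that are
#'   scanned unsmoothed. Detection, prominence and the adaptive threshold
#'   all operate on this track; reported heights are profile values.
#' @return A `data.frame` of class `peak_calls` with columns `position`,
#'   `height`, `prominence`, `relative_efficiency` (`NA` until
#'   [estimate_efficiency()] is applied), sorted by position. Profile
#'   metadata is carried in attributes.
#' @export
call_peaks <- function(profile, min_prominence = NULL,
                       min_separation = 1e5, refine = TRUE,
                       detect_window = NULL) {
  stopifnot(inherits(profile, "mfa_profile"))
  v0 <- profile$value
  pos <- profile$position
  n <- length(v0)
  if (n == 0) stop("empty profile")
  circular <- isTRUE(attr(profile, "circular"))
  L <- attr(profile, "chrom_length")
  if (is.null(L) || is.na(L)) L <- max(pos) + mean(diff(pos))

  if (is.null(detect_window)) {
    spacing <- if (circular) L / n else mean(diff(pos))
    detect_window <- min(round(min_separation / spacing / 2), n %/% 10)
  }
  detect_window <- max(1L, as.integer(detect_window))
  if (detect_window %% 2 == 0) detect_window <- detect_window + 1L
  v <- if (detect_window >= 3) {
    moving_average(v0, detect_window, circular)
  } else v0

  res_mad <- stats::mad(v0 - v)
  if (is.null(min_prominence)) {
    if (detect_window >= 3) {
      # Amplitude noise of the detection track, estimated robustly from
      # the high-pass residual of the input profile. The residual MAD
      # gives the per-point noise scale; dividing the squared residual
      # scale by the squared successive-difference scale (times 2)
      # estimates the input track's autocorrelation length, so the
      # detection track's amplitude noise is residual_mad *
      # sqrt(corr_len / detect_window). A floor of 0.1% of the profile
      # range guards against degenerate noiseless input.
      dv0 <- if (circular) diff(c(v0, v0[1])) else diff(v0)
      diff_mad <- stats::mad(dv0)
      corr_len <- if (diff_mad > 0) max(1, 2 * (res_mad / diff_mad)^2) else 1
      amp_sd <- res_mad * sqrt(corr_len / detect_window)
      min_prominence <- max(5 * amp_sd, 1e-3 * diff(range(v0)))
    } else {
      dv <- if (circular) diff(c(v, v[1])) else diff(v)
      min_prominence <- 5 * stats::mad(dv)
    }
  }

  apex <- local_maxima(v, circular)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0),
                      relative_efficiency = numeric(0))
  if (!length(apex))
    return(structure(empty, class = c("peak_calls", "data.frame"),
                     chrom = attr(profile, "chrom"), chrom_length = L,
                     circular = circular,
                     min_prominence = min_prominence,
                     min_separation = min_separation))

  prom <- peak_prominence(v, apex, circular)
  keep <- prom >= min_prominence
  apex <- apex[keep]; prom <- prom[keep]

  # Greedy separation: keep the higher of any two calls within range.
  if (length(apex) > 1) {
    ord <- order(v[apex], decreasing = TRUE)
    accepted <- integer(0)
    for (i in ord) {
      p <- pos[apex[i]]
      d <- if (circular) circular_distance(pos[apex[accepted]], p, L)
           else abs(pos[apex[accepted]] - p)
      if (!length(accepted) || all(d >= min_separation))
        accepted <- c(accepted, i)
    }
    prom <- prom[sort(accepted)]
    apex <- apex[sort(accepted)]
  }

  out_idx <- apex
  if (refine && length(apex) && n >= 15) {
    # Noise-adaptive refinement bandwidth: on an effectively noiseless
    # profile a narrow window localizes the apex cusp exactly; under
    # noise a wide window (with a quadratic background term) trades a
    # small model-mismatch bias for a much smaller variance.
    spacing2 <- if (circular) L / n else mean(diff(pos))
    noisy <- res_mad > 0.01 * diff(range(v0))
    hw <- if (noisy) round(3 * min_separation / spacing2) else
      max(detect_window, 5L)
    out_idx <- vapply(apex, function(i) {
      refine_peak_position(v0, i, hw = hw, circular = circular,
                           quad = noisy)
    }, integer(1))
  }
  res <- data.frame(position = pos[out_idx], height = v0[out_idx],
                    prominence = prom, relative_efficiency = NA_real_)
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("peak_calls", "data.frame"),
            chrom = attr(profile, "chrom"), chrom_length = L,
            circular = circular, min_prominence = min_prominence,
            min_separation = min_separation)
}

# Centered moving average with circular wrap (odd window).
moving_average <- function(v, window, circular) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  if (circular) {
    padded <- c(v[(n - h + 1):n], v, v[1:h])
    as.numeric(stats::filter(padded, rep(1 / window, window),
                             sides = 2))[(h + 1):(h + n)]
  } else {
    vapply(seq_len(n), function(i) {
      hi <- min(h, i - 1, n - i)
      mean(v[(i - hi):(i + hi)])
    }, numeric(1))
  }
}

# Indices of local maxima, plateau-aware: runs of equal values collapse to
# their middle index; a run is a maximum if higher than both adjacent runs
# (wrapping on circular profiles; on linear profiles edge runs only need to
# beat their single neighbour).
local_maxima <- function(v, circular) {
  r <- rle(v)
  nr <- length(r$values)
  if (nr == 1) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- c(if (circular) r$values[nr] else -Inf, r$values[-nr])
  nxt <- c(r$values[-1], if (circular) r$values[1] else -Inf)
  if (circular && r$values[1] == r$values[nr] && nr > 2) {
    # first and last runs wrap into one run; compare against their true
    # neighbours instead of each other

    prev[1] <- r$values[nr - 1]
    nxt[nr] <- r$values[2]
  }
  is_max <- r$values > prev & r$values > nxt
  idx <- floor((starts + ends) / 2)[is_max]
  sort(idx)
}

# Topographic prominence of each apex: on each side, walk until a point
# higher than the apex is met (wrapping on circular profiles) and record
# the minimum along the way; prominence is the apex height minus the
# higher of the two flanking minima. The global maximum drops to the
# profile minimum on both sides.
peak_prominence <- function(v, apex, circular) {
  n <- length(v)
  vapply(apex, function(a) {
    h <- v[a]
    side_min <- function(step) {
      lo <- h
      i <- a
      for (k in seq_len(n - 1)) {
        i <- i + step
        if (circular) i <- ((i - 1) %% n) + 1
        else if (i < 1 || i > n) return(lo)
        if (v[i] > h) return(lo)
        if (v[i] < lo) lo <- v[i]
      }
      lo # no higher point anywhere: global maximum
    }
    h - max(side_min(-1L), side_min(1L))
  }, numeric(1))
}

# Broken-stick refinement of a peak apex, returning a profile point
# index. The replication-profile peak of an origin is a cusp (piecewise
# linear in circular distance on the exponent scale), so its position is
# estimated by regressing the profile, over a window around the detected
# apex, on an intercept, a linear (optionally quadratic) background and a
# kink term |offset - b|, and taking the breakpoint b with the smallest
# residual sum of squares among peak-shaped fits (negative kink). The
# breakpoint of a cusp is invariant under the symmetric smoothing applied
# upstream, which makes this estimator unbiased where a centroid or a
# parabola vertex is pulled toward the shallower flank of an asymmetric
# peak.
refine_peak_position <- function(v, apex, hw, circular, quad = TRUE) {
  n <- length(v)
  hw <- max(3L, min(as.integer(hw), (n - 1L) %/% 2L))
  grid <- max(2L, round(hw * 0.8))
  idx <- (apex - hw):(apex + hw)
  if (circular) idx <- ((idx - 1L) %% n) + 1L
  else idx <- idx[idx >= 1 & idx <= n]
  w <- v[idx]
  m <- length(w)
  center <- which(idx == ((apex - 1L) %% n) + 1L)[1]
  j <- seq_len(m) - center
  lo <- max(-grid, j[1] + 1L)
  hi <- min(grid, j[m] - 1L)
  if (lo >= hi) return(as.integer(apex))
  best <- 0L
  best_rss <- Inf
  for (b in lo:hi) {
    X <- if (quad) cbind(1, j, j^2, abs(j - b)) else cbind(1, j, abs(j - b))
    fit <- stats::lm.fit(X, w)
    if (fit$coefficients[ncol(X)] >= 0) next  # a valley fit, not a peak
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- b }
  }
  out <- apex + best
  as.integer(if (circular) ((out - 1L) %% n) + 1L else
    max(1L, min(n, out)))
}

#' Estimate relative origin firing efficiencies from peak heights
#'
#' The relative efficiency of each called origin peak is its height above
#' the profile baseline (the global profile minimum), normalized so the
#' efficiencies sum to 1 across peaks.
#'
#' @param peaks A `peak_calls` table from [call_peaks()] with at least one
#'   peak.
#' @param profile The profile the peaks were called on.
#' @return The peaks table with `relative_efficiency` filled in.
#' @export
estimate_efficiency <- function(peaks, profile) {
  stopifnot(inherits(peaks, "peak_calls"), inherits(profile, "mfa_profile"))
  if (!nrow(peaks)) stop("no peaks to estimate efficiencies for")
  baseline <- min(profile$value)
  excess <- peaks$height - baseline
  if (sum(excess) <= 0)
    stop("all peaks are at the profile baseline")
  peaks$relative_efficiency <- excess / sum(excess)
  peaks
}

#' Compare parent and mutant peak sets to call origin activation and loss
#'
#' Labels each known origin by matching it against peaks called in a parent
#' and a mutant profile of the same chromosome: `active` (peak in both),
#' `lost` (parent only), `activated` (mutant only, the dormant-origin
#' activation signature), or `unchanged-absent` (neither). Mutant peaks not
#' matching any known origin are reported as novel-peak calls in
#' `attr(, "novel_peaks")` together with their nearest known origin.
#'
#' @param parent,mutant `peak_calls` tables for the two strains.
#' @param known_origins A `data.frame` with columns `id` and `position`
#'   (e.g. an [origin_set()]); ids must be unique.
#' @param match_tolerance Maximum origin-to-peak distance in bp for a match
#'   (default 20 kb, roughly the positional blur of binning plus
#'   smoothing).
#' @return A `data.frame` of class `activation_calls` with columns `id`,
#'   `position`, `status`, `parent_peak`, `mutant_peak` (matched peak
#'   positions or `NA`).
#' @export
compare_profiles <- function(parent, mutant, known_origins,
                             match_tolerance = 2e4) {
  if (anyDuplicated(known_origins$id)) stop("duplicate origin ids")
  L <- attr(parent, "chrom_length") %||% attr(mutant, "chrom_length")
  circular <- isTRUE(attr(parent, "circular") %||%
                     attr(mutant, "circular") %||% TRUE)
  nearest <- function(peaks, p) {
    if (!nrow(peaks)) return(NA_real_)
    d <- if (circular) circular_distance(peaks$position, p, L)
         else abs(peaks$position - p)
    if (min(d) <= match_tolerance) peaks$position[which.min(d)] else NA_real_
  }
  parent_peak <- vapply(known_origins$position, nearest,
                        numeric(1), peaks = parent)
  mutant_peak <- vapply(known_origins$position, nearest,
                        numeric(1), peaks = mutant)
  status <- ifelse(!is.na(parent_peak) & !is.na(mutant_peak), "active",
            ifelse(!is.na(parent_peak), "lost",
            ifelse(!is.na(mutant_peak), "activated", "unchanged-absent")))
  novel <- mutant[vapply(mutant$position, function(p) {
    d <- if (circular) circular_distance(known_origins$position, p, L)
         else abs(known_origins$position - p)
    all(d > match_tolerance)
  }, logical(1)), , drop = FALSE]
  novel_info <- if (nrow(novel)) {
    nearest_id <- vapply(novel$position, function(p) {
      d <- if (circular) circular_distance(known_origins$position, p, L)
           else abs(known_origins$position - p)
      known_origins$id[which.min(d)]
    }, character(1))
    data.frame(position = novel$position, height = novel$height,
               nearest_origin = nearest_id, stringsAsFactors = FALSE)
  } else {
    data.frame(position = numeric(0), height = numeric(0),
               nearest_origin = character(0), stringsAsFactors = FALSE)
  }
  structure(data.frame(id = known_origins$id,
                       position = known_origins$position,
                       status = status, parent_peak = parent_peak,
                       mutant_peak = mutant_peak, stringsAsFactors = FALSE),
            class = c("activation_calls", "data.frame"),
            novel_peaks = novel_info, match_tolerance = match_tolerance)
}

#' Classify sequence-predicted origins as active or dormant
#'
#' A predicted origin with a called replication peak within
#' `match_tolerance` is labelled `active`; otherwise it is `dormant` (the
#' ORB architecture is present but no initiation is detected in the
#' profile).
#'
#' @param predictions An origin prediction set from [predict_origins()], or
#'   a `data.frame` with columns `gene_id` and `position`.
#' @param peaks A `peak_calls` table from the same chromosome.
#' @param match_tolerance Maximum distance in bp for a peak match.
#' @return A `data.frame` with columns `gene_id`, `position`, `status`.
#' @export
classify_predicted_origins <- function(predictions, peaks,
                                       match_tolerance = 2e4) {
  tab <- if (inherits(predictions, "origin_prediction_set")) {
    data.frame(gene_id = vapply(predictions$predictions, `[[`, character(1),
                                "gene_id"),
               position = vapply(predictions$predictions, `[[`, numeric(1),
                                 "position"), stringsAsFactors = FALSE)
  } else predictions
  L <- attr(peaks, "chrom_length")
  circular <- isTRUE(attr(peaks, "circular") %||% TRUE)
  status <- vapply(tab$position, function(p) {
    if (!nrow(peaks)) return("dormant")
    d <- if (circular && !is.null(L) && !is.na(L))
      circular_distance(peaks$position, p, L) else abs(peaks$position - p)
    if (any(d <= match_tolerance)) "active" else "dormant"
  }, character(1))
  data.frame(gene_id = tab$gene_id, position = tab$position,
             status = status, stringsAsFactors = FALSE)
}
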