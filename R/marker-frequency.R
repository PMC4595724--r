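#' Expected marker frequency under the multi-origin population model
#'
#' Computes the expected relative copy number (marker frequency, MF) of loci
#' on a circular chromosome in an asynchronous culture replicating from
#' several origins of unequal firing efficiency.
#'
#' The model: in each replicating cell a subset `S` of origins fires, each
#' origin independently with its efficiency; cells in which no origin fires
#' are not viable replication states, so the subset distribution is
#' renormalized over non-empty subsets. Given `S`, the locus at `x` is
#' replicated at time `t_S(x) = min_{i in S} d(x, o_i) / v`, the shortest
#' circular distance to a fired origin divided by the fork speed. For an
#' exponentially growing asynchronous population the cell-age density is
#' `(2 log 2 / T) 2^(-a/T)` on `[0, T]`, which gives an expected copy number
#' of `2^(1 - t_S(x)/T)` for that subset. Mixing replicating cells (fraction
#' `f`) with non-replicating cells (copy number 1) yields
#' `MF(x) = f * E_S[2^(1 - t_S(x)/T)] + (1 - f)`, which lies in
#' `[1, 1 + f]`.
#'
#' The expectation is evaluated by exact enumeration over the (at most
#' `2^k - 1`) non-empty origin subsets; at most 12 origins are supported.
#' The replication period implied by every reachable subset (half the
#' largest inter-origin gap of the subset, divided by the fork speed) must
#' not exceed the doubling time, otherwise an error is raised: multi-round
#' replication is outside the model.
#'
#' @param chromosome A [chromosome()] object.
#' @param origins An [origin_set()]; at least one efficiency must be > 0.
#' @param params A [replication_params()] object.
#' @param positions Numeric vector of query positions in `[0, length)`.
#' @return Numeric vector of marker frequencies, one per query position.
#' @examples
#' chr <- chromosome("chr", 2e6)
#' ori <- origin_set("oriC1", 0, 1)
#' par <- replication_params(fork_speed = 1e4, doubling_time = 100)
#' expected_marker_frequency(chr, ori, par, 0)  # 2 at the origin when f = 1
#' @export
expected_marker_frequency <- function(chromosome, origins, params, positions) {
  stopifnot(inherits(chromosome, "chromosome"),
            inherits(params, "replication_params"))
  L <- chromosome$length
  positions <- as.numeric(positions)
  if (any(!is.finite(positions)) || any(positions < 0 | positions >= L))
    stop("positions must lie in [0, chromosome length)")
  e <- origins$efficiency
  o <- origins$position
  if (any(o >= L)) stop("origin positions must lie in [0, chromosome length)")
  k <- length(e)
  if (k > 12) stop("at most 12 origins are supported for subset enumeration")
  if (all(e == 0))
    stop("all origin efficiencies are 0: no replication is possible")

  subsets <- enumerate_firing_subsets(e)
  v <- params$fork_speed
  Td <- params$doubling_time
  f <- params$cycling_fraction

  # C-period validation: every reachable subset must complete within T.
  for (s in seq_along(subsets$weight)) {
    members <- subsets$members[[s]]
    tmax <- max_replication_time(o[members], L, chromosome$circular) / v
    if (tmax > Td * (1 + 1e-9))
      stop("replication period of firing configuration {",
           paste(origins$id[members], collapse = ","),
           "} (", signif(tmax, 4), " min) exceeds the doubling time (",
           Td, " min): the single-round population model does not apply")
  }

  d <- if (chromosome$circular) {
    vapply(o, function(oi) circular_distance(positions, oi, L),
           numeric(length(positions)))
  } else {
    vapply(o, function(oi) abs(positions - oi), numeric(length(positions)))
  }
  d <- matrix(d, nrow = length(positions), ncol = k)

  mrep <- numeric(length(positions))
  for (s in seq_along(subsets$weight)) {
    members <- subsets$members[[s]]
    tS <- do.call(pmin, as.data.frame(d[, members, drop = FALSE])) / v
    mrep <- mrep + subsets$weight[s] * 2^(1 - tS / Td)
  }
  f * mrep + (1 - f)
}

# Non-empty firing subsets with positive probability, renormalized.
enumerate_firing_subsets <- function(efficiency) {
  k <- length(efficiency)
  members <- list()
  weight <- numeric(0)
  for (mask in seq_len(2^k - 1L)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L
    w <- prod(efficiency[sel]) * prod(1 - efficiency[!sel])
    if (w > 0) {
      members[[length(members) + 1L]] <- which(sel)
      weight <- c(weight, w)
    }
  }
  list(members = members, weight = weight / sum(weight))
}

# Largest distance from any locus to its nearest origin in `pos`.
# On a circle this is half the largest gap between consecutive origins.
max_replication_time <- function(pos, length, circular) {
  pos <- sort(pos)
  if (!circular) return(max(pos[1], length - 1 - pos[length(pos)],
                            if (length(pos) > 1) max(diff(pos)) / 2 else 0))
  gaps <- if (length(pos) == 1) length else
    c(diff(pos), length - pos[length(pos)] + pos[1])
  max(gaps) / 2
}
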