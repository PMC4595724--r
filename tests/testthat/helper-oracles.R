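# Independent oracles used to cross-check the implementation. Each is a
# deliberately different route to the same quantity: plain Monte-Carlo
# sampling for the marker-frequency expectation, literal all-pairs
# substring comparison for the repeat search, and a from-scratch affine-gap
# dynamic program for protein identity.

# Monte-Carlo marker frequency: sample firing subsets cell by cell
# (resampling cells in which no origin fired), average the exponential-age
# copy number. Returns estimate and standard error per position.
mc_marker_frequency <- function(chromosome, origins, params, positions,
                                nsim = 2e5, seed = 1) {
  e <- origins$efficiency
  k <- length(e)
  L <- chromosome$length
  v <- params$fork_speed
  Td <- params$doubling_time
  f <- params$cycling_fraction
  set.seed(seed)
  draw <- function(m) matrix(stats::runif(m * k), m, k) <=
    matrix(e, m, k, byrow = TRUE)
  fired <- draw(nsim)
  empty <- which(rowSums(fired) == 0)
  while (length(empty)) {
    fired[empty, ] <- draw(length(empty))
    empty <- empty[rowSums(fired[empty, , drop = FALSE]) == 0]
  }
  t(vapply(positions, function(x) {
    d <- pmin(abs(x - origins$position), L - abs(x - origins$position))
    Tm <- matrix(d / v, nsim, k, byrow = TRUE)
    Tm[!fired] <- Inf
    tS <- do.call(pmin, as.data.frame(Tm))
    M <- 2^(1 - tS / Td)
    c(mf = f * mean(M) + (1 - f), se = f * stats::sd(M) / sqrt(nsim))
  }, c(mf = 0, se = 0)))
}

# Brute-force repeat search: every pair of length-`len` substrings, on the
# same strand and across strands, compared position by position. Returns a
# data.frame of qualifying pairs (0-based starts; for cross-strand pairs
# `start2` is the genomic start of the minus-strand instance).
bf_repeat_pairs <- function(sequence, len, max_mismatch) {
  x <- utf8ToInt(sequence)
  n <- length(x)
  if (n < 2 * len)
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      cross = logical(0)))
  y <- utf8ToInt(paste(rev(strsplit(chartr("ACGT", "TGCA", sequence),
                                    "", fixed = TRUE)[[1]]), collapse = ""))
  ns <- n - len + 1L
  X <- matrix(x[outer(seq_len(ns) - 1L, seq_len(len), `+`)], ns, len)
  Y <- matrix(y[outer(seq_len(ns) - 1L, seq_len(len), `+`)], ns, len)
  out <- list()
  for (i in seq_len(ns - 1L)) {
    mm <- rowSums(X[(i + 1):ns, , drop = FALSE] !=
                    matrix(X[i, ], ns - i, len, byrow = TRUE))
    hit <- which(mm <= max_mismatch)
    for (j in hit)
      out[[length(out) + 1L]] <- c(i - 1L, i + j - 1L, 0L)
  }
  for (i in seq_len(ns)) {
    mm <- rowSums(Y != matrix(X[i, ], ns, len, byrow = TRUE))
    for (j in which(mm <= max_mismatch)) {
      g2 <- n - (j - 1L) - len       # genomic start of minus instance
      if (i - 1L == g2) next         # self-palindrome
      a <- min(i - 1L, g2); b <- max(i - 1L, g2)
      out[[length(out) + 1L]] <- c(a, b, 1L)
    }
  }
  if (!length(out))
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      cross = logical(0)))
  m <- unique(do.call(rbind, out))
  data.frame(start1 = m[, 1], start2 = m[, 2], cross = m[, 3] == 1L)
}

# From-scratch global affine-gap alignment (gap of length g costs
# open + g * extend) under BLOSUM62, with traceback. Returns the optimal
# score and the percent identity over alignment columns.
nw_align_oracle <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in b (a residue over a gap)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- S[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + sc
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback for the aligned strings
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1],
                       Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  pa <- character(0); pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      sc <- S[av[i - 1], bv[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state_next <- which.max(prev)
      pa <- c(av[i - 1], pa); pb <- c(bv[j - 1], pb)
      i <- i - 1; j <- j - 1
      state <- state_next
    } else if (state == 2) {
      pa <- c(av[i - 1], pa); pb <- c("-", pb)
      from_m <- M[i - 1, j] - open - extend
      from_x <- Ix[i - 1, j] - extend
      state <- if (from_m >= from_x) 1 else 2
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(bv[j - 1], pb)
      from_m <- M[i, j - 1] - open - extend
      from_y <- Iy[i, j - 1] - extend
      state <- if (from_m >= from_y) 1 else 3
      j <- j - 1
    }
  }
  list(score = score, identity = 100 * sum(pa == pb) / length(pa))
}

# Random protein helpers: related pairs built by mutating a common
# ancestor (substitutions plus a short indel) so the optimal alignment is
# essentially unique.
aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(aa_alphabet, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(protein, n_sub, indel_len, seed) {
  set.seed(seed)
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  at <- sample(seq_along(v), n_sub)
  v[at] <- vapply(v[at], function(r)
    sample(setdiff(aa_alphabet, r), 1), character(1))
  if (indel_len > 0) {
    cut <- sample(seq_len(length(v) - indel_len - 2), 1) + 1
    v <- v[-(cut:(cut + indel_len - 1))]
  }
  paste(v, collapse = "")
}
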