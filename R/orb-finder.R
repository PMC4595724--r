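#' Extract the intergenic region immediately upstream of a gene
#'
#' Returns the gap between the gene's upstream boundary (strand-aware: the
#' translational start side) and the nearest neighbouring gene, truncated to
#' `max_span` bp adjacent to the gene.
#'
#' @param annotation A `GRanges` of features; rows with
#'   `mcols(annotation)$type == "gene"` are considered genes.
#' @param gene_id Identifier matched against `mcols(annotation)$ID`.
#' @param max_span Maximum region span in bp (default 2000).
#' @return A list of class `intergenic_region` with elements `chrom`,
#'   `start`, `end` (0-based half-open), `gene_id`, `strand`.
#' @export
extract_upstream_intergenic <- function(annotation, gene_id,
                                        max_span = 2000) {
  type <- S4Vectors::mcols(annotation)$type
  genes <- annotation[!is.na(type) & type == "gene"]
  ids <- S4Vectors::mcols(genes)$ID
  hit <- which(ids == gene_id)
  if (!length(hit)) stop("gene '", gene_id, "' not found in annotation")
  g <- genes[hit[1]]
  strand <- as.character(BiocGenerics::strand(g))
  others <- genes[-hit[1]]
  # 0-based half-open coordinates
  gstart <- BiocGenerics::start(g) - 1
  gend <- BiocGenerics::end(g)
  if (strand == "-") {
    nxt <- BiocGenerics::start(others) - 1
    nxt <- nxt[nxt >= gend]
    region_start <- gend
    region_end <- if (length(nxt)) min(nxt) else
      suppressWarnings(as.numeric(
        GenomeInfoDb::seqlengths(annotation)[
          as.character(GenomeInfoDb::seqnames(g))])) %||% NA
    if (is.na(region_end)) region_end <- gend + max_span
    region_end <- min(region_end, gend + max_span)
  } else {
    prev <- BiocGenerics::end(others)
    prev <- prev[prev <= gstart]
    region_end <- gstart
    region_start <- if (length(prev)) max(prev) else 0
    region_start <- max(region_start, gstart - max_span, 0)
  }
  if (region_end <= region_start)
    stop("no intergenic region upstream of gene '", gene_id, "'")
  structure(list(chrom = as.character(GenomeInfoDb::seqnames(g)),
                 start = region_start, end = region_end,
                 gene_id = gene_id, strand = strand),
            class = "intergenic_region")
}

#' Find repeated motifs in a sequence, allowing mismatches
#'
#' Exhaustive mismatch-tolerant repeat search: reports maximal pairs of
#' substrings with length in `[min_len, max_len]` that occur at least twice
#' in the region, on either strand (a reverse-complement match counts as a
#' minus-strand instance), with at most `max_mismatch` mismatches between
#' the two copies. The search scans every alignment offset of the sequence
#' against itself and against its reverse complement, extending each
#' candidate window maximally under the mismatch budget; heavily
#' overlapping windows on the same offset are collapsed to the best
#' (longest, then fewest mismatches), and a pair sharing one instance with
#' an already-accepted motif contributes its other instance to that motif
#' instead of founding a new one.
#'
#' The motif consensus is the majority base per column over the aligned
#' instances, ties resolved in favour of the first instance.
#'
#' @param sequence Region sequence (character scalar over A/C/G/T, or a
#'   `DNAString`); degenerate characters are an error.
#' @param min_len,max_len Motif length bounds in bp (defaults 18 and 35).
#' @param max_mismatch Maximum mismatches allowed between two instances of
#'   a motif (default 3).
#' @return A list of motifs; each motif is a list with elements
#'   `consensus`, `length`, `instances` (a `data.frame` with columns
#'   `start`, `end` (0-based half-open within the region), `strand`,
#'   `mismatches`). The list has class `orb_motif_list`.
#' @export
find_repeated_motifs <- function(sequence, min_len = 18, max_len = 35,
                                 max_mismatch = 3) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains degenerate or non-nucleotide characters")
  n <- nchar(sequence)
  if (n < 2 * min_len)
    stop("region shorter than twice the minimum motif length")
  x <- utf8ToInt(sequence)
  y <- utf8ToInt(rev_comp(sequence))

  pairs <- list()
  push <- function(s1, s2, strand2, len, mism) {
    pairs[[length(pairs) + 1L]] <<- c(s1, s2, strand2, len, mism)
  }

  # same-strand pairs: offsets delta >= 1
  for (delta in seq_len(n - min_len)) {
    cmp <- x[seq_len(n - delta)] != x[(1 + delta):n]
    for (w in scan_windows(cmp, min_len, max_len, max_mismatch)) {
      push(w[1] - 1, w[1] - 1 + delta, 0L, w[2], w[3])
    }
  }
  # cross-strand pairs: all alignments of x against revcomp(x)
  for (delta in (-(n - min_len)):(n - min_len)) {
    if (delta >= 0) {
      cmp <- x[seq_len(n - delta)] != y[(1 + delta):n]
      xoff <- -1; yoff <- delta - 1
    } else {
      cmp <- x[(1 - delta):n] != y[seq_len(n + delta)]
      xoff <- -delta - 1; yoff <- -1
    }
    for (w in scan_windows(cmp, min_len, max_len, max_mismatch)) {
      i <- w[1] + xoff          # 0-based x start
      j <- w[1] + yoff          # 0-based start in revcomp coordinates
      len <- w[2]
      g2 <- n - j - len         # genomic start of the minus-strand instance
      if (i == g2) next         # a window matching its own reverse
                                # complement (palindrome) is not a pair
      # an inverted pair reads identically from either strand; canonical
      # form is plus on the left instance, minus on the right
      push(min(i, g2), max(i, g2), 1L, len, w[3])
    }
  }
  if (!length(pairs)) return(structure(list(), class = "orb_motif_list"))

  pm <- do.call(rbind, pairs)
  colnames(pm) <- c("s1", "s2", "strand2", "len", "mism")
  # strand2: 0 = both "+"; 1 = plus left instance, minus right instance
  pm <- pm[!duplicated(pm[, c("s1", "s2", "strand2"), drop = FALSE]), ,
           drop = FALSE]
  ord <- order(-pm[, "len"], pm[, "mism"], pm[, "s1"])
  pm <- pm[ord, , drop = FALSE]

  motifs <- list()
  inst_key <- function(m) paste(m$instances$start, m$instances$end,
                                m$instances$strand)
  overlap_frac <- function(a1, a2, b1, b2) {
    ov <- max(0, min(a2, b2) - max(a1, b1))
    ov / min(a2 - a1, b2 - b1)
  }
  for (r in seq_len(nrow(pm))) {
    s1 <- pm[r, "s1"]; s2 <- pm[r, "s2"]; len <- pm[r, "len"]
    st <- pm[r, "strand2"]
    strands <- if (st == 0) c("+", "+") else c("+", "-")
    inst <- data.frame(start = c(s1, s2), end = c(s1 + len, s2 + len),
                       strand = strands, mismatches = c(0, pm[r, "mism"]),
                       stringsAsFactors = FALSE)
    matched <- 0L
    host <- 0L
    for (m in seq_along(motifs)) {
      mi <- motifs[[m]]$instances
      hits <- vapply(seq_len(nrow(inst)), function(a) {
        any(vapply(seq_len(nrow(mi)), function(b) {
          mi$strand[b] == inst$strand[a] &&
            overlap_frac(mi$start[b], mi$end[b],
                         inst$start[a], inst$end[a]) >= 0.5
        }, logical(1)))
      }, logical(1))
      if (sum(hits) > matched) { matched <- sum(hits); host <- m }
      if (matched == 2L) break
    }
    if (matched == 2L) next            # redundant with an accepted motif
    if (matched == 1L) {               # extra instance of a known motif
      mi <- motifs[[host]]$instances
      new <- inst[!vapply(seq_len(nrow(inst)), function(a) {
        any(vapply(seq_len(nrow(mi)), function(b) {
          mi$strand[b] == inst$strand[a] &&
            overlap_frac(mi$start[b], mi$end[b],
                         inst$start[a], inst$end[a]) >= 0.5
        }, logical(1)))
      }, logical(1)), , drop = FALSE]
      motifs[[host]]$instances <- rbind(mi, new)
      next
    }
    motifs[[length(motifs) + 1L]] <- list(instances = inst, length = len)
  }

  # consensus per motif: majority base per column, ties to instance 1
  for (m in seq_along(motifs)) {
    inst <- motifs[[m]]$instances
    len <- motifs[[m]]$length
    mat <- vapply(seq_len(nrow(inst)), function(a) {
      s <- substr(sequence, inst$start[a] + 1, inst$start[a] + len)
      if (inst$strand[a] == "-") s <- rev_comp(s)
      strsplit(s, "", fixed = TRUE)[[1]]
    }, character(len))
    mat <- matrix(mat, nrow = len)
    cons <- apply(mat, 1, function(col) {
      tb <- table(factor(col, levels = unique(col)))
      names(tb)[which.max(tb)]
    })
    motifs[[m]]$consensus <- paste(cons, collapse = "")
    motifs[[m]]$instances$mismatches <- vapply(seq_len(nrow(inst)),
      function(a) sum(mat[, a] != cons), numeric(1))
  }
  structure(motifs, class = "orb_motif_list")
}

# Maximal windows with at most k mismatches in a binary mismatch vector.
# Returns a list of c(start, len, mismatches) in 1-based alignment
# coordinates; heavily overlapping windows are collapsed to the best
# (longest, then fewest mismatches, then leftmost).
scan_windows <- function(cmp, min_len, max_len, k) {
  m <- length(cmp)
  if (m < min_len) return(list())
  C <- c(0, cumsum(cmp))
  mpos <- which(cmp)
  a <- seq_len(m - min_len + 1L)
  idx <- C[a] + k + 1L
  lim <- ifelse(idx > length(mpos), m, mpos[pmin(idx, length(mpos))] - 1L)
  if (!length(mpos)) lim <- rep(m, length(a))
  reach <- pmin(lim, a + max_len - 1L, m)
  len <- reach - a + 1L
  ok <- len >= min_len
  if (!any(ok)) return(list())
  leftmax <- c(TRUE, reach[-1] > reach[-length(reach)])
  sel <- which(ok & leftmax)
  if (!length(sel)) return(list())
  starts <- a[sel]
  ends <- reach[sel]
  mism <- C[ends + 1L] - C[starts]
  # cluster overlapping windows, keep the best per cluster
  out <- list()
  cl_start <- 1L
  for (i in seq_along(starts)) {
    last <- i == length(starts)
    if (!last && starts[i + 1L] <= ends[i]) next_in <- TRUE else
      next_in <- FALSE
    if (!next_in) {
      j <- cl_start:i
      best <- j[order(-(ends[j] - starts[j]), mism[j], starts[j])][1]
      out[[length(out) + 1L]] <- c(starts[best],
                                   ends[best] - starts[best] + 1L,
                                   mism[best])
      cl_start <- i + 1L
    }
  }
  out
}

#' Does a motif consensus carry a G-string?
#'
#' ORB elements are distinguished from other repeated motifs by a G-rich
#' run (the "G-string"). A consensus qualifies if it, or its reverse
#' complement, contains a run of at least `g_run` consecutive G.
#'
#' @param consensus Non-empty nucleotide string.
#' @param g_run Minimum run length (default 4).
#' @return `TRUE` or `FALSE`.
#' @examples
#' has_g_string("ACGGGGTACGTACGTACG")       # G run on the plus strand
#' has_g_string("ATCCCCTACGTACGTACGT")      # G run on the minus strand
#' @export
has_g_string <- function(consensus, g_run = 4) {
  if (!nchar(consensus)) stop("empty consensus")
  grepl(strrep("G", g_run), consensus, fixed = TRUE) ||
    grepl(strrep("C", g_run), consensus, fixed = TRUE)
}

#' Predict cdc6-associated replication origins from sequence
#'
#' For each cdc6 gene: extract the upstream intergenic region, search it
#' for repeated motifs, keep motifs whose consensus carries a G-string, and
#' keep those with at least one instance on each strand (an inverted ORB
#' pair). Each qualifying gene yields one origin prediction anchored at the
#' midpoint of the span covered by the inverted pair; genes failing any
#' step are reported with the failing step named.
#'
#' @param chromosome A [chromosome()] carrying a sequence.
#' @param annotation Gene annotation (`GRanges`) consistent with the
#'   sequence.
#' @param cdc6_ids Character vector of cdc6 gene ids to assess.
#' @param max_span Upstream intergenic truncation (bp).
#' @param min_len,max_len,max_mismatch Motif search parameters, see
#'   [find_repeated_motifs()].
#' @param g_run Minimum G-run for the G-string rule.
#' @return A list of class `origin_prediction_set` with elements
#'   `predictions` (list of per-gene predictions: `gene_id`, `region`,
#'   `motif` with instances in genomic coordinates, `inverted_pair`
#'   instance indices, `position`) and `failures` (a `data.frame` with
#'   columns `gene_id`, `step`).
#' @export
predict_origins <- function(chromosome, annotation, cdc6_ids,
                            max_span = 2000, min_len = 18, max_len = 35,
                            max_mismatch = 3, g_run = 4) {
  if (is.null(chromosome$sequence))
    stop("chromosome carries no sequence")
  predictions <- list()
  failures <- data.frame(gene_id = character(0), step = character(0),
                         stringsAsFactors = FALSE)
  fail <- function(id, step) {
    failures[nrow(failures) + 1L, ] <<- list(id, step)
  }
  for (id in cdc6_ids) {
    region <- tryCatch(
      extract_upstream_intergenic(annotation, id, max_span),
      error = function(e) conditionMessage(e))
    if (is.character(region)) { fail(id, "no intergenic region"); next }
    if (region$end - region$start < 2 * min_len) {
      fail(id, "intergenic region too short"); next
    }
    seq <- substr(chromosome$sequence, region$start + 1, region$end)
    motifs <- find_repeated_motifs(seq, min_len, max_len, max_mismatch)
    if (!length(motifs)) { fail(id, "no repeated motif"); next }
    motifs <- Filter(function(m) has_g_string(m$consensus, g_run), motifs)
    if (!length(motifs)) { fail(id, "no G-string"); next }
    inv <- Filter(function(m) length(unique(m$instances$strand)) == 2,
                  motifs)
    if (!length(inv)) { fail(id, "no inverted pair"); next }
    best <- inv[[order(-vapply(inv, `[[`, numeric(1), "length"))[1]]]
    ip <- c(which(best$instances$strand == "+")[1],
            which(best$instances$strand == "-")[1])
    best$instances$start <- best$instances$start + region$start
    best$instances$end <- best$instances$end + region$start
    span <- c(min(best$instances$start[ip]), max(best$instances$end[ip]))
    predictions[[length(predictions) + 1L]] <- list(
      gene_id = id, region = region, motif = best, inverted_pair = ip,
      position = mean(span))
  }
  structure(list(predictions = predictions, failures = failures),
            class = "origin_prediction_set")
}
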