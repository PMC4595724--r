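#' Generate a synthetic genome with planted cdc6/ORB origin architecture
#'
#' Builds a random background sequence (GC-rich, as typical of haloarchaeal
#' genomes) and, at each requested cdc6 locus, plants (i) a cdc6 gene
#' feature, (ii) a flanking delimiter gene bounding the upstream intergenic
#' region, and (iii) two copies of the ORB consensus in the upstream
#' intergenic region, one on each strand (an inverted ORB pair) separated by
#' `orb_spacing` bp. The returned annotation records genes and planted
#' motifs as ground truth.
#'
#' Upstream intergenic layout on the plus strand (mirrored for minus-strand
#' loci), with `P` the cdc6 gene start:
#' `[delimiter gene][ ORB(-) .. spacing .. ORB(+) .. 60 bp ][cdc6 gene at P)`.
#' The intergenic region spans 300 bp, so `2 * nchar(orb_consensus) +
#' orb_spacing` must leave room for the 60-bp gene-proximal gap.
#'
#' @param length Genome length in bp.
#' @param cdc6_loci A `data.frame` with columns `position` (gene start, bp,
#'   0-based) and `strand` (`"+"` or `"-"`); optionally `id`.
#' @param orb_consensus ORB consensus sequence to plant (length 18-35).
#' @param orb_spacing Distance in bp between the two planted ORB copies.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param gene_length Length of each planted gene feature (bp).
#' @return A list with elements `chromosome` (a [chromosome()] carrying the
#'   sequence) and `annotation` (a `GRanges` of gene and ORB features; ORB
#'   features carry `type = "ORB_repeat"` and their planted strand).
#' @examples
#' g <- generate_genome(50000,
#'                      data.frame(position = 25000, strand = "+"),
#'                      orb_consensus = "TTCACGGGGGTCCAGTGGAAACGAACACGT",
#'                      seed = 1)
#' @export
generate_genome <- function(length, cdc6_loci, orb_consensus,
                            orb_spacing = 30, seed = NULL,
                            gene_length = 1200) {
  length <- as.numeric(length)
  orb_consensus <- toupper(orb_consensus)
  lc <- nchar(orb_consensus)
  if (lc < 18 || lc > 35)
    stop("orb_consensus length must be in [18, 35]")
  if (grepl("[^ACGT]", orb_consensus))
    stop("orb_consensus must be over the A/C/G/T alphabet")
  if (is.null(cdc6_loci$strand)) cdc6_loci$strand <- "+"
  if (is.null(cdc6_loci$id))
    cdc6_loci$id <- paste0("cdc6_", seq_len(nrow(cdc6_loci)))
  intergenic <- 300
  proximal_gap <- 60
  delim_length <- 600
  if (2 * lc + orb_spacing + proximal_gap > intergenic)
    stop("planted ORB pair (2 x ", lc, " bp + ", orb_spacing,
         " bp spacing) does not fit the ", intergenic,
         "-bp intergenic region")

  feats <- list()
  add <- function(id, type, start, end, strand, locus, sequence = NA) {
    feats[[length(feats) + 1L]] <<- data.frame(
      id = id, type = type, start = start, end = end, strand = strand,
      locus = locus, sequence = sequence, stringsAsFactors = FALSE)
  }
  orb_rc <- rev_comp(orb_consensus)
  for (i in seq_len(nrow(cdc6_loci))) {
    P <- cdc6_loci$position[i]
    id <- cdc6_loci$id[i]
    if (cdc6_loci$strand[i] == "+") {
      gene <- c(P, P + gene_length)
      fwd <- c(P - proximal_gap - lc, P - proximal_gap)
      rev_ <- c(fwd[1] - orb_spacing - lc, fwd[1] - orb_spacing)
      delim <- c(P - intergenic - delim_length, P - intergenic)
      delim_strand <- "-"
    } else {
      Pe <- P + gene_length
      gene <- c(P, Pe)
      fwd <- c(Pe + proximal_gap, Pe + proximal_gap + lc)
      rev_ <- c(fwd[2] + orb_spacing, fwd[2] + orb_spacing + lc)
      delim <- c(Pe + intergenic, Pe + intergenic + delim_length)
      delim_strand <- "+"
    }
    if (min(gene, fwd, rev_, delim) < 0 || max(gene, fwd, rev_, delim) > length)
      stop("genome length too small for cdc6 locus '", id,
           "' and its planted elements")
    add(id, "gene", gene[1], gene[2], cdc6_loci$strand[i], id)
    add(paste0(id, "_flank"), "gene", delim[1], delim[2], delim_strand, id)
    add(paste0(id, "_ORB1"), "ORB_repeat", fwd[1], fwd[2], "+", id,
        orb_consensus)
    add(paste0(id, "_ORB2"), "ORB_repeat", rev_[1], rev_[2], "-", id, orb_rc)
  }
  feats <- do.call(rbind, feats)
  ord <- order(feats$start)
  check <- feats[ord, ]
  if (any(check$start[-1] < check$end[-nrow(check)]))
    stop("planted elements overlap: cdc6 loci are too close together")

  seqchars <- with_seed(seed, {
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c(0.2, 0.3, 0.3, 0.2))
  })
  seq <- paste(seqchars, collapse = "")
  for (i in which(feats$type == "ORB_repeat")) {
    planted <- if (feats$strand[i] == "+") orb_consensus else orb_rc
    substr(seq, feats$start[i] + 1, feats$end[i]) <- planted
  }

  gr <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = feats$start + 1, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$id
  S4Vectors::mcols(gr)$locus <- feats$locus
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  chrom <- chromosome("chr", length, circular = TRUE, sequence = seq)
  GenomeInfoDb::seqlengths(gr) <- length
  list(chromosome = chrom, annotation = gr)
}
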