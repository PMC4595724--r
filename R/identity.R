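#' Global-alignment percent identity between two Cdc6 proteins
#'
#' Aligns the two protein sequences globally (Needleman-Wunsch with affine
#' gaps) under the BLOSUM62 matrix, gap opening 11 and gap extension 1, and
#' returns the percent identity over alignment columns: 100 times the
#' number of identical aligned positions divided by the alignment length,
#' gap columns included in the denominator. The result is symmetric in its
#' arguments (the argument order is canonicalized before aligning, so
#' tie-breaking among co-optimal alignments cannot break symmetry).
#'
#' @param protein_a,protein_b Amino-acid sequences (character scalars over
#'   the 20-letter alphabet).
#' @param gap_opening,gap_extension Affine gap penalties; a gap of length
#'   `g` costs `gap_opening + g * gap_extension`.
#' @return Percent identity in `[0, 100]`, with the optimal alignment
#'   score in `attr(, "score")`.
#' @examples
#' cdc6_identity("AAAA", "AACA")  # 75
#' @export
cdc6_identity <- function(protein_a, protein_b, gap_opening = 11,
                          gap_extension = 1) {
  protein_a <- toupper(as.character(protein_a))
  protein_b <- toupper(as.character(protein_b))
  for (s in c(protein_a, protein_b)) {
    if (!nchar(s)) stop("empty protein sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s))
      stop("invalid residues in protein sequence: ",
           paste(unique(strsplit(gsub("[ACDEFGHIKLMNPQRSTVWY]", "", s),
                                 "")[[1]]), collapse = ""))
  }
  if (protein_b < protein_a) { tmp <- protein_a; protein_a <- protein_b
                               protein_b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  p <- strsplit(as.character(Biostrings::pattern(al)), "", fixed = TRUE)[[1]]
  s <- strsplit(as.character(Biostrings::subject(al)), "", fixed = TRUE)[[1]]
  structure(100 * sum(p == s) / length(p), score = Biostrings::score(al))
}

#' Is one Cdc6 an ortholog-of-origin of another?
#'
#' Companion classifier for [cdc6_identity()]: two initiator proteins are
#' called orthologs serving the same origin type when their global percent
#' identity exceeds the threshold (default 80).
#'
#' @inheritParams cdc6_identity
#' @param threshold Identity threshold in percent (exclusive).
#' @return `TRUE` or `FALSE`.
#' @export
is_cdc6_ortholog <- function(protein_a, protein_b, threshold = 80) {
  as.numeric(cdc6_identity(protein_a, protein_b)) > threshold
}
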