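#' Write and read a genome FASTA
#'
#' @param chromosome A [chromosome()] carrying a sequence.
#' @param path Output file.
#' @return `write_genome_fasta` returns `path` invisibly;
#'   `read_genome_fasta` returns a [chromosome()].
#' @export
write_genome_fasta <- function(chromosome, path) {
  if (is.null(chromosome$sequence)) stop("chromosome carries no sequence")
  set <- Biostrings::DNAStringSet(stats::setNames(chromosome$sequence,
                                                  chromosome$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param circular Circularity flag to attach on read (not stored in
#'   FASTA).
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("no sequences in ", path)
  name <- sub("\\s.*$", "", names(set)[1])
  chromosome(name, Biostrings::width(set)[1], circular = circular,
             sequence = as.character(set[[1]]))
}

#' Write and read feature annotation as GFF3
#'
#' Internally the package uses 0-based half-open coordinates; GFF3 is
#' 1-based closed and the conversion happens inside the `GRanges`
#' representation used here, which is already 1-based.
#'
#' @param annotation A `GRanges` with `type` and `ID` metadata columns.
#' @param path Output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr
}

#' Write and read the per-probe signal table (TSV)
#'
#' Tab-separated with the header
#' `probe_pos  exp_signal  stat_signal  ratio`.
#'
#' @param table A probe ratio table.
#' @param path File path.
#' @export
write_probe_table <- function(table, path) {
  utils::write.table(
    table[, c("probe_pos", "exp_signal", "stat_signal", "ratio")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty probe table: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("probe_pos", "exp_signal", "stat_signal", "ratio")
  if (!identical(header[1:4], expected))
    stop("line 1: expected header '", paste(expected, collapse = "\t"), "'")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 4)
      stop("line ", i + 1, ": expected 4 tab-separated fields")
    if (anyNA(suppressWarnings(as.numeric(fields[[i]][1:4]))))
      stop("line ", i + 1, ": non-numeric field")
  }
  m <- matrix(as.numeric(unlist(lapply(fields, `[`, 1:4))), ncol = 4,
              byrow = TRUE)
  tab <- compute_ratios(m[, 2], m[, 3], m[, 1])
  tab
}

#' Write and read read positions as BED3
#'
#' Plain 3-column BED, 0-based half-open, sorted by start. The reader
#' rejects malformed rows with a line-numbered error.
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_bed <- function(reads, path) {
  writeLines(paste(reads$chrom, format(reads$start, scientific = FALSE,
                                       trim = TRUE),
                   format(reads$end, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop("line ", i, ": BED rows need at least 3 fields")
    se <- suppressWarnings(as.numeric(f[2:3]))
    if (anyNA(se)) stop("line ", i, ": non-numeric BED coordinates")
    if (se[1] < 0 || se[2] <= se[1])
      stop("line ", i, ": invalid BED interval [", f[2], ", ", f[3], ")")
  }
  data.frame(chrom = vapply(fields, `[`, character(1), 1),
             start = vapply(fields, function(f) as.numeric(f[2]),
                            numeric(1)),
             end = vapply(fields, function(f) as.numeric(f[3]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Write and read an MFA profile as bedGraph
#'
#' Position-sorted, 0-based half-open; each profile point spans up to the
#' next point (the final interval ends at the chromosome length when
#' known).
#'
#' @param profile An `mfa_profile`.
#' @param path File path.
#' @export
write_profile_bedgraph <- function(profile, path) {
  pos <- profile$position
  L <- attr(profile, "chrom_length")
  ends <- c(pos[-1], if (!is.null(L) && !is.na(L)) L else
    pos[length(pos)] + mean(diff(pos)))
  writeLines(paste(attr(profile, "chrom") %||% "chr",
                   format(pos, scientific = FALSE, trim = TRUE),
                   format(ends, scientific = FALSE, trim = TRUE),
                   format(profile$value, digits = 10, scientific = FALSE,
                          trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_profile_bedgraph
#' @param circular,source,smoothed Profile metadata to attach on read
#'   (bedGraph does not store it).
#' @export
read_profile_bedgraph <- function(path, circular = TRUE, source = "array",
                                  smoothed = TRUE) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 4)
      stop("line ", i, ": bedGraph rows need 4 fields")
    if (anyNA(suppressWarnings(as.numeric(fields[[i]][2:4]))))
      stop("line ", i, ": non-numeric bedGraph fields")
  }
  start <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  val <- vapply(fields, function(f) as.numeric(f[4]), numeric(1))
  last_end <- as.numeric(fields[[length(fields)]][3])
  mfa_profile(start, val, chrom = fields[[1]][1], chrom_length = last_end,
              circular = circular, source = source, smoothed = smoothed)
}

#' Write peak calls as BED6 with a JSON sidecar
#'
#' The BED6 carries one row per peak (name `peak_<n>`, score = height,
#' strand `.`); the sidecar `<path>.json` carries heights, prominences and
#' relative efficiencies.
#'
#' @param peaks A `peak_calls` table.
#' @param path BED output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  chrom <- attr(peaks, "chrom") %||% "chr"
  writeLines(paste(chrom,
                   format(peaks$position, scientific = FALSE, trim = TRUE),
                   format(peaks$position + 1, scientific = FALSE,
                          trim = TRUE),
                   paste0("peak_", seq_len(nrow(peaks))),
                   format(peaks$height, digits = 6, trim = TRUE), ".",
                   sep = "\t"), path)
  jsonlite::write_json(
    list(chrom = chrom,
         peaks = data.frame(position = peaks$position,
                            height = peaks$height,
                            prominence = peaks$prominence,
                            relative_efficiency =
                              peaks$relative_efficiency)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
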