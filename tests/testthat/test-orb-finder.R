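make_annotation <- function(starts, ends, strands, ids,
                            types = "gene", seqlen = NULL) {
  gr <- GenomicRanges::GRanges("chr",
                               IRanges::IRanges(start = starts, end = ends),
                               strand = strands)
  S4Vectors::mcols(gr)$type <- types
  S4Vectors::mcols(gr)$ID <- ids
  if (!is.null(seqlen)) GenomeInfoDb::seqlengths(gr) <- seqlen
  gr
}

test_that("upstream intergenic extraction is strand-aware", {
  # plus-strand gene at [5000, 6000), neighbour ends at 4200 (0-based)
  ann <- make_annotation(c(3500, 5001), c(4200, 6000), c("+", "+"),
                         c("nbr", "g"))
  r <- extract_upstream_intergenic(ann, "g")
  expect_equal(c(r$start, r$end), c(4200, 5000))
  # minus-strand gene at [5000, 6000), next gene starts at 6800
  ann2 <- make_annotation(c(5001, 6801), c(6000, 7500), c("-", "+"),
                          c("g", "nbr"))
  r2 <- extract_upstream_intergenic(ann2, "g")
  expect_equal(c(r2$start, r2$end), c(6000, 6800))
  # truncation to max_span, anchored at the gene
  ann3 <- make_annotation(c(1, 9001), c(100, 9500), c("+", "+"),
                          c("nbr", "g"))
  r3 <- extract_upstream_intergenic(ann3, "g", max_span = 2000)
  expect_equal(c(r3$start, r3$end), c(7000, 9000))
  expect_error(extract_upstream_intergenic(ann, "missing"), "not found")
  # abutting genes leave no intergenic region
  ann4 <- make_annotation(c(1, 1001), c(1000, 2000), c("+", "+"),
                          c("nbr", "g"))
  expect_error(extract_upstream_intergenic(ann4, "g"), "no intergenic")
})

test_that("an exact 30-mer and its reverse complement are found as one inverted motif", {
  motif <- substr(test_orb, 1, 30)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  set.seed(5)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  seq <- paste0(bg(100), motif, bg(50), rc, bg(100))
  found <- find_repeated_motifs(seq, max_mismatch = 0)
  expect_equal(length(found), 1)
  inst <- found[[1]]$instances
  expect_equal(nrow(inst), 2)
  expect_setequal(inst$strand, c("+", "-"))
  # both planted copies are covered by the reported instances
  expect_true(any(inst$start <= 100 & inst$end >= 130))
  expect_true(any(inst$start <= 180 & inst$end >= 210))
})

test_that("random sequences contain no repeats, matching the brute-force oracle", {
  for (s in 1:6) {
    seq <- random_dna(500, seed = 1000 + s, prob = rep(0.25, 4))
    oracle <- bf_repeat_pairs(seq, len = 18, max_mismatch = 0)
    found <- find_repeated_motifs(seq, max_mismatch = 0)
    expect_equal(length(found) > 0, nrow(oracle) > 0)
    expect_equal(length(found), 0)
  }
})

test_that("mismatch budget controls recovery of degenerate planted repeats", {
  motif <- substr(test_orb, 1, 30)
  mutated <- motif
  substr(mutated, 5, 5) <- "A"; substr(mutated, 20, 20) <- "T"
  expect_equal(sum(strsplit(motif, "")[[1]] !=
                     strsplit(mutated, "")[[1]]), 2)
  set.seed(9)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  seq <- paste0(bg(80), motif, bg(60), mutated, bg(80))
  hit2 <- find_repeated_motifs(seq, max_mismatch = 2)
  covered <- function(found) any(vapply(found, function(m) {
    any(m$instances$start <= 80 & m$instances$end >= 110) &&
      any(m$instances$start <= 170 & m$instances$end >= 200)
  }, logical(1)))
  expect_true(covered(hit2))
  hit1 <- find_repeated_motifs(seq, max_mismatch = 1)
  expect_false(covered(hit1))
  # both routes agree at matching budgets
  expect_gt(nrow(bf_repeat_pairs(seq, 30, 2)), 0)
  expect_equal(nrow(bf_repeat_pairs(seq, 30, 1)), 0)
})

test_that("every reported motif pair is a genuine repeat within the mismatch budget", {
  # soundness of the search engine, validated by direct substring
  # comparison (independent of the diagonal-scan implementation)
  rc_str <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                           "")[[1]]), collapse = "")
  for (s in 1:4) {
    motif <- substr(test_orb, 1, 24)
    set.seed(200 + s)
    bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    seq <- paste0(bg(150), motif, bg(40), rc_str(motif), bg(150))
    for (m in find_repeated_motifs(seq, max_mismatch = 3)) {
      inst <- m$instances
      len <- m$length
      expect_gte(len, 18); expect_lte(len, 35)
      oriented <- vapply(seq_len(nrow(inst)), function(i) {
        sub <- substr(seq, inst$start[i] + 1, inst$start[i] + len)
        if (inst$strand[i] == "-") rc_str(sub) else sub
      }, character(1))
      mm <- sum(strsplit(oriented[1], "")[[1]] !=
                  strsplit(oriented[2], "")[[1]])
      expect_lte(mm, 3)
    }
  }
})

test_that("the G-string rule checks both strands", {
  expect_true(has_g_string("ACGGGGTACGTACGTACG"))
  expect_false(has_g_string(strrep("A", 20)))
  expect_true(has_g_string("ATCCCCTACGTACGTACGT"))  # G run on minus strand
  expect_false(has_g_string("AGGGTAGGGTAGGGTAGG", g_run = 4))
  expect_true(has_g_string("AGGGTAGGGTAGGGTAGG", g_run = 3))
})

test_that("origin prediction applies the G-string and inverted-pair rules per locus", {
  loci <- data.frame(position = c(20000, 60000, 100000, 140000),
                     strand = c("+", "+", "-", "+"))
  g <- generate_genome(160000, loci, orb_consensus = test_orb,
                       orb_spacing = 30, seed = 7)
  res <- predict_origins(g$chromosome, g$annotation,
                         paste0("cdc6_", 1:4), max_mismatch = 0)
  expect_equal(length(res$predictions), 4)
  expect_equal(nrow(res$failures), 0)
  for (p in res$predictions) {
    expect_setequal(p$motif$instances$strand[p$inverted_pair], c("+", "-"))
    # the predicted origin midpoint lies inside the upstream region
    expect_gte(p$position, p$region$start)
    expect_lte(p$position, p$region$end)
  }
})

test_that("loci without a G-string or without an inverted pair are excluded with the step named", {
  no_g <- "TTCACTATGTCCACTGAAACGTACACGT"   # no G>=4 run on either strand
  expect_false(has_g_string(no_g))
  g1 <- generate_genome(60000, data.frame(position = 30000, strand = "+"),
                        orb_consensus = no_g, seed = 11)
  r1 <- predict_origins(g1$chromosome, g1$annotation, "cdc6_1",
                        max_mismatch = 0)
  expect_equal(length(r1$predictions), 0)
  expect_equal(r1$failures$step, "no G-string")

  # plant both copies on the same strand: direct repeat, not inverted
  g2 <- generate_genome(60000, data.frame(position = 30000, strand = "+"),
                        orb_consensus = test_orb, seed = 12)
  ann <- g2$annotation
  orbs <- which(S4Vectors::mcols(ann)$type == "ORB_repeat")
  seq <- g2$chromosome$sequence
  minus <- orbs[as.character(BiocGenerics::strand(ann)[orbs]) == "-"]
  substr(seq, BiocGenerics::start(ann)[minus],
         BiocGenerics::end(ann)[minus]) <- test_orb
  chrom2 <- chromosome("chr", nchar(seq), sequence = seq)
  r2 <- predict_origins(chrom2, ann, "cdc6_1", max_mismatch = 0)
  expect_equal(length(r2$predictions), 0)
  expect_equal(r2$failures$step, "no inverted pair")
})

test_that("predictions are invariant under reverse-complementing the genome", {
  loci <- data.frame(position = c(20000, 60000), strand = c("+", "+"))
  g <- generate_genome(80000, loci, orb_consensus = test_orb, seed = 21)
  res <- predict_origins(g$chromosome, g$annotation, c("cdc6_1", "cdc6_2"),
                         max_mismatch = 0)
  L <- 80000
  seq_rc <- paste(rev(strsplit(chartr("ACGT", "TGCA",
                                      g$chromosome$sequence),
                               "")[[1]]), collapse = "")
  ann <- g$annotation
  new_start <- L - BiocGenerics::end(ann) + 1
  new_end <- L - BiocGenerics::start(ann) + 1
  flipped <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(start = new_start, end = new_end),
    strand = ifelse(as.character(BiocGenerics::strand(ann)) == "+",
                    "-", "+"))
  S4Vectors::mcols(flipped) <- S4Vectors::mcols(ann)
  chrom_rc <- chromosome("chr", L, sequence = seq_rc)
  res_rc <- predict_origins(chrom_rc, flipped, c("cdc6_1", "cdc6_2"),
                            max_mismatch = 0)
  expect_equal(length(res_rc$predictions), length(res$predictions))
  pos <- sort(vapply(res$predictions, `[[`, numeric(1), "position"))
  pos_rc <- sort(L - vapply(res_rc$predictions, `[[`, numeric(1),
                            "position"))
  expect_equal(pos, pos_rc, tolerance = 1e-8)
})

test_that("synthetic-genome regions round-trip through extraction and motif search", {
  g <- generate_genome(50000, data.frame(position = 25000, strand = "+"),
                       orb_consensus = test_orb, orb_spacing = 30,
                       seed = 33)
  region <- extract_upstream_intergenic(g$annotation, "cdc6_1")
  ann <- g$annotation
  orbs <- ann[S4Vectors::mcols(ann)$type == "ORB_repeat"]
  # region covers both planted instances
  expect_true(all(BiocGenerics::start(orbs) - 1 >= region$start &
                    BiocGenerics::end(orbs) <= region$end))
  seq <- substr(g$chromosome$sequence, region$start + 1, region$end)
  found <- find_repeated_motifs(seq, max_mismatch = 0)
  expect_gte(length(found), 1)
  strands <- unlist(lapply(found, function(m) m$instances$strand))
  expect_setequal(unique(strands), c("+", "-"))
})
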