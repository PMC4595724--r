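# Shared noiseless wild-type profile: simulate -> ratios -> filter ->
# bin -> smooth, at the study conditions.
noiseless_profile <- function(origins, chr = wt_chromosome(),
                              par = wt_params(), seed = 1) {
  design <- probe_design(chr$length)
  tab <- filter_outliers(simulate_microarray(chr, origins, par, design,
                                             noise_model(0), seed = seed))
  smooth_profile(bin_probes(tab, 30), 5)
}

test_that("noiseless wild-type profile yields exactly one peak per active origin", {
  ori <- active_origins()
  prof <- noiseless_profile(ori)
  pk <- call_peaks(prof)
  spacing <- wt_chromosome()$length / nrow(prof)
  expect_equal(nrow(pk), 3)
  for (i in seq_len(3)) {
    d <- min(circ_d(pk$position, ori$position[i], 2.9e6))
    expect_lte(d, 2 * spacing)
  }
})

test_that("deleting an origin removes its peak from the noiseless profile", {
  deleted <- origin_set(c("oriC1", "oriC2", "oriC3"),
                        c(3e5, 1.3e6, 2.2e6), c(0, 0.5, 0.3))
  pk <- call_peaks(noiseless_profile(deleted))
  expect_true(all(circ_d(pk$position, 3e5, 2.9e6) > 20000))
})

test_that("constant and empty profiles produce no or an error", {
  const <- oriMFA:::mfa_profile(seq(0, 900, 100), rep(1, 10),
                                chrom_length = 1000, circular = TRUE)
  expect_equal(nrow(call_peaks(const)), 0)
  empty <- oriMFA:::mfa_profile(numeric(0), numeric(0))
  expect_error(call_peaks(empty), "empty")
})

test_that("relative efficiencies are normalized peak heights above baseline", {
  ori <- active_origins()
  prof <- noiseless_profile(ori)
  pk <- estimate_efficiency(call_peaks(prof), prof)
  expect_equal(sum(pk$relative_efficiency), 1)
  # rank agreement with the simulated efficiencies (peaks sorted by
  # position match origins oriC1..oriC3)
  expect_equal(order(pk$relative_efficiency, decreasing = TRUE),
               order(ori$efficiency, decreasing = TRUE))
  # single peak -> efficiency 1
  single <- origin_set("only", 5e5, 0.8)
  prof1 <- noiseless_profile(single)
  pk1 <- estimate_efficiency(call_peaks(prof1), prof1)
  expect_equal(nrow(pk1), 1)
  expect_equal(pk1$relative_efficiency, 1)
})

test_that("two equally efficient symmetric origins get equal efficiency estimates", {
  # exact mirror symmetry: a grid that divides the chromosome evenly and
  # origins placed symmetrically on it
  chr <- wt_chromosome()
  par <- wt_params()
  ori <- origin_set(c("a", "b"), c(7.25e5, 2.175e6), c(0.6, 0.6))
  grid <- seq(0, chr$length - 1000, by = 1000)
  mf <- expected_marker_frequency(chr, ori, par, grid)
  prof <- smooth_profile(oriMFA:::mfa_profile(grid, mf,
                                              chrom_length = chr$length,
                                              circular = TRUE), 5)
  pk <- estimate_efficiency(call_peaks(prof), prof)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$relative_efficiency[1], pk$relative_efficiency[2],
               tolerance = 1e-9)
})

test_that("activation comparison labels lost, activated, active and absent origins", {
  wt <- call_peaks(noiseless_profile(wt_origins(e4 = 0)))
  ko_ori <- origin_set(c("oriC1", "oriC2", "oriC3", "oriC4"),
                       c(3e5, 1.3e6, 2.2e6, 2.7e6), c(0, 0, 0, 0.8))
  ko <- call_peaks(noiseless_profile(ko_ori))
  known <- data.frame(id = c("oriC1", "oriC2", "oriC3", "oriC4"),
                      position = c(3e5, 1.3e6, 2.2e6, 2.7e6))
  calls <- compare_profiles(wt, ko, known, match_tolerance = 2e4)
  expect_equal(calls$status,
               c("lost", "lost", "lost", "activated"))
  # antisymmetry under swapping parent and mutant
  rev_calls <- compare_profiles(ko, wt, known, match_tolerance = 2e4)
  expect_equal(rev_calls$status,
               c("activated", "activated", "activated", "lost"))
  # identical peak lists: every matched origin active
  same <- compare_profiles(wt, wt, known, match_tolerance = 2e4)
  expect_equal(same$status, c("active", "active", "active",
                              "unchanged-absent"))
  # empty mutant list: parent-active origins all lost
  none <- call_peaks(oriMFA:::mfa_profile(seq(0, 2.9e6 - 1, 882),
                                          rep(1, 3288),
                                          chrom_length = 2.9e6,
                                          circular = TRUE))
  gone <- compare_profiles(wt, none, known, match_tolerance = 2e4)
  expect_equal(gone$status, c("lost", "lost", "lost", "unchanged-absent"))
  expect_error(compare_profiles(wt, ko,
                                data.frame(id = c("a", "a"),
                                           position = c(1, 2))),
               "duplicate")
})

test_that("predicted origins are classified active or dormant by peak support", {
  peaks <- call_peaks(noiseless_profile(active_origins()))
  preds <- data.frame(gene_id = paste0("cdc6_", 1:4),
                      position = c(3e5, 1.3e6, 2.2e6, 2.7e6))
  cls <- classify_predicted_origins(preds, peaks, match_tolerance = 2e4)
  expect_equal(cls$status, c("active", "active", "active", "dormant"))
  no_peaks <- peaks[0, , drop = FALSE]
  attr(no_peaks, "chrom_length") <- 2.9e6
  cls2 <- classify_predicted_origins(preds, no_peaks)
  expect_equal(cls2$status, rep("dormant", 4))
  cls3 <- classify_predicted_origins(preds, peaks,
                                     match_tolerance = 2.9e6)
  expect_equal(cls3$status, rep("active", 4))
})

test_that("peak positions shift with the coordinate origin on a circular profile", {
  ori <- active_origins()
  prof <- noiseless_profile(ori)
  pk <- call_peaks(prof)
  n <- nrow(prof)
  shift_pts <- 700
  L <- 2.9e6
  rolled <- oriMFA:::mfa_profile(prof$position, # same grid
                                 c(prof$value[(shift_pts + 1):n],
                                   prof$value[1:shift_pts]),
                                 chrom = "chr", chrom_length = L,
                                 circular = TRUE, smoothed = TRUE)
  pk2 <- call_peaks(rolled)
  expect_equal(nrow(pk2), nrow(pk))
  shift_bp <- prof$position[shift_pts + 1]
  expected <- sort((pk$position - shift_bp) %% L)
  expect_true(all(circ_d(sort(pk2$position), expected, L) <= 2 * L / n))
})

test_that("noisy wild-type profiles give few spurious calls and locate the strong origins", {
  chr <- wt_chromosome()
  par <- wt_params()
  ori <- active_origins()
  design <- probe_design(chr$length)
  for (s in 1:5) {
    tab <- filter_outliers(simulate_microarray(chr, ori, par, design,
                                               noise_model(0.07),
                                               seed = s))
    pk <- call_peaks(smooth_profile(bin_probes(tab, 30), 5))
    spurious <- sum(vapply(pk$position, function(p)
      all(circ_d(ori$position, p, chr$length) > 2e4), logical(1)))
    expect_lte(spurious, 1)
    # the two strongest origins are always recovered within the
    # 20-kb matching tolerance used downstream
    expect_lte(min(circ_d(pk$position, 3e5, chr$length)), 2e4)
    expect_lte(min(circ_d(pk$position, 1.3e6, chr$length)), 2e4)
  }
})
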