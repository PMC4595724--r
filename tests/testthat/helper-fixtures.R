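# Shared fixtures: the wild-type study condition (circular 2.9-Mb
# chromosome, three active origins of unequal efficiency, one dormant
# origin) plus small fast variants for unit tests.

wt_chromosome <- function(length = 2.9e6) chromosome("chr", length)

wt_origins <- function(e4 = 0) {
  origin_set(c("oriC1", "oriC2", "oriC3", "oriC4"),
             c(3e5, 1.3e6, 2.2e6, 2.7e6),
             c(0.9, 0.5, 0.3, e4))
}

active_origins <- function() {
  origin_set(c("oriC1", "oriC2", "oriC3"), c(3e5, 1.3e6, 2.2e6),
             c(0.9, 0.5, 0.3))
}

# Fork speed / doubling time such that the slowest reachable firing
# configuration (a single origin on the 2.9-Mb circle) finishes at
# 0.8 of the doubling time.
wt_params <- function(length = 2.9e6, doubling_time = 180,
                      cycling_fraction = 0.5) {
  replication_params(fork_speed = length / (1.6 * doubling_time),
                     doubling_time = doubling_time,
                     cycling_fraction = cycling_fraction)
}

# A single fully efficient origin on a small circle: closed-form MF.
single_origin_system <- function(L = 2e6, doubling_time = 100, f = 1) {
  list(chromosome = chromosome("mini", L),
       origins = origin_set("ori", 0, 1),
       params = replication_params(L / (2 * doubling_time), doubling_time,
                                   f))
}

random_dna <- function(n, seed, prob = c(0.2, 0.3, 0.3, 0.2)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# ORB consensus used by planted-genome fixtures (30 bp, carries a G run).
test_orb <- "TTCACGGGGGTCCACTGGAAACGTACACGT"

circ_d <- function(a, b, L) pmin(abs(a - b), L - abs(a - b))

temp_path <- function(ext) tempfile(fileext = ext)

# Small noiseless single-origin profile for IO tests.
noiseless_profile_io <- function() {
  sys <- single_origin_system(L = 2e5, doubling_time = 100)
  design <- probe_design(2e5)
  tab <- filter_outliers(simulate_microarray(sys$chromosome, sys$origins,
                                             sys$params, design,
                                             noise_model(0), seed = 1))
  smooth_profile(bin_probes(tab, 30), 5)
}
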