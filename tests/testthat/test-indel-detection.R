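test_that("seeding requires five consecutive bins past the cut", {
  expect_equal(nrow(seed_runs(flat_profile(rep(1, 100)))), 0)
  d <- rep(1, 100); d[21:24] <- 0.3            # four bins: not enough
  expect_equal(nrow(seed_runs(flat_profile(d))), 0)
  d[25] <- 0.3                                  # five bins: one seed
  s <- seed_runs(flat_profile(d))
  expect_equal(nrow(s), 1)
  expect_equal(c(s$lo, s$hi), c(21, 25))
  # the 135-bin reconstruction of a published terminal deletion
  layout <- fixture_layout()
  one <- data.frame(scaffold = "Chr08_A", start = 1, end = 13.5e6,
                    mean_dosage = 0.68)
  s <- seed_runs(profile_from_indel_table(one, layout))
  s <- s[s$scaffold == "Chr08_A", ]
  expect_equal(nrow(s), 1)
  expect_equal(s$hi - s$lo + 1, 135)
})

test_that("seed runs equal a brute-force enumeration on noisy profiles", {
  params <- detection_params()
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(500:10000, 1)
    d <- pmax(0, 1 + stats::rnorm(n, 0, 0.12))
    # implant blocks of various dosages and a masked stretch
    d[101:160] <- 0.7 + stats::rnorm(60, 0, 0.05)
    d[301:310] <- 1.7 + stats::rnorm(10, 0, 0.05)
    masked <- rep(FALSE, n); masked[sample.int(n, n %/% 20)] <- TRUE
    prof <- flat_profile(d, masked)
    got <- seed_runs(prof, params)
    want <- brute_force_seeds(prof, params)
    expect_equal(got[order(got$type, got$lo), c("type", "lo", "hi")],
                 want[order(want$type, want$lo), c("type", "lo", "hi")],
                 ignore_attr = TRUE)
  }
})

test_that("a stricter deletion cut never creates a new seed", {
  set.seed(9)
  d <- pmax(0, 1 + stats::rnorm(2000, 0, 0.15))
  d[501:540] <- 0.75
  prof <- flat_profile(d)
  loose <- seed_runs(prof, detection_params(del_cut = 0.80))
  strict <- seed_runs(prof, detection_params(del_cut = 0.70))
  loose_bins <- unlist(lapply(seq_len(nrow(loose)), function(i) {
    if (loose$type[i] == "deletion") seq(loose$lo[i], loose$hi[i])
  }))
  strict_bins <- unlist(lapply(seq_len(nrow(strict)), function(i) {
    if (strict$type[i] == "deletion") seq(strict$lo[i], strict$hi[i])
  }))
  expect_true(all(strict_bins %in% loose_bins))
})

test_that("masked bins are transparent to runs", {
  d <- rep(1, 60)
  d[21:30] <- 0.3
  masked <- rep(FALSE, 60); masked[25:26] <- TRUE
  d[25:26] <- NA
  s <- seed_runs(flat_profile(d, masked))
  expect_equal(nrow(s), 1)
  # indices are within the unmasked subsequence: 8 passing bins remain
  expect_equal(s$hi - s$lo + 1, 8)
  calls <- detect_indels(flat_profile(d, masked))
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(20e5 + 1, 30e5))
})

test_that("an isolated clean seed is called at its own extent", {
  d <- rep(1, 200); d[61:100] <- 0.3
  calls <- detect_indels(flat_profile(d))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion")
  expect_equal(c(calls$start, calls$end), c(60e5 + 1, 100e5))
  expect_equal(calls$mean_dosage, 0.3)
  expect_equal(calls$n_bins, 40L)
})

test_that("nearby same-type runs merge across a sub-threshold gap", {
  d <- rep(1, 120)
  d[31:40] <- 0.3
  d[41:60] <- 0.95   # 20-bin gap, below gap_bins
  d[61:70] <- 0.3
  calls <- detect_indels(flat_profile(d))
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(30e5 + 1, 70e5))
  expect_equal(calls$mean_dosage, mean(d[31:70]))
  # beyond gap_bins the calls stay separate
  d2 <- rep(1, 200)
  d2[31:40] <- 0.3
  d2[76:85] <- 0.3   # 35-bin gap
  calls2 <- detect_indels(flat_profile(d2))
  expect_equal(nrow(calls2), 2)
})

test_that("whole-scaffold aneuploidy yields a single full-length call", {
  layout <- genome_layout(c("chrA", "chrB"), c(2e7, 1.5e7))
  rows <- data.frame(scaffold = "chrA", start = 1, end = 2e7,
                     mean_dosage = 0.7)
  prof <- profile_from_indel_table(rows, layout)
  calls <- detect_indels(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(1, 2e7))
  expect_equal(calls$n_bins, 200L)
})

test_that("opposite-sign overlaps resolve toward the stronger call", {
  # two deletion runs whose gap-merge would swallow an embedded insertion
  d <- rep(1, 120)
  d[21:30] <- 0.2
  d[40:46] <- 1.6
  d[55:64] <- 0.2
  calls <- detect_indels(flat_profile(d))
  expect_setequal(calls$type, c("deletion", "insertion"))
  ins <- calls[calls$type == "insertion", ]
  del <- calls[calls$type == "deletion", ]
  expect_equal(c(ins$start, ins$end), c(39e5 + 1, 46e5))
  # the insertion (|d-1| = 0.6) outranks the diluted merged deletion,
  # which is truncated clear of the overlap
  expect_true(all(del$end < ins$start | del$start > ins$end))
  expect_true(all(del$mean_dosage < 1) && all(ins$mean_dosage > 1))
})

test_that("mean dosage averages unmasked bins in an interval", {
  prof <- flat_profile(c(rep(1, 10), rep(0.7, 10), rep(1, 10)))
  expect_equal(mean_dosage(prof, "sc1", 10e5 + 1, 20e5), 0.7)
  prof2 <- flat_profile(c(rep(0.2, 5), rep(0.4, 5)))
  expect_equal(mean_dosage(prof2, "sc1", 1, 10e5), 0.3)
  # a published interval mean from the reconstruction
  recon <- profile_from_indel_table(p011_rows(), fixture_layout())
  expect_equal(mean_dosage(recon, "Chr03_E", 17100001, 18400000), 0.38)
  # fully masked interval is undefined
  prof3 <- flat_profile(rep(1, 10), masked = rep(TRUE, 10))
  expect_warning(v <- mean_dosage(prof3, "sc1", 1, 10e5), "masked")
  expect_true(is.na(v))
})
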