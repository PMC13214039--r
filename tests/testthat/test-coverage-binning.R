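# builds a small coordinate-sorted SAM in a temp file
write_test_sam <- function(reads, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              "@SQ\tSN:sc1\tLN:200000",
              "@SQ\tSN:scX\tLN:100000")
  body <- vapply(reads, function(r) {
    paste(r$qname, "0", r$rname, r$pos, r$mapq, "50M", "*", "0", "0",
          "*", "*", sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

test_that("reads land in the bin of their leftmost base, under a mapq filter", {
  layout <- genome_layout("sc1", 2e5)
  reads <- list(list(qname = "r1", rname = "sc1", pos = 1, mapq = 60),
                list(qname = "r2", rname = "sc1", pos = 99999, mapq = 60),
                list(qname = "r3", rname = "sc1", pos = 100001, mapq = 60),
                list(qname = "r4", rname = "sc1", pos = 150000, mapq = 39),
                list(qname = "r5", rname = "scX", pos = 10, mapq = 60))
  tab <- bin_counts_from_alignments(write_test_sam(reads), layout)
  expect_equal(tab$count, c(2L, 1L))   # r4 under threshold, r5 off-layout
  expect_equal(attr(tab, "skipped_reads"), 1L)
  # lowering the threshold admits r4
  tab2 <- bin_counts_from_alignments(write_test_sam(reads), layout,
                                     min_mapq = 30)
  expect_equal(tab2$count, c(2L, 2L))
})

test_that("unsorted alignments are rejected and empty input warns", {
  layout <- genome_layout("sc1", 2e5)
  unsorted <- list(list(qname = "r1", rname = "sc1", pos = 150000, mapq = 60),
                   list(qname = "r2", rname = "sc1", pos = 10, mapq = 60))
  expect_error(bin_counts_from_alignments(write_test_sam(unsorted), layout),
               "sorted")
  empty <- write_test_sam(list())
  expect_warning(tab <- bin_counts_from_alignments(empty, layout),
                 "no mapped reads")
  expect_true(all(tab$count == 0))
})

make_counts <- function(counts, layout) {
  bins <- layout_bins(layout)
  bins$count <- counts
  bin_count_table(bins, layout)
}

test_that("normalization recovers relative dosage and is scale invariant", {
  layout <- genome_layout("sc1", 1e8)  # 1,000 bins
  ctrl <- make_counts(rep(1000L, 1000), layout)
  s <- rep(1000L, 1000); s[101:150] <- 500L
  prof <- normalize_to_control(make_counts(s, layout), ctrl)
  expect_equal(prof$dosage[101:150], rep(0.5, 50))
  expect_equal(prof$dosage[-(101:150)], rep(1, 950))
  # identity
  ident <- normalize_to_control(ctrl, ctrl)
  expect_true(all(ident$dosage[!ident$masked] == 1))
  # zero sample counts give dosage 0 (a full deletion)
  s0 <- rep(1000L, 1000); s0[201:260] <- 0L
  prof0 <- normalize_to_control(make_counts(s0, layout), ctrl)
  expect_true(all(prof0$dosage[201:260] == 0))
  # scaling every sample count leaves the profile unchanged
  prof3 <- normalize_to_control(make_counts(s * 3L, layout), ctrl)
  expect_equal(prof3$dosage, prof$dosage)
  # median of unmasked dosages is exactly 1 by construction
  expect_identical(stats::median(prof$dosage[!prof$masked]), 1)
})

test_that("low-coverage control bins are masked, mismatches error", {
  layout <- genome_layout("sc1", 1e7)
  c_counts <- rep(400L, 100); c_counts[11:13] <- c(0L, 50L, 90L)
  ctrl <- make_counts(c_counts, layout)
  prof <- normalize_to_control(make_counts(rep(400L, 100), layout), ctrl)
  expect_equal(which(prof$masked), 11:13)  # below 25% of control median
  expect_true(all(is.na(prof$dosage[11:13])))
  other <- genome_layout("sc2", 1e7)
  expect_error(
    normalize_to_control(make_counts(rep(1L, 100), other), ctrl),
    "different layouts")
  all_zero <- make_counts(rep(0L, 100), layout)
  expect_error(normalize_to_control(ctrl, all_zero), "masked")
})

test_that("render -> normalize round trip recovers truth dosage", {
  layout <- genome_layout("sc1", 5e7)
  leaf <- layer_model("leaf")
  ev <- data.frame(scaffold = "sc1", start = 1e7 + 1, end = 3e7,
                   type = "deletion", layers = "L1", copies = 1L)
  depth <- 200
  sample <- render_bin_counts(ev, layout, leaf, depth = depth, seed = 31)
  ctrl <- render_bin_counts(NULL, layout, leaf, depth = depth, seed = 32)
  prof <- normalize_to_control(sample, ctrl)
  truth <- truth_profile(ev, layout, leaf)
  mae <- mean(abs(prof$dosage[!prof$masked] - truth$dosage[!prof$masked]))
  expect_lt(mae, 3 / sqrt(depth))
})

test_that("bin count and dosage profile TSVs round trip", {
  layout <- genome_layout("sc1", 1e6)
  tab <- make_counts(1:10, layout)
  f <- tempfile(fileext = ".tsv")
  write_bin_counts(tab, f)
  back <- read_bin_counts(f, layout)
  expect_equal(back$count, tab$count)
  prof <- normalize_to_control(tab, make_counts(rep(5L, 10), layout))
  g <- tempfile(fileext = ".tsv")
  write_dosage_profile(prof, g)
  back2 <- read_dosage_profile(g)
  expect_equal(back2$dosage, prof$dosage)
  expect_equal(back2$masked, prof$masked)
})
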