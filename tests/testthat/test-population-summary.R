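test_that("dose response rates and totals are conserved", {
  individuals <- data.frame(individual = c("a", "b", "c"), dose = 45)
  calls <- data.frame(
    individual = c("a", "a", "b", "b", "b", "c", "c", "c", "c"),
    type = "deletion", size_mb = 5, stringsAsFactors = FALSE)
  tab <- dose_response_table(calls, individuals)
  expect_equal(tab$all_per_sample, 3)      # counts {2,3,4} over 3 samples
  expect_equal(tab$all_total, 9)
  # rate x n = total, exactly
  expect_equal(tab$all_per_sample * tab$n_samples, tab$all_total)
  # multiple doses: grand total conserved, empty stratum kept
  individuals2 <- rbind(individuals,
                        data.frame(individual = "d", dose = 15))
  tab2 <- dose_response_table(calls, individuals2)
  expect_equal(sum(tab2$all_total), nrow(calls))
  expect_equal(tab2$all_total[tab2$dose == 15], 0)
  expect_error(dose_response_table(
    data.frame(individual = "zz", type = "deletion", size_mb = 1),
    individuals), "unknown")
})

test_that("aggregating the printed dose table reproduces its rates", {
  pop <- population_from_dose_table(mint_dose_table())
  tab <- dose_response_table(pop$calls, pop$individuals)
  expect_equal(round(tab$all_per_sample, 2), c(2.62, 4.71, 5.66, 7.00))
  expect_equal(sum(tab$all_total), 1406)
})

test_that("layer summary computes union coverage, not summed lengths", {
  layout <- genome_layout("chrA", 1e8)
  one <- data.frame(scaffold = "chrA", start = 1, end = 1e7,
                    type = "deletion", layer = "L1", size_mb = 10,
                    stringsAsFactors = FALSE)
  s <- layer_summary(one, layout)
  expect_equal(s$pct_genome[s$layer == "L1"], 10)
  two <- rbind(one, data.frame(scaffold = "chrA", start = 5e6 + 1,
                               end = 1.5e7, type = "deletion",
                               layer = "L1", size_mb = 10))
  s2 <- layer_summary(two, layout)
  expect_equal(s2$pct_genome[s2$layer == "L1"], 15)  # union, not 20
  # transcript coverage counts a gene once on any overlap
  ann <- data.frame(id = sprintf("g%d", 1:10), scaffold = "chrA",
                    start = seq(1e6, 8.2e7, length.out = 10),
                    end = seq(1e6, 8.2e7, length.out = 10) + 1e4,
                    strand = "+", stringsAsFactors = FALSE)
  s3 <- layer_summary(two, layout, annotation = ann)
  inside <- sum(ann$start <= 1.5e7)
  expect_equal(s3$pct_transcripts[s3$layer == "L1"], 100 * inside / 10)
  # no-call dosages surface as an explicit unclassified stratum
  three <- rbind(two, data.frame(scaffold = "chrA", start = 9e7 + 1,
                                 end = 9.5e7, type = "deletion",
                                 layer = "no-call", size_mb = 5))
  s4 <- layer_summary(three, layout)
  expect_true("unclassified" %in% s4$layer)
})

test_that("border density counts interior breakpoints only", {
  layout <- genome_layout(c("chrA", "chrB"), c(1e7, 5e6))
  none <- data.frame(scaffold = character(), start = numeric(),
                     end = numeric())
  bd <- border_density(none, layout)
  expect_equal(bd$zero_fraction, 1)
  expect_equal(nrow(bd$windows), 15)
  # a call inside one window contributes both borders there
  one <- data.frame(scaffold = "chrA", start = 2.2e6, end = 2.8e6)
  bd1 <- border_density(one, layout)
  expect_equal(bd1$windows$n_borders[bd1$windows$scaffold == "chrA"][3], 2)
  expect_equal(bd1$n_borders, 2)
  # whole-scaffold aneuploidy contributes no border
  aneu <- data.frame(scaffold = "chrB", start = 1, end = 5e6)
  expect_equal(border_density(aneu, layout)$n_borders, 0)
  # terminal-arm deletion contributes exactly one (interior) border
  term <- data.frame(scaffold = "chrA", start = 1, end = 3e6)
  expect_equal(border_density(term, layout)$n_borders, 1)
  # invariant: total = 2 x interior calls + 1 x arm-terminal calls
  mix <- rbind(one, aneu, term)
  expect_equal(border_density(mix, layout)$n_borders, 2 + 0 + 1)
})

test_that("shared deleted regions match the published chromosome 11 case", {
  calls <- data.frame(
    individual = c("P011", "P028"), scaffold = "Chr11_D",
    start = 1, end = c(2.5e6, 7e6), type = "deletion", layer = "L1",
    stringsAsFactors = FALSE)
  shared <- shared_deleted_regions(calls, c("P011", "P028"))
  expect_equal(nrow(shared), 1)
  expect_equal(c(shared$start, shared$end), c(1, 2.5e6))
  # disjoint deletions share nothing
  calls2 <- calls; calls2$start[2] <- 3e6; calls2$end[2] <- 7e6
  expect_equal(nrow(shared_deleted_regions(calls2, c("P011", "P028"))), 0)
  expect_error(shared_deleted_regions(calls, "P011"), "two individuals")
})

test_that("interval intersections agree with a per-bin oracle", {
  layout <- genome_layout("chrA", 1e7)
  # three individuals with nested deletions -> innermost interval
  calls <- data.frame(
    individual = c("x", "y", "z"), scaffold = "chrA",
    start = c(1e6 + 1, 2e6 + 1, 3e6 + 1), end = c(9e6, 8e6, 7e6),
    type = "deletion", stringsAsFactors = FALSE)
  shared <- shared_deleted_regions(calls, c("x", "y", "z"))
  expect_equal(c(shared$start, shared$end), c(3e6 + 1, 7e6))
  oracle <- brute_force_shared(calls, c("x", "y", "z"), layout)
  expect_equal(min(oracle$bin_start), shared$start)
  expect_equal(max(oracle$bin_end), shared$end)
  expect_equal(nrow(oracle), (shared$end - shared$start + 1) / 1e5)
  # randomized cases against the oracle
  for (seed in 1:4) {
    set.seed(seed)
    rc <- do.call(rbind, lapply(c("x", "y"), function(id) {
      s <- sort(sample(0:99, 4)) * 1e5
      data.frame(individual = id, scaffold = "chrA",
                 start = s[c(1, 3)] + 1, end = s[c(2, 4)],
                 type = "deletion", stringsAsFactors = FALSE)
    }))
    shared <- shared_deleted_regions(rc, c("x", "y"))
    oracle <- brute_force_shared(rc, c("x", "y"), layout)
    got_bins <- sum(shared$end - shared$start + 1) / 1e5
    expect_equal(got_bins, nrow(oracle))
  }
})

test_that("gene overlap requires at least one shared base", {
  ann <- data.frame(id = c("BMg1", "BMg2"), scaffold = "Chr11_D",
                    start = c(2131790, 2500001), end = c(2133606, 2600000),
                    strand = "+", stringsAsFactors = FALSE)
  iv <- data.frame(scaffold = "Chr11_D", start = 1, end = 2.5e6)
  hit <- genes_in_intervals(ann, iv)
  expect_equal(hit$id, "BMg1")   # BMg2 abuts at end+1: excluded
  # brute-force scan over a toy annotation
  ann10 <- data.frame(id = sprintf("g%02d", 1:10), scaffold = "chrA",
                      start = (0:9) * 1e6 + 1, end = (0:9) * 1e6 + 5e5,
                      strand = "+", stringsAsFactors = FALSE)
  iv2 <- data.frame(scaffold = "chrA", start = 2.2e6, end = 5.9e6)
  hit2 <- genes_in_intervals(ann10, iv2)
  manual <- ann10$id[ann10$end >= 2.2e6 & ann10$start <= 5.9e6]
  expect_equal(hit2$id, manual)
  expect_equal(length(hit2$id), 4)
  # unknown scaffold skipped with warning
  expect_warning(
    none <- genes_in_intervals(ann10, data.frame(scaffold = "chrZ",
                                                 start = 1, end = 100)),
    "skipping")
  expect_equal(nrow(none), 0)
})

test_that("GFF3 annotation loads into the overlap interface", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\ttest\tgene\t1000\t2000\t.\t+\t.\tID=geneA",
    "chrA\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chrA\ttest\tgene\t5000\t6000\t.\t-\t.\tID=geneB"), gff)
  ann <- read_gene_annotation(gff)
  expect_equal(ann$id, c("geneA", "geneB"))
  expect_equal(ann$start, c(1000, 5000))
  hit <- genes_in_intervals(ann, data.frame(scaffold = "chrA",
                                            start = 1500, end = 5200))
  expect_equal(hit$id, c("geneA", "geneB"))
})
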