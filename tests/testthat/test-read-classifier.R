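test_that("BED reads load with converted coordinates and score mismatches", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t122\tr1\t0\t+", bed)
  reads <- load_reads(bed, "bed")
  expect_equal(reads$start, 101L)
  expect_equal(reads$end, 122L)
  expect_equal(reads$length, 22L)
  expect_equal(reads$mismatches, 0L)
  expect_equal(reads$identity, 1)

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_warning(r0 <- load_reads(empty, "bed"), "empty")
  expect_equal(nrow(r0), 0)
})

test_that("TSV reads load with validation", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tmismatches\tsample",
               "chr1\t101\t122\t+\t1\ts1"), tsv)
  reads <- load_reads(tsv, "tsv")
  expect_equal(reads$length, 22L)
  expect_equal(reads$identity, 1 - 1 / 22)
  expect_equal(reads$sample, "s1")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart", "chr1\t5"), bad)
  expect_error(load_reads(bad, "tsv"), "lacks column")
})

test_that("SAM reads load primary mapped records only, with NM mismatches", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 101, 60, "22M", "*", 0, 0,
          paste(rep("A", 22), collapse = ""), "*", "NM:i:1", sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r3", 256, "chr1", 151, 60, "20M", "*", 0, 0, "*", "*",
          "NM:i:0", sep = "\t"),
    paste("r4", 16, "chr1", 201, 60, "10M5N10M", "*", 0, 0,
          paste(rep("C", 20), collapse = ""), "*", "NM:i:0", sep = "\t")
  ), sam)
  expect_message(reads <- load_reads(sam, "sam"), "dropped")
  expect_setequal(reads$read_id, c("r1", "r4"))
  r1 <- reads[reads$read_id == "r1", ]
  expect_equal(c(r1$start, r1$end, r1$mismatches), c(101L, 122L, 1L))
  r4 <- reads[reads$read_id == "r4", ]
  expect_equal(r4$end - r4$start + 1L, 25L)  # spliced span on the reference
  expect_equal(r4$strand, "-")
})

test_that("read filter enforces length, mismatch, and identity thresholds", {
  reads <- toy_reads("chr1",
                     start = c(101, 101, 101, 101, 101),
                     end = c(116, 117, 122, 122, 130),
                     mismatches = c(0L, 0L, 3L, 2L, 2L))
  kept <- filter_reads(reads)
  # len 16 out; len 17 in; 3 mm out; 2 mm in 22 nt -> identity 0.909 in;
  # 2 mm in 30 nt in
  expect_setequal(kept$read_id, c("r2", "r4", "r5"))

  # identity can reject even when the mismatch cap is met: 2 mm in 17 nt
  tight <- toy_reads("chr1", 101, 117, mismatches = 2L)
  expect_equal(nrow(filter_reads(tight)), 0)
})

test_that("read filter equals its predicate and is monotone in min_length", {
  set.seed(7)
  n <- 400
  reads <- toy_reads("chr1", start = rep(1000L, n),
                     end = 1000L + sample(10:35, n, TRUE),
                     mismatches = sample(0:4, n, TRUE))
  kept <- filter_reads(reads)
  manual <- reads[reads$length >= 17 & reads$mismatches <= 2 &
                    (1 - reads$mismatches / reads$length) >= 0.9, ]
  expect_equal(kept$read_id, manual$read_id)

  n_kept <- vapply(15:30, function(ml)
    nrow(filter_reads(reads, min_length = ml)), integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("containment, border-crossing, and strand rules drive assignment", {
  hp <- toy_hairpin(len = 80)  # chr1:1001-1080, +
  mt <- rbind(toy_mature(hp, "5p", 6L, 27L), toy_mature(hp, "3p", 52L, 73L))
  maps <- list(build_segment_map(hp, mt))

  # local [9,25] inside mature_5p
  inside <- toy_reads("chr1", 1009, 1025)
  expect_equal(assign_reads(inside, maps)$category, "mature_5p")

  # local [21,40] crosses the mature_5p/loop border
  crossing <- toy_reads("chr1", 1021, 1040)
  expect_equal(assign_reads(crossing, maps)$category, "overlap")

  # fully outside every window
  away <- toy_reads("chr1", 5000, 5020)
  expect_equal(assign_reads(away, maps)$category, "unassigned")

  # one end outside the window -> not assignable
  poking <- toy_reads("chr1", 940, 960)
  expect_equal(assign_reads(poking, maps)$category, "unassigned")

  # antisense read: unassigned under "same", assigned under "both"
  anti <- toy_reads("chr1", 1009, 1025, strand = "-")
  expect_equal(assign_reads(anti, maps)$category, "unassigned")
  expect_equal(assign_reads(anti, maps, strand_mode = "both")$category,
               "mature_5p")
})

test_that("multi-window reads resolve to the nearest window midpoint", {
  hp1 <- toy_hairpin("hp-a", start = 1001L, len = 80L)
  hp2 <- toy_hairpin("hp-b", start = 1121L, len = 80L)
  mt <- rbind(toy_mature(hp1, "5p", 6L, 27L), toy_mature(hp2, "5p", 6L, 27L))
  maps <- list(build_segment_map(hp1, mt), build_segment_map(hp2, mt))
  # windows: [951,1130] and [1071,1250], midpoints 1040.5 and 1160.5

  r <- toy_reads("chr1", 1075, 1095)  # midpoint 1085 -> hp-a
  expect_equal(assign_reads(r, maps)$hairpin_id, "hp-a")

  tie <- toy_reads("chr1", 1091, 1110)  # midpoint 1100.5, equidistant
  expect_message(call <- assign_reads(tie, maps), "tied")
  expect_equal(call$hairpin_id, "hp-a")  # lexicographically smallest
})

test_that("classifier equals the position-wise oracle on synthetic reads", {
  spec <- simulation_spec(n_mirnas = 15, single_arm_fraction = 0.5,
                          mean_reads_per_mirna = 100)
  fx <- make_annotation_fixture(spec, seed = 5)
  maps <- build_segment_maps(list(hairpins = fx$hairpins,
                                  matures = fx$matures))
  sim <- suppressMessages(
    simulate_reads(spec, fx, "s1", "MCF10A", seed = 21))
  calls <- assign_reads(sim$reads, maps)
  want <- oracle_classify(sim$reads, maps)
  expect_equal(calls$category, want$category)
  expect_equal(calls$hairpin_id, want$hairpin_id)
  # and the generator's intended category is recovered
  expect_equal(calls$category, sim$truth$category)
})

test_that("assignment is deterministic", {
  spec <- simulation_spec(n_mirnas = 8)
  fx <- make_annotation_fixture(spec, seed = 2)
  maps <- build_segment_maps(list(hairpins = fx$hairpins,
                                  matures = fx$matures))
  sim <- suppressMessages(simulate_reads(spec, fx, "s1", "MCF7", seed = 3))
  a <- assign_reads(sim$reads, maps)
  b <- assign_reads(sim$reads, maps)
  expect_identical(a, b)
})

test_that("segment partitions count, normalise, and sum to one", {
  calls <- data.frame(
    read_id = paste0("r", 1:10), hairpin_id = "mir-x",
    category = rep("mature_5p", 10), stringsAsFactors = FALSE
  )
  part <- segment_partition(calls, by = "miRNA")
  expect_equal(part$frac_mature_5p, 1)
  expect_equal(part$n_total, 10)

  # two miRNAs with opposite compositions: every row still sums to 1
  calls2 <- rbind(
    data.frame(read_id = paste0("a", 1:8), hairpin_id = "mir-a",
               category = rep(c("mature_5p", "extension"), c(6, 2))),
    data.frame(read_id = paste0("b", 1:8), hairpin_id = "mir-b",
               category = rep(c("extension", "overlap"), c(5, 3)))
  )
  part2 <- segment_partition(calls2, by = "miRNA")
  fr <- as.matrix(part2[, grep("^frac_", names(part2))])
  expect_equal(unname(rowSums(fr)), c(1, 1), tolerance = 1e-12)

  # unassigned calls are dropped with a message
  calls3 <- rbind(calls, data.frame(read_id = "rx", hairpin_id = NA,
                                    category = "unassigned"))
  expect_message(part3 <- segment_partition(calls3, by = "miRNA"),
                 "unassigned")
  expect_equal(part3$n_total, 10)
})

test_that("sample-level composition reports pooled and per-miRNA views", {
  calls <- rbind(
    data.frame(read_id = paste0("a", 1:90), hairpin_id = "mir-a",
               category = "mature_5p", sample = "s1"),
    data.frame(read_id = paste0("b", 1:10), hairpin_id = "mir-b",
               category = "extension", sample = "s1")
  )
  part <- segment_partition(calls, by = "sample")
  # pooled: 90/100 mature; equal-weight mean over the two miRNAs: 0.5
  expect_equal(part$pooled$frac_mature_5p, 0.9)
  expect_equal(part$mean_mirna$frac_mature_5p, 0.5)
})

test_that("planted mixtures are recovered within 3 percentage points", {
  spec <- simulation_spec(
    n_mirnas = 6, single_arm_fraction = 0,
    mean_reads_per_mirna = 2000, abundance_sdlog = 0,
    mixture = c(mature_5p = 0.6, mature_3p = 0, undefined_complement = 0,
                extension = 0.15, overlap = 0.25)
  )
  fx <- make_annotation_fixture(spec, seed = 8)
  maps <- build_segment_maps(list(hairpins = fx$hairpins,
                                  matures = fx$matures))
  sim <- suppressMessages(simulate_reads(spec, fx, "s1", "MCF10A", seed = 9))
  calls <- assign_reads(sim$reads, maps)
  part <- segment_partition(calls, by = "miRNA")
  expect_true(all(abs(part$frac_mature_5p - 0.60) <= 0.03))
  expect_true(all(abs(part$frac_extension - 0.15) <= 0.03))
  expect_true(all(abs(part$frac_overlap - 0.25) <= 0.03))
})
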