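test_that("GFF3 parsing resolves hairpins, matures, and arms", {
  gff <- write_gff_lines(c(
    "chr1\t.\tmiRNA_primary_transcript\t1001\t1080\t.\t+\t.\tID=MI1;Name=hp-1",
    "chr1\t.\tmiRNA\t1005\t1026\t.\t+\t.\tID=MT1;Name=hp-1-5p;Derives_from=MI1"
  ))
  ann <- read_hairpin_annotations(gff)
  expect_equal(nrow(ann$hairpins), 1)
  expect_equal(ann$hairpins$length, 80L)
  expect_equal(nrow(ann$matures), 1)
  expect_equal(ann$matures$arm, "5p")

  # mature on the 3' half -> 3p by the midpoint rule
  gff3p <- write_gff_lines(c(
    "chr1\t.\tmiRNA_primary_transcript\t1001\t1080\t.\t+\t.\tID=MI1;Name=hp-1",
    "chr1\t.\tmiRNA\t1055\t1076\t.\t+\t.\tID=MT1;Name=hp-1-3p;Derives_from=MI1"
  ))
  expect_equal(read_hairpin_annotations(gff3p)$matures$arm, "3p")

  # minus-strand hairpin: genomic left end is the 3' side
  gffm <- write_gff_lines(c(
    "chr1\t.\tmiRNA_primary_transcript\t1001\t1080\t.\t-\t.\tID=MI1;Name=hp-1",
    "chr1\t.\tmiRNA\t1005\t1026\t.\t-\t.\tID=MT1;Name=hp-1-x;Derives_from=MI1"
  ))
  expect_equal(read_hairpin_annotations(gffm)$matures$arm, "3p")
})

test_that("GFF3 parsing rejects bad matures and warns on unknown parents", {
  orphan <- write_gff_lines(c(
    "chr1\t.\tmiRNA_primary_transcript\t1001\t1080\t.\t+\t.\tID=MI1;Name=hp-1",
    "chr1\t.\tmiRNA\t1005\t1026\t.\t+\t.\tID=MT1;Name=m1;Derives_from=NOPE"
  ))
  expect_warning(ann <- read_hairpin_annotations(orphan), "unknown parent")
  expect_equal(nrow(ann$matures), 0)

  outside <- write_gff_lines(c(
    "chr1\t.\tmiRNA_primary_transcript\t1001\t1080\t.\t+\t.\tID=MI1;Name=hp-1",
    "chr1\t.\tmiRNA\t995\t1016\t.\t+\t.\tID=MT1;Name=m1;Derives_from=MI1"
  ))
  expect_error(read_hairpin_annotations(outside), "outside parent")
})

test_that("fixture GFF round-trips with arms matching the generator truth", {
  spec <- simulation_spec(n_mirnas = 20)
  fx <- make_annotation_fixture(spec, seed = 42)
  gff <- tempfile(fileext = ".gff3")
  write_annotation_gff3(fx, gff)
  ann <- read_hairpin_annotations(gff)
  expect_equal(nrow(ann$hairpins), 20)
  expect_equal(nrow(ann$matures), nrow(fx$matures))
  expect_equal(sort(ann$hairpins$hairpin_id),
               sort(fx$hairpins$hairpin_id))
  expect_equal(unname(fx$truth$arms[ann$matures$mature_id]),
               ann$matures$arm)
})

test_that("single-mature hairpins get a mirrored undefined complement", {
  hp <- toy_hairpin(len = 80)
  mt <- toy_mature(hp, "5p", 6L, 27L)
  map <- build_segment_map(hp, mt)
  comp <- map[map$label == "undefined_complement", ]
  # mirror rule: [L-e+1+2, L-s+1+2] = [56, 77], same length as the mature
  expect_equal(c(comp$local_start, comp$local_end), c(56L, 77L))
  expect_equal(comp$local_end - comp$local_start, 27L - 6L)

  # mirroring the complement recovers the mature exactly (involution)
  L <- 80L; ov <- 2L
  expect_equal(L - comp$local_end + 1L + ov, 6L)
  expect_equal(L - comp$local_start + 1L + ov, 27L)
})

test_that("two-arm hairpins have no undefined complement", {
  hp <- toy_hairpin(len = 80)
  mt <- rbind(toy_mature(hp, "5p", 6L, 27L), toy_mature(hp, "3p", 52L, 73L))
  map <- build_segment_map(hp, mt)
  expect_false("undefined_complement" %in% map$label)
  expect_setequal(unique(map$label),
                  c("mature_5p", "mature_3p", "extension"))
})

test_that("segment map construction handles edge cases", {
  hp <- toy_hairpin(len = 80)
  expect_error(build_segment_map(hp, toy_mature(hp, "5p", 6L, 27L)[0, ]),
               "no annotated mature")

  # complement clipped to the hairpin and truncated away from the mature
  hp2 <- toy_hairpin(id = "hp-b", len = 40)
  mt2 <- toy_mature(hp2, "5p", 1L, 22L)
  expect_warning(map2 <- build_segment_map(hp2, mt2), "truncated")
  comp2 <- map2[map2$label == "undefined_complement", ]
  expect_equal(c(comp2$local_start, comp2$local_end), c(23L, 40L))
})

test_that("segment maps partition the window exactly (position-wise)", {
  for (seed in c(1, 2, 3, 4)) {
    spec <- simulation_spec(n_mirnas = 25, single_arm_fraction = 0.5)
    fx <- make_annotation_fixture(spec, seed = seed)
    maps <- build_segment_maps(list(hairpins = fx$hairpins,
                                    matures = fx$matures))
    for (m in maps) {
      L <- fx$hairpins$length[fx$hairpins$hairpin_id == m$hairpin_id[1]]
      cover <- integer(L + 100L)
      for (i in seq_len(nrow(m))) {
        idx <- (m$local_start[i]:m$local_end[i]) + 50L
        cover[idx] <- cover[idx] + 1L
      }
      expect_true(all(cover == 1L))
    }
  }
})

test_that("segment map genomic coordinates respect strand", {
  hp <- toy_hairpin(len = 80, strand = "-")
  mt <- toy_mature(hp, "5p", 6L, 27L)
  map <- build_segment_map(hp, mt)
  m5 <- map[map$label == "mature_5p", ]
  # 5p on a minus-strand hairpin sits at the genomic right end
  expect_equal(m5$end, hp$end - 6L + 1L)
  expect_equal(m5$start, hp$end - 27L + 1L)
  expect_true(all(map$start <= map$end))
})

test_that("cluster neighbours obey the strict 10 kb boundary", {
  base <- rbind(toy_hairpin("mir-x", start = 1000L, len = 101L),
                toy_hairpin("mir-y", start = 12100L, len = 100L))
  # gap = 12100 - 1100 - 1 = 10999 -> no pair at 10k, pair at 11k+
  expect_equal(nrow(find_cluster_neighbors(base)), 0)

  near <- base; near$start[2] <- 11100L; near$end[2] <- 11199L
  # gap = 11100 - 1100 - 1 = 9999 -> exactly one pair
  pairs <- find_cluster_neighbors(near)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$distance, 9999L)

  at_bound <- base; at_bound$start[2] <- 11101L; at_bound$end[2] <- 11200L
  expect_equal(nrow(find_cluster_neighbors(at_bound)), 0)
})

test_that("a planted three-member cluster yields all three pairs", {
  hp <- rbind(toy_hairpin("mir-a", start = 1L, len = 100L),
              toy_hairpin("mir-b", start = 1201L, len = 100L),
              toy_hairpin("mir-c", start = 2401L, len = 100L))
  pairs <- find_cluster_neighbors(hp)
  expect_equal(nrow(pairs), 3)
  expect_setequal(paste(pairs$mirna_a, pairs$mirna_b),
                  c("mir-a mir-b", "mir-a mir-c", "mir-b mir-c"))
})

test_that("cluster neighbours equal the all-pairs oracle on random layouts", {
  set.seed(99)
  for (rep in 1:3) {
    n <- 80
    hp <- data.frame(
      hairpin_id = sprintf("m%03d", sample(n)),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(4e5, n),
      strand = "+",
      stringsAsFactors = FALSE
    )
    hp$end <- hp$start + sample(60:110, n, replace = TRUE)
    hp$length <- hp$end - hp$start + 1L
    got <- find_cluster_neighbors(hp)
    want <- oracle_cluster_pairs(hp)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("empty input yields an empty cluster table", {
  expect_equal(nrow(find_cluster_neighbors(toy_hairpin()[0, ])), 0)
})

test_that("segment map export writes local TSV and genomic BED", {
  hp <- toy_hairpin(len = 80)
  mt <- rbind(toy_mature(hp, "5p", 6L, 27L), toy_mature(hp, "3p", 52L, 73L))
  maps <- list(build_segment_map(hp, mt))
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  export_segment_maps(maps, tsv, bed)
  tab <- read.delim(tsv)
  expect_equal(names(tab),
               c("hairpin_id", "label", "local_start", "local_end"))
  reimported <- rtracklayer::import(bed)
  expect_equal(length(reimported), nrow(tab))
  expect_equal(min(GenomicRanges::start(reimported)), hp$start - 50L)
})
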