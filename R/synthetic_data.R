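# Synthetic data with ground truth: annotation fixtures, segmental read
# mixtures, and replicated negative-binomial count matrices emulating a
# three-cell-line, three-replicate spliceosome-fraction study design.

#' Specification for the synthetic-data generator
#'
#' Collects every tunable of the generator with defaults emulating the
#' study design the package targets: three cell-line groups in biological
#' triplicate, per-miRNA segmental read mixtures, log-normal baseline
#' abundances with planted fold changes, and negative-binomial replicate
#' noise.
#'
#' @param n_mirnas Number of synthetic miRNA precursors (default 24).
#' @param chrom,chrom_length Toy chromosome name and length.
#' @param hairpin_length Range (min, max) of precursor lengths in nt
#'   (default 60--110).
#' @param mature_length Range of mature product lengths in nt
#'   (default 20--23).
#' @param single_arm_fraction Fraction of precursors with only one
#'   annotated mature arm, exercising the undefined complement
#'   (default 0.4).
#' @param cluster_fraction Fraction of precursors placed as planted
#'   genomic cluster partners, i.e. within `cluster_gap` of a neighbour
#'   (default 0.25).
#' @param cluster_gap,isolated_gap Ranges (nt) for the gap to the previous
#'   precursor for clustered and non-clustered placements; `isolated_gap`
#'   must stay at or above 10000 so only planted pairs are neighbours.
#' @param groups Group (cell line) names; the first is the reference.
#' @param n_replicates Biological replicates per group (default 3).
#' @param mean_reads_per_mirna Median of the log-normal per-miRNA baseline
#'   abundance, in reads per sample (default 200).
#' @param abundance_sdlog Log-normal spread of baseline abundances
#'   (default 1; 0 makes all miRNAs equally abundant).
#' @param dispersion Negative-binomial size parameter; counts are drawn
#'   as `rnbinom(mu, size = dispersion)` so smaller values mean noisier
#'   replicates (default 10).
#' @param read_length Range of simulated read lengths in nt, truncated to
#'   the containing segment (default 17--30).
#' @param mixture Named probabilities over the five read categories
#'   (`mature_5p`, `mature_3p`, `undefined_complement`, `extension`,
#'   `overlap`); must sum to 1. Categories infeasible for a given
#'   precursor are renormalised away at simulation time.
#' @param decoy_fraction Fraction of additional decoy reads (sub-17-nt or
#'   high-mismatch) added to exercise the read filter (default 0).
#' @param trend_probs Probabilities that a non-reference group's planted
#'   fold change is Up, Down, or Same for a given miRNA
#'   (default 0.3/0.5/0.2, mirroring a decrease-dominated design).
#' @param lfc_range Magnitude range of planted |log2 fold changes| for
#'   Up/Down miRNAs (default 1--3).
#' @param extension_flank,overhang Segment-map geometry (see
#'   [build_segment_map()]).
#' @param seed Default seed used when an operation is not given one.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_mirnas = 24L,
                            chrom = "chrS",
                            chrom_length = 5e6,
                            hairpin_length = c(60L, 110L),
                            mature_length = c(20L, 23L),
                            single_arm_fraction = 0.4,
                            cluster_fraction = 0.25,
                            cluster_gap = c(200L, 5000L),
                            isolated_gap = c(15000L, 40000L),
                            groups = c("MCF10A", "MCF7", "MDA"),
                            n_replicates = 3L,
                            mean_reads_per_mirna = 200,
                            abundance_sdlog = 1,
                            dispersion = 10,
                            read_length = c(17L, 30L),
                            mixture = c(mature_5p = 0.45, mature_3p = 0.15,
                                        undefined_complement = 0.05,
                                        extension = 0.12, overlap = 0.23),
                            decoy_fraction = 0,
                            trend_probs = c(U = 0.3, D = 0.5, S = 0.2),
                            lfc_range = c(1, 3),
                            extension_flank = 50L,
                            overhang = 2L,
                            seed = 7L) {
  spec <- list(
    n_mirnas = as.integer(n_mirnas), chrom = chrom,
    chrom_length = chrom_length,
    hairpin_length = as.integer(hairpin_length),
    mature_length = as.integer(mature_length),
    single_arm_fraction = single_arm_fraction,
    cluster_fraction = cluster_fraction,
    cluster_gap = as.integer(cluster_gap),
    isolated_gap = as.integer(isolated_gap),
    groups = groups, n_replicates = as.integer(n_replicates),
    mean_reads_per_mirna = mean_reads_per_mirna,
    abundance_sdlog = abundance_sdlog,
    dispersion = dispersion,
    read_length = as.integer(read_length),
    mixture = mixture, decoy_fraction = decoy_fraction,
    trend_probs = trend_probs, lfc_range = lfc_range,
    extension_flank = as.integer(extension_flank),
    overhang = as.integer(overhang),
    seed = as.integer(seed)
  )
  stopifnot(
    spec$n_mirnas > 0,
    length(spec$groups) >= 2,
    spec$n_replicates >= 1,
    abs(sum(spec$mixture) - 1) < 1e-8,
    all(names(spec$mixture) %in% setdiff(READ_CATEGORIES, "unassigned")),
    spec$isolated_gap[1] >= 10000L,
    spec$read_length[1] >= 1L,
    spec$decoy_fraction >= 0, spec$decoy_fraction < 1,
    abs(sum(spec$trend_probs) - 1) < 1e-8
  )
  class(spec) <- "simulation_spec"
  spec
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

runif_int <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate an annotation fixture with ground truth
#'
#' Places non-overlapping synthetic precursors along a toy chromosome. A
#' configurable fraction is laid out as planted cluster pairs (gap below
#' 10 kb); all remaining gaps are at least 10 kb, so the planted pairs are
#' exactly the expected output of [find_cluster_neighbors()]. Matures sit
#' near the precursor termini; a configurable fraction of precursors has a
#' single annotated arm. Baseline abundances and per-group fold changes
#' are planted at the same time so downstream read and count simulations
#' share one truth.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (defaults to `spec$seed`); identical
#'   `(spec, seed)` give identical fixtures.
#' @return A list of class `sf_fixture` with elements `hairpins` and
#'   `matures` (same shape as [read_hairpin_annotations()]) and `truth`,
#'   a list with `arms` (named vector per mature), `single_arm`
#'   (hairpin ids), `cluster_pairs` (data frame `mirna_a`, `mirna_b`,
#'   `distance`), `base_mean` (named per-miRNA baseline), `fold_change`
#'   (miRNA-by-group matrix, reference column 1), and `trend`
#'   (miRNA-by-group character matrix of planted U/D/S labels relative to
#'   the reference, derived from the fold changes with the 20% band).
#' @export
make_annotation_fixture <- function(spec, seed = spec$seed) {
  local_seed(seed, {
    n <- spec$n_mirnas
    ids <- sprintf("syn-mir-%03d", seq_len(n))
    len <- runif_int(n, spec$hairpin_length)

    # block layout: planted cluster pairs, then singletons, shuffled
    n_pairs <- floor(round(spec$cluster_fraction * n) / 2)
    pair_members <- if (n_pairs > 0) seq_len(2 * n_pairs) else integer()
    blocks <- c(rep(seq_len(n_pairs), each = 2),
                seq(n_pairs + 1, length.out = n - 2 * n_pairs))
    ord <- unlist(split(seq_len(n), blocks)[
      as.character(sample(unique(blocks)))], use.names = FALSE)
    # ord is a permutation: position along chromosome -> miRNA index
    in_pair <- seq_len(n) %in% pair_members
    start <- integer(n)
    pos <- 1L
    prev_idx <- 0L
    for (k in seq_len(n)) {
      i <- ord[k]
      gap <- if (k == 1) {
        runif_int(1, spec$isolated_gap)
      } else if (in_pair[i] && in_pair[prev_idx] &&
                 blocks[i] == blocks[prev_idx]) {
        runif_int(1, spec$cluster_gap)
      } else {
        runif_int(1, spec$isolated_gap)
      }
      pos <- pos + gap
      start[i] <- pos
      pos <- pos + len[i]
      prev_idx <- i
    }
    if (pos > spec$chrom_length) {
      stop("chromosome too short for ", n, " precursors (need ", pos,
           " > ", spec$chrom_length, " nt)")
    }
    hairpins <- data.frame(
      hairpin_id = ids, chrom = spec$chrom,
      start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      length = len,
      stringsAsFactors = FALSE
    )

    # mature placement near the termini
    n_single <- round(spec$single_arm_fraction * n)
    single <- sample(ids, n_single)
    mat <- list()
    arms <- list()
    for (i in seq_len(n)) {
      hp <- hairpins[i, ]
      which_arms <- if (ids[i] %in% single) {
        sample(c("5p", "3p"), 1)
      } else {
        c("5p", "3p")
      }
      for (arm in which_arms) {
        ml <- runif_int(1, spec$mature_length)
        off <- sample(0:3, 1)
        loc <- if (arm == "5p") c(1L + off, off + ml) else
          c(hp$length - ml + 1L - off, hp$length - off)
        gen <- local_to_genomic(loc[1], loc[2], hp)
        mat[[length(mat) + 1]] <- data.frame(
          mature_id = paste0(sub("mir", "miR", ids[i]), "-", arm),
          hairpin_id = ids[i], chrom = hp$chrom,
          start = gen$start, end = gen$end, strand = hp$strand,
          arm = arm, local_start = loc[1], local_end = loc[2],
          stringsAsFactors = FALSE
        )
      }
    }
    matures <- do.call(rbind, mat)

    # planted cluster pairs with their realised distances
    cluster_pairs <- if (n_pairs > 0) {
      do.call(rbind, lapply(seq_len(n_pairs), function(p) {
        m <- which(blocks == p)
        a <- ids[m[1]]; b <- ids[m[2]]
        left <- m[which.min(start[m])]
        right <- m[which.max(start[m])]
        d <- start[right] - (start[left] + len[left] - 1L) - 1L
        data.frame(
          mirna_a = min(a, b), mirna_b = max(a, b),
          distance = as.integer(d), stringsAsFactors = FALSE
        )
      }))
    } else {
      data.frame(mirna_a = character(), mirna_b = character(),
                 distance = integer(), stringsAsFactors = FALSE)
    }

    # abundance truth shared by the read and count simulators
    base_mean <- stats::setNames(
      stats::rlnorm(n, meanlog = log(spec$mean_reads_per_mirna),
                    sdlog = spec$abundance_sdlog), ids)
    fc <- matrix(1, nrow = n, ncol = length(spec$groups),
                 dimnames = list(ids, spec$groups))
    for (g in spec$groups[-1]) {
      cls <- sample(names(spec$trend_probs), n, replace = TRUE,
                    prob = spec$trend_probs)
      mag <- 2^stats::runif(n, spec$lfc_range[1], spec$lfc_range[2])
      fc[, g] <- ifelse(cls == "U", mag, ifelse(cls == "D", 1 / mag, 1))
    }
    trend <- matrix("S", nrow = n, ncol = length(spec$groups),
                    dimnames = list(ids, spec$groups))
    trend[fc > 1.2] <- "U"
    trend[fc < 0.8] <- "D"

    structure(
      list(
        hairpins = hairpins,
        matures = matures[, c("mature_id", "hairpin_id", "chrom", "start",
                              "end", "strand", "arm")],
        matures_local = matures,
        truth = list(
          arms = stats::setNames(matures$arm, matures$mature_id),
          single_arm = sort(single),
          cluster_pairs = cluster_pairs[
            order(cluster_pairs$mirna_a, cluster_pairs$mirna_b), ,
            drop = FALSE],
          base_mean = base_mean,
          fold_change = fc,
          trend = trend[, -1, drop = FALSE]
        ),
        spec = spec, seed = seed
      ),
      class = "sf_fixture"
    )
  })
}

#' Write a fixture (or parsed annotation) as miRBase-dialect GFF3
#'
#' Hairpins become `miRNA_primary_transcript` features and matures
#' `miRNA` features whose `Derives_from` references the precursor ID.
#'
#' @param annotation An `sf_fixture` or a list with `hairpins`/`matures`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  hp <- annotation$hairpins
  mt <- annotation$matures
  hp_uid <- sprintf("SYNMI%04d", seq_len(nrow(hp)))
  names(hp_uid) <- hp$hairpin_id
  gr_hp <- GenomicRanges::GRanges(
    hp$chrom, IRanges::IRanges(hp$start, hp$end), strand = hp$strand,
    type = "miRNA_primary_transcript",
    ID = unname(hp_uid), Name = hp$hairpin_id
  )
  gr_mt <- GenomicRanges::GRanges(
    mt$chrom, IRanges::IRanges(mt$start, mt$end), strand = mt$strand,
    type = "miRNA",
    ID = sprintf("SYNMIMAT%04d", seq_len(nrow(mt))),
    Name = mt$mature_id,
    Derives_from = unname(hp_uid[mt$hairpin_id])
  )
  gr <- c(gr_hp, gr_mt)
  gr$source <- "spliceomiR"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Sample sheet implied by a simulation spec
#'
#' @param spec A [simulation_spec()].
#' @return Data frame with `sample_id` (`<group>_r<replicate>`), `group`,
#'   `replicate`.
#' @export
simulated_sample_sheet <- function(spec) {
  data.frame(
    sample_id = paste0(rep(spec$groups, each = spec$n_replicates), "_r",
                       rep(seq_len(spec$n_replicates),
                           length(spec$groups))),
    group = rep(spec$groups, each = spec$n_replicates),
    replicate = rep(seq_len(spec$n_replicates), length(spec$groups)),
    stringsAsFactors = FALSE
  )
}

# Labelled (non-extension) segments of one fixture hairpin, local coords,
# computed from the planted mature positions and the duplex mirror rule.
fixture_labelled_segments <- function(fixture, hairpin_id) {
  spec <- fixture$spec
  hp <- fixture$hairpins[fixture$hairpins$hairpin_id == hairpin_id, ]
  mt <- fixture$matures_local[
    fixture$matures_local$hairpin_id == hairpin_id, , drop = FALSE]
  segs <- data.frame(
    label = paste0("mature_", mt$arm),
    start = mt$local_start, end = mt$local_end,
    stringsAsFactors = FALSE
  )
  if (nrow(mt) == 1) {
    L <- hp$length
    cs <- max(L - mt$local_end + 1L + spec$overhang, 1L)
    ce <- min(L - mt$local_start + 1L + spec$overhang, L)
    if (cs <= mt$local_end && ce >= mt$local_start) {
      if (mt$arm == "5p") cs <- max(cs, mt$local_end + 1L)
      else ce <- min(ce, mt$local_start - 1L)
    }
    if (cs <= ce) {
      segs <- rbind(segs, data.frame(label = "undefined_complement",
                                     start = cs, end = ce,
                                     stringsAsFactors = FALSE))
    }
  }
  segs[order(segs$start), , drop = FALSE]
}

#' Simulate aligned reads for one sample
#'
#' Per-miRNA read counts are drawn negative-binomially around the planted
#' group mean (`base_mean * fold_change[group]`, size = `dispersion`).
#' Each read's segmental category is drawn from the spec's mixture,
#' renormalised over the categories feasible for its precursor (a message
#' reports when renormalisation occurred), and its coordinates are placed
#' to realise the category exactly: contained in the segment, or, for
#' `overlap`, straddling the downstream border of a mature segment by at
#' least 2 nt on each side. Optional decoy reads (sub-17-nt, or with 3--5
#' mismatches) exercise the read filter and are flagged in the truth.
#'
#' @param spec A [simulation_spec()].
#' @param fixture Fixture from [make_annotation_fixture()].
#' @param sample_id Sample identifier attached to the reads.
#' @param group Group (cell line) of the sample; must be one of
#'   `spec$groups`.
#' @param seed Integer seed.
#' @return A list with `reads` (a read table as from [load_reads()], with
#'   a `sample` column) and `truth` (per read: `read_id`, `hairpin_id`,
#'   `category`, `decoy`).
#' @export
simulate_reads <- function(spec, fixture, sample_id, group,
                           seed = spec$seed) {
  stopifnot(group %in% spec$groups)
  local_seed(seed, {
    ids <- fixture$hairpins$hairpin_id
    mu <- fixture$truth$base_mean *
      fixture$truth$fold_change[, group]
    counts <- stats::rnbinom(length(ids), mu = mu, size = spec$dispersion)
    names(counts) <- ids

    all_reads <- list()
    all_truth <- list()
    renormalised <- character()
    for (i in seq_along(ids)) {
      n_i <- counts[i]
      if (n_i == 0) next
      hp <- fixture$hairpins[i, ]
      segs <- fixture_labelled_segments(fixture, ids[i])
      feasible <- c(
        segs$label,
        "extension",
        if (any(grepl("mature", segs$label))) "overlap"
      )
      mix <- spec$mixture[names(spec$mixture) %in% feasible]
      if (length(mix) < length(spec$mixture)) {
        renormalised <- c(renormalised, ids[i])
      }
      if (sum(mix) == 0) {  # all mass on infeasible categories
        mix[] <- 1
      }
      mix <- mix / sum(mix)
      cat_i <- sample(names(mix), n_i, replace = TRUE, prob = mix)
      len_i <- runif_int(n_i, spec$read_length)
      place <- place_reads_local(cat_i, len_i, segs, hp$length,
                                 spec$extension_flank)
      gen_s <- integer(n_i); gen_e <- integer(n_i)
      for (r in seq_len(n_i)) {
        g <- local_to_genomic(place$start[r], place$end[r], hp)
        gen_s[r] <- g$start; gen_e[r] <- g$end
      }
      all_reads[[length(all_reads) + 1]] <- data.frame(
        chrom = hp$chrom, start = gen_s, end = gen_e,
        strand = hp$strand, mismatches = 0L,
        stringsAsFactors = FALSE
      )
      all_truth[[length(all_truth) + 1]] <- data.frame(
        hairpin_id = ids[i], category = cat_i, decoy = FALSE,
        stringsAsFactors = FALSE
      )
    }
    if (length(renormalised) > 0) {
      message("mixture renormalised for ", length(renormalised),
              " precursor(s) with infeasible categories")
    }
    reads <- if (length(all_reads) > 0) do.call(rbind, all_reads) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), mismatches = integer(),
                 stringsAsFactors = FALSE)
    truth <- if (length(all_truth) > 0) do.call(rbind, all_truth) else
      data.frame(hairpin_id = character(), category = character(),
                 decoy = logical(), stringsAsFactors = FALSE)

    # decoy reads: half too short, half with too many mismatches
    n_decoy <- round(spec$decoy_fraction * nrow(reads))
    if (n_decoy > 0) {
      di <- sample(nrow(reads), n_decoy, replace = TRUE)
      short <- seq_len(n_decoy) <= n_decoy / 2
      dlen <- ifelse(short, runif_int(n_decoy, c(10L, 16L)),
                     runif_int(n_decoy, c(20L, 25L)))
      dmm <- ifelse(short, 0L, runif_int(n_decoy, c(3L, 5L)))
      dstart <- reads$start[di]
      decoys <- data.frame(
        chrom = reads$chrom[di], start = dstart,
        end = dstart + dlen - 1L, strand = reads$strand[di],
        mismatches = as.integer(dmm), stringsAsFactors = FALSE
      )
      reads <- rbind(reads, decoys)
      truth <- rbind(truth, data.frame(
        hairpin_id = truth$hairpin_id[di], category = "decoy",
        decoy = TRUE, stringsAsFactors = FALSE
      ))
    }

    reads$read_id <- if (nrow(reads) > 0) {
      paste0(sample_id, "_read_", seq_len(nrow(reads)))
    } else {
      character()
    }
    truth$read_id <- reads$read_id
    reads$length <- as.integer(reads$end - reads$start + 1L)
    reads$identity <- if (nrow(reads) > 0) {
      1 - reads$mismatches / reads$length
    } else {
      numeric()
    }
    reads$sample <- if (nrow(reads) > 0) sample_id else character()
    reads <- reads[, c("read_id", "chrom", "start", "end", "strand",
                       "length", "mismatches", "identity", "sample")]
    truth <- truth[, c("read_id", "hairpin_id", "category", "decoy")]
    list(reads = reads, truth = truth)
  })
}

# Place reads in hairpin-local coordinates so each realises its category.
place_reads_local <- function(categories, lengths, segs, L, flank) {
  win_start <- 1L - flank
  win_end <- L + flank
  n <- length(categories)
  out_s <- integer(n)
  # extension runs = window minus labelled segments
  run_s <- c(win_start, segs$end + 1L)
  run_e <- c(segs$start - 1L, win_end)
  keep <- run_s <= run_e
  run_s <- run_s[keep]; run_e <- run_e[keep]
  # mature segment whose downstream border overlap reads straddle
  m_idx <- grep("mature", segs$label)[1]
  for (r in seq_len(n)) {
    cat_r <- categories[r]
    len_r <- lengths[r]
    if (cat_r == "overlap") {
      border <- segs$end[m_idx]
      len_r <- max(len_r, 4L)
      choices <- seq(2L, len_r - 2L)  # nt inside the mature segment
      a <- choices[sample.int(length(choices), 1)]
      a <- min(a, segs$end[m_idx] - segs$start[m_idx] + 1L)
      out_s[r] <- border - a + 1L
      lengths[r] <- len_r
    } else {
      if (cat_r == "extension") {
        fits <- which(run_e - run_s + 1L >= len_r)
        if (length(fits) == 0) {
          fits <- which.max(run_e - run_s)
          len_r <- run_e[fits] - run_s[fits] + 1L
        }
        pick <- fits[sample.int(length(fits), 1)]
        ss <- run_s[pick]; ee <- run_e[pick]
      } else {
        si <- which(segs$label == cat_r)[1]
        ss <- segs$start[si]; ee <- segs$end[si]
      }
      len_r <- min(len_r, ee - ss + 1L)
      out_s[r] <- ss + sample.int(ee - ss + 1L - len_r + 1L, 1) - 1L
      lengths[r] <- len_r
    }
  }
  list(start = out_s, end = out_s + lengths - 1L)
}

#' Write simulated reads as BED6
#'
#' Coordinates are converted to BED's 0-based half-open convention by
#' rtracklayer; the score column carries the mismatch count, matching the
#' convention of [load_reads()].
#'
#' @param reads Read table (e.g. from [simulate_reads()]).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start, reads$end),
    strand = reads$strand,
    name = reads$read_id, score = reads$mismatches
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Simulate a replicated count matrix with planted trends
#'
#' Draws a miRNA-by-sample matrix of negative-binomial counts for every
#' group and replicate in the spec, around planted per-group means
#' (`base_mean * fold_change`). The truth bundle reports the planted
#' fold changes, the implied U/D/S trend labels (20% stability band), and
#' the per-group presence truth of the realised matrix (group sum of at
#' least 10 reads).
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @param fixture Optional fixture from [make_annotation_fixture()]; when
#'   supplied, its planted abundance truth is reused, otherwise a
#'   standalone truth is drawn.
#' @return List with `counts` (integer matrix), `samples` (sample sheet),
#'   and `truth` (`base_mean`, `fold_change`, `trend`, `presence`).
#' @export
simulate_count_matrix <- function(spec, seed = spec$seed, fixture = NULL) {
  local_seed(seed, {
    if (is.null(fixture)) {
      ids <- sprintf("syn-mir-%03d", seq_len(spec$n_mirnas))
      base_mean <- stats::setNames(
        stats::rlnorm(spec$n_mirnas,
                      meanlog = log(spec$mean_reads_per_mirna),
                      sdlog = spec$abundance_sdlog), ids)
      fc <- matrix(1, nrow = spec$n_mirnas, ncol = length(spec$groups),
                   dimnames = list(ids, spec$groups))
      for (g in spec$groups[-1]) {
        cls <- sample(names(spec$trend_probs), spec$n_mirnas,
                      replace = TRUE, prob = spec$trend_probs)
        mag <- 2^stats::runif(spec$n_mirnas, spec$lfc_range[1],
                              spec$lfc_range[2])
        fc[, g] <- ifelse(cls == "U", mag,
                          ifelse(cls == "D", 1 / mag, 1))
      }
    } else {
      ids <- fixture$hairpins$hairpin_id
      base_mean <- fixture$truth$base_mean
      fc <- fixture$truth$fold_change
    }
    trend <- matrix("S", nrow = length(ids),
                    ncol = ncol(fc) - 1,
                    dimnames = list(ids, colnames(fc)[-1]))
    trend[fc[, -1, drop = FALSE] > 1.2] <- "U"
    trend[fc[, -1, drop = FALSE] < 0.8] <- "D"

    samples <- simulated_sample_sheet(spec)
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      as.integer(stats::rnbinom(length(ids),
                                mu = base_mean * fc[, samples$group[j]],
                                size = spec$dispersion))
    }, integer(length(ids)))
    dimnames(counts) <- list(ids, samples$sample_id)
    attr(counts, "normalized") <- FALSE

    grp <- samples$group[match(colnames(counts), samples$sample_id)]
    presence <- vapply(spec$groups, function(g) {
      rowSums(counts[, grp == g, drop = FALSE]) >= 10
    }, logical(length(ids)))

    list(
      counts = counts, samples = samples,
      truth = list(base_mean = base_mean, fold_change = fc,
                   trend = trend, presence = presence)
    )
  })
}
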