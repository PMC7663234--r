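# End-to-end orchestration: annotate -> classify -> quantify -> compare,
# with reproducible outputs and a JSON run summary.

#' Assemble a pipeline run configuration
#'
#' Thresholds default to the values the analysis is built around: read
#' length >= 17 nt, at most 2 mismatches, 90% identity, presence at >= 10
#' reads per cell-line group, a 20% trend stability band, adjusted
#' p < 0.05, cluster neighbours below 10 kb, 50-nt extension flanks, and
#' a strict joint-expression floor of 50 reads.
#'
#' @param gff Path to the miRBase-style GFF3 annotation.
#' @param reads Named character vector: `sample_id` -> read file (BED6).
#' @param samples Path to the sample sheet CSV, or a data frame.
#' @param out_dir Output directory (created if missing).
#' @param ref_group,test_group Reference and test groups for the trend,
#'   fold-change and consistency layers; defaults are the first and last
#'   group of the sample sheet.
#' @param literature Optional literature table (CSV with `miRNA`, `n_up`,
#'   `n_down`, or a data frame); when absent the consistency stage is
#'   skipped and noted in the summary.
#' @param de_table Optional differential-expression table (TSV/CSV with
#'   `miRNA`, `log2FC`, `padj`, or a data frame).
#' @param min_length,max_mismatches,min_identity Read filter thresholds.
#' @param min_group_reads Presence threshold per group.
#' @param band Trend stability band.
#' @param alpha Adjusted-p threshold for the significant list.
#' @param cluster_distance Strict cluster-neighbour bound in nt.
#' @param extension_flank Segment-map flank width in nt.
#' @param min_joint_reads Strict joint-expression bound for the
#'   consistency layer.
#' @param strand_mode Read/hairpin strand handling (see [assign_reads()]).
#' @param seed Seed recorded in the summary.
#' @return A list of class `run_config`.
#' @export
run_config <- function(gff, reads, samples, out_dir,
                       ref_group = NULL, test_group = NULL,
                       literature = NULL, de_table = NULL,
                       min_length = 17L, max_mismatches = 2L,
                       min_identity = 0.90, min_group_reads = 10L,
                       band = 0.20, alpha = 0.05,
                       cluster_distance = 10000L, extension_flank = 50L,
                       min_joint_reads = 50, strand_mode = "same",
                       seed = 1L) {
  cfg <- list(
    gff = gff, reads = reads, samples = samples, out_dir = out_dir,
    ref_group = ref_group, test_group = test_group,
    literature = literature, de_table = de_table,
    min_length = min_length, max_mismatches = max_mismatches,
    min_identity = min_identity, min_group_reads = min_group_reads,
    band = band, alpha = alpha, cluster_distance = cluster_distance,
    extension_flank = extension_flank,
    min_joint_reads = min_joint_reads, strand_mode = strand_mode,
    seed = seed
  )
  thresholds <- c("min_length", "max_mismatches", "min_identity",
                  "min_group_reads", "band", "alpha", "cluster_distance",
                  "extension_flank", "min_joint_reads")
  bad <- thresholds[vapply(cfg[thresholds],
                           function(x) !is.numeric(x) || x <= 0,
                           logical(1))]
  if (length(bad) > 0) {
    stop("non-positive threshold(s): ", paste(bad, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; the `reads` entry must be a named map of
#'   sample id to read file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw$reads <- unlist(raw$reads)
  do.call(run_config, raw)
}

stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed on ", input, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full classification and comparison pipeline
#'
#' Executes annotate, classify, quantify and compare in order, writing
#' every intermediate table as TSV plus a JSON summary holding the counts
#' at each filter stage, the configuration (with an MD5 hash), and the
#' seed. Re-running with identical configuration and inputs reproduces
#' every output byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(
    package_version = as.character(utils::packageVersion("spliceomiR")),
    seed = config$seed
  )

  samples <- stage("samples", "sample sheet", {
    if (is.character(config$samples)) read_sample_sheet(config$samples)
    else validate_sample_sheet(config$samples)
  })
  if (is.null(config$ref_group)) config$ref_group <- samples$group[1]
  if (is.null(config$test_group)) {
    config$test_group <- samples$group[nrow(samples)]
  }

  ann <- stage("annotate", config$gff,
               read_hairpin_annotations(config$gff))
  maps <- stage("annotate", config$gff,
                build_segment_maps(ann, config$extension_flank))
  export_segment_maps(maps, tsv_path = out("segment_maps.tsv"),
                      bed_path = out("segment_maps.bed"))
  clusters <- find_cluster_neighbors(ann$hairpins,
                                     config$cluster_distance)
  utils::write.table(clusters, out("cluster_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$n_hairpins <- nrow(ann$hairpins)
  summary$n_matures <- nrow(ann$matures)
  summary$n_cluster_pairs <- nrow(clusters)

  reads <- do.call(rbind, lapply(names(config$reads), function(s) {
    stage("classify", config$reads[[s]],
          load_reads(config$reads[[s]], format = "bed", sample = s))
  }))
  summary$n_reads_loaded <- nrow(reads)
  kept <- filter_reads(reads, config$min_length, config$max_mismatches,
                       config$min_identity)
  summary$n_reads_filtered <- nrow(kept)
  calls <- stage("classify", "reads",
                 assign_reads(kept, maps, config$strand_mode))
  summary$n_reads_assigned <- sum(calls$category != "unassigned")
  utils::write.table(
    calls[calls$category != "unassigned",
          c("read_id", "hairpin_id", "category", "sample")],
    out("segment_calls.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  partition <- segment_partition(calls, by = "miRNA", normalized = TRUE)
  utils::write.table(partition, out("segment_partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  counts <- stage("quantify", "calls",
                  build_count_matrix(calls, samples))
  write_matrix <- function(m, f) {
    utils::write.table(data.frame(miRNA = rownames(m), m,
                                  check.names = FALSE),
                       out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_matrix(counts, "counts_raw.tsv")
  pf <- presence_filter(counts, samples, config$min_group_reads)
  summary$n_mirnas_detected <- nrow(counts)
  summary$n_mirnas_present <- nrow(pf$counts)
  rpm <- rpm_normalize(pf$counts)
  write_matrix(round(rpm, 4), "counts_rpm.tsv")
  gm <- group_means(rpm, samples)
  write_matrix(round(gm, 4), "group_means_rpm.tsv")

  if (length(unique(samples$group)) >= 3) {
    venn <- venn_partition(pf$presence_sets[unique(samples$group)[1:3]])
    jsonlite::write_json(
      list(set_names = venn$set_names, regions = as.list(venn$regions),
           union_size = venn$union_size,
           set_totals = as.list(venn$set_totals)),
      out("venn.json"), auto_unbox = TRUE
    )
    summary$venn_union <- venn$union_size
  }

  universe <- rownames(gm)
  if (!is.null(config$de_table)) {
    de <- if (is.character(config$de_table)) {
      utils::read.delim(config$de_table, stringsAsFactors = FALSE)
    } else {
      config$de_table
    }
    sig <- stage("compare", "de_table",
                 select_significant(de, config$alpha))
    utils::write.table(sig, out("significant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_significant <- nrow(sig)
    universe <- intersect(universe, sig$miRNA)
  }

  other <- setdiff(unique(samples$group),
                   c(config$ref_group, config$test_group))
  trend_test <- call_trend(gm[universe, config$ref_group],
                           gm[universe, config$test_group],
                           band = config$band, mirna = universe)
  utils::write.table(trend_test, out("trends.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(other) >= 1) {
    trend_other <- call_trend(gm[universe, config$ref_group],
                              gm[universe, other[1]],
                              band = config$band, mirna = universe)
    pt <- partition_trends(
      trend_other, trend_test,
      paste(c(other[1], config$test_group), "vs", config$ref_group)
    )
    utils::write.table(
      data.frame(trend = rownames(pt$counts), pt$counts,
                 check.names = FALSE),
      out("trend_partition.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    summary$trend_percent <- as.list(
      as.data.frame(pt$percent, check.names = FALSE))
  }

  fc <- fold_change_table(gm, config$ref_group, config$test_group)
  utils::write.table(fc, out("fold_change.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(config$literature)) {
    lit <- if (is.character(config$literature)) {
      utils::read.csv(config$literature, stringsAsFactors = FALSE)
    } else {
      config$literature
    }
    top <- select_top_expressed(pf$counts, samples,
                                c(config$ref_group, config$test_group),
                                config$min_joint_reads)
    cc <- consistency_classify(
      trend_test[trend_test$miRNA %in% top, , drop = FALSE], lit)
    utils::write.table(cc, out("consistency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_consistency_scored <- nrow(cc)
  } else {
    summary$consistency <- "skipped (no literature table)"
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(cfg_for_hash, tmp, version = 2, compress = FALSE)
  summary$config_md5 <- unname(tools::md5sum(tmp))
  summary$config <- config[c("min_length", "max_mismatches",
                             "min_identity", "min_group_reads", "band",
                             "alpha", "cluster_distance",
                             "extension_flank", "min_joint_reads",
                             "strand_mode", "ref_group", "test_group")]
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
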