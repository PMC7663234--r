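# Count matrices, presence filtering, RPM normalisation, group summaries.

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `group`, `replicate`.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(tab)
}

validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "group", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample sheet")
  }
  if (anyDuplicated(paste(samples$group, samples$replicate))) {
    stop("duplicated (group, replicate) in sample sheet")
  }
  samples
}

#' Build a miRNA-by-sample count matrix from segment calls
#'
#' Every assignable call to a hairpin counts toward that miRNA, regardless
#' of segmental category, unless `include_categories` restricts the set
#' (e.g. `c("mature_5p", "mature_3p")` for mature-only counting).
#'
#' @param calls Segment calls from [assign_reads()] with a `sample`
#'   column.
#' @param samples Sample sheet (`sample_id`, `group`, `replicate`).
#' @param include_categories `"all"` (default) or a character vector of
#'   categories to count.
#' @return Integer matrix, rows = miRNA, columns = `samples$sample_id`,
#'   with attribute `normalized = FALSE`.
#' @export
build_count_matrix <- function(calls, samples, include_categories = "all") {
  samples <- validate_sample_sheet(samples)
  calls <- calls[!is.na(calls$hairpin_id) &
                   calls$category != "unassigned", , drop = FALSE]
  if (!"sample" %in% names(calls)) stop("calls carry no sample column")
  unknown <- setdiff(unique(calls$sample), samples$sample_id)
  if (length(unknown) > 0) {
    stop("sample(s) in calls missing from sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  if (!identical(include_categories, "all")) {
    bad <- setdiff(include_categories, READ_CATEGORIES)
    if (length(bad) > 0) stop("unknown categories: ",
                              paste(bad, collapse = ", "))
    calls <- calls[calls$category %in% include_categories, , drop = FALSE]
  }
  tt <- table(
    factor(calls$hairpin_id),
    factor(calls$sample, levels = samples$sample_id)
  )
  m <- matrix(as.integer(tt), nrow = nrow(tt),
              dimnames = list(rownames(tt), colnames(tt)))
  attr(m, "normalized") <- FALSE
  m
}

group_of <- function(counts, samples) {
  samples$group[match(colnames(counts), samples$sample_id)]
}

#' Presence filter: expressed in a group means >= `min_reads_per_group`
#' reads summed over that group's replicates
#'
#' A miRNA is called present ("expressed") in a group when its raw counts
#' summed across the group's replicates reach `min_reads_per_group`. The
#' matrix is restricted to miRNAs present in at least one group; retained
#' values are never altered, so the operation is idempotent.
#'
#' @param counts Raw count matrix from [build_count_matrix()].
#' @param samples Sample sheet.
#' @param min_reads_per_group Presence threshold on the group sum
#'   (default 10).
#' @return List with `counts` (filtered matrix), `presence` (logical
#'   miRNA-by-group matrix for retained miRNAs), and `presence_sets`
#'   (named list of miRNA identifier vectors per group, ready for
#'   [venn_partition()]).
#' @export
presence_filter <- function(counts, samples, min_reads_per_group = 10L) {
  samples <- validate_sample_sheet(samples)
  if (isTRUE(attr(counts, "normalized"))) {
    stop("presence_filter expects raw counts")
  }
  grp <- group_of(counts, samples)
  groups <- unique(samples$group)
  group_sums <- vapply(groups, function(g) {
    rowSums(counts[, grp == g, drop = FALSE])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1) {
    group_sums <- matrix(group_sums, nrow = 1,
                         dimnames = list(rownames(counts), groups))
  }
  presence <- group_sums >= min_reads_per_group
  keep <- rowSums(presence) > 0
  filtered <- counts[keep, , drop = FALSE]
  attr(filtered, "normalized") <- FALSE
  sets <- lapply(groups, function(g) rownames(presence)[presence[, g]])
  names(sets) <- groups
  list(
    counts = filtered,
    presence = presence[keep, , drop = FALSE],
    presence_sets = sets
  )
}

#' Reads-per-million normalisation
#'
#' Scales each sample (column) to reads per million, where the denominator
#' is that sample's total miRNA-assigned reads (the column sum), not the
#' total library size: only miRNA-aligned reads enter the matrix upstream.
#'
#' @param counts Raw count matrix.
#' @return Numeric matrix whose columns each sum to 1e6, with attribute
#'   `normalized = TRUE`.
#' @export
rpm_normalize <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero assigned reads in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  m <- sweep(counts, 2, totals, "/") * 1e6
  attr(m, "normalized") <- TRUE
  m
}

#' Per-group mean expression
#'
#' @param counts Count matrix (raw or RPM).
#' @param samples Sample sheet.
#' @return Numeric matrix, rows = miRNA, columns = groups, arithmetic mean
#'   over each group's replicates.
#' @export
group_means <- function(counts, samples) {
  samples <- validate_sample_sheet(samples)
  grp <- group_of(counts, samples)
  groups <- unique(samples$group)
  m <- vapply(groups, function(g) {
    rowMeans(counts[, grp == g, drop = FALSE])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1) {
    m <- matrix(m, nrow = 1, dimnames = list(rownames(counts), groups))
  }
  m
}

#' Sample-by-sample correlation of miRNA profiles
#'
#' Computes the correlation between per-sample expression profiles,
#' by default Pearson on `log10(x + 1)`-transformed values; a rank-based
#' method is available via `method = "spearman"` (no transform applied,
#' ranks are transform-invariant). Samples with a constant profile yield
#' `NA` against all others.
#'
#' @param counts Count matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_transform Apply `log10(x + 1)` first (default TRUE for
#'   Pearson).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(counts, method = c("pearson", "spearman"),
                                  log_transform = TRUE) {
  method <- match.arg(method)
  if (ncol(counts) < 2) stop("need at least two samples")
  x <- if (log_transform && method == "pearson") log10(counts + 1) else counts
  cc <- suppressWarnings(stats::cor(x, method = method))
  diag(cc) <- 1
  cc
}

#' Select significantly differentially expressed miRNAs
#'
#' Filters an externally computed differential-expression table (e.g. a
#' DESeq2 results export) to adjusted p-values strictly below `alpha` and
#' ranks by significance.
#'
#' @param de_table Data frame with at least `miRNA` and `padj` columns
#'   (`log2FC` is carried through when present).
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05, strict).
#' @return The significant rows, sorted by ascending `padj`.
#' @export
select_significant <- function(de_table, alpha = 0.05) {
  if (!"padj" %in% names(de_table)) {
    stop("differential-expression table lacks a 'padj' column")
  }
  keep <- !is.na(de_table$padj) & de_table$padj < alpha
  out <- de_table[keep, , drop = FALSE]
  out[order(out$padj), , drop = FALSE]
}

#' Select miRNAs above a joint expression threshold in two groups
#'
#' Retains miRNAs whose reads summed over the replicates of a reference
#' and a test group exceed `min_joint_reads` (strictly).
#'
#' @param counts Count matrix.
#' @param samples Sample sheet.
#' @param groups Character vector of the two group names `c(ref, test)`.
#' @param min_joint_reads Strict lower bound on the joint sum
#'   (default 50).
#' @return Character vector of retained miRNA identifiers.
#' @export
select_top_expressed <- function(counts, samples, groups,
                                 min_joint_reads = 50) {
  samples <- validate_sample_sheet(samples)
  stopifnot(length(groups) == 2)
  unknown <- setdiff(groups, samples$group)
  if (length(unknown) > 0) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  }
  grp <- group_of(counts, samples)
  joint <- rowSums(counts[, grp %in% groups, drop = FALSE])
  rownames(counts)[joint > min_joint_reads]
}
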