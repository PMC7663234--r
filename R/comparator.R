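# Comparative layer: Venn partitions, Up/Down/Same trend discretisation,
# and literature-consistency classification.

TREND_LEVELS <- c("U", "D", "S")
CONSISTENCY_VERDICTS <- c("consistent", "opposite", "mixed",
                          "minimal_support", "not_available")

#' Three-set Venn partition of presence sets
#'
#' Partitions three named sets of miRNA identifiers into the seven
#' exclusive Venn regions and reports the union size and per-set totals.
#'
#' @param sets Named list of three character vectors.
#' @return An object of class `venn_partition`: a list with `set_names`,
#'   `regions` (named counts for `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`,
#'   where letters refer to the sets in input order and each region is
#'   exclusive), `union_size`, and `set_totals`.
#' @examples
#' venn_partition(list(
#'   MCF10A = c("a", "b", "c"), MCF7 = c("b", "c"), MDA = c("c", "d")
#' ))
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- c("A", "B", "C")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  regions <- c(
    A = sum(inA & !inB & !inC),
    B = sum(!inA & inB & !inC),
    C = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC)
  )
  structure(
    list(
      set_names = names(sets),
      regions = regions,
      union_size = length(universe),
      set_totals = stats::setNames(lengths(sets), names(sets))
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Three-set Venn partition (", paste(x$set_names, collapse = ", "),
      ")\n", sep = "")
  cat("  exclusive regions:\n")
  print(x$regions)
  cat("  union:", x$union_size, "\n")
  cat("  per-set totals:",
      paste(x$set_names, x$set_totals, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct three presence sets from printed Venn region counts
#'
#' Builds synthetic member identifiers realising given exclusive region
#' counts, so that published Venn figures can be re-analysed with
#' [venn_partition()].
#'
#' @param regions Named numeric vector with entries `A`, `B`, `C`, `AB`,
#'   `AC`, `BC`, `ABC` (exclusive counts).
#' @param set_names Names for the three sets.
#' @return Named list of three character vectors.
#' @export
venn_sets_from_regions <- function(regions,
                                   set_names = c("A", "B", "C")) {
  needed <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  stopifnot(all(needed %in% names(regions)))
  ids <- unlist(lapply(needed, function(r) {
    n <- regions[[r]]
    if (n > 0) paste0(r, "_", seq_len(n)) else character()
  }))
  member <- function(set_letter) {
    pick <- needed[grepl(set_letter, needed)]
    ids[sub("_.*", "", ids) %in% pick]
  }
  stats::setNames(
    list(member("A"), member("B"), member("C")),
    set_names
  )
}

#' Discretise an expression change into an Up/Down/Same trend
#'
#' Compares a test-group mean against a reference-group mean and labels
#' the change `U` (up), `D` (down), or `S` (same). Stability is a
#' symmetric band around the reference: `S` iff
#' `1 - band <= test/ref <= 1 + band` (boundaries inclusive). Zeros are
#' handled symmetrically: both means zero is `S`; a zero reference with a
#' positive test mean is `U`; a zero test mean with a positive reference
#' is `D`. The label is scale-invariant.
#'
#' @param ref_mean,test_mean Non-negative mean expression values
#'   (vectorised).
#' @param band Half-width of the stability band as a fraction of the
#'   reference (default 0.20).
#' @param mirna Optional miRNA identifiers carried into the result.
#' @return Data frame with `ref_mean`, `test_mean`, `ratio` (`NA` when the
#'   reference is zero), and `label` (factor with levels U, D, S).
#' @export
call_trend <- function(ref_mean, test_mean, band = 0.20, mirna = NULL) {
  if (any(ref_mean < 0, na.rm = TRUE) || any(test_mean < 0, na.rm = TRUE)) {
    stop("negative mean expression")
  }
  n <- max(length(ref_mean), length(test_mean))
  ref_mean <- rep_len(ref_mean, n)
  test_mean <- rep_len(test_mean, n)
  ratio <- ifelse(ref_mean > 0, test_mean / ref_mean, NA_real_)
  label <- character(n)
  zero_both <- ref_mean == 0 & test_mean == 0
  zero_ref <- ref_mean == 0 & test_mean > 0
  label[zero_both] <- "S"
  label[zero_ref] <- "U"
  pos <- ref_mean > 0
  label[pos & ratio > 1 + band] <- "U"
  label[pos & ratio < 1 - band] <- "D"
  label[pos & ratio >= 1 - band & ratio <= 1 + band] <- "S"
  out <- data.frame(
    ref_mean = ref_mean, test_mean = test_mean, ratio = ratio,
    label = factor(label, levels = TREND_LEVELS),
    stringsAsFactors = FALSE
  )
  if (!is.null(mirna)) out <- cbind(data.frame(miRNA = mirna), out)
  out
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Tabulate trend labels across two comparisons
#'
#' Counts U/D/S labels in each of two comparisons over the same miRNA
#' universe, reports integer percentages (rounded half away from zero),
#' and cross-tabulates the paired trends.
#'
#' @param trends_a,trends_b Trend tables from [call_trend()] (or any data
#'   frame with a `label` column), same length and miRNA order.
#' @param comparison_names Length-2 names for the comparisons.
#' @return List with `counts` (3-by-2 matrix U/D/S by comparison),
#'   `percent` (same shape, integer percentages), `n` (universe size),
#'   and `paired` (U/D/S-by-U/D/S cross-tabulation).
#' @export
partition_trends <- function(trends_a, trends_b,
                             comparison_names = c("A_vs_ref", "B_vs_ref")) {
  la <- factor(trends_a$label, levels = TREND_LEVELS)
  lb <- factor(trends_b$label, levels = TREND_LEVELS)
  if (length(la) != length(lb)) {
    stop("the two comparisons cover different miRNA universes")
  }
  counts <- cbind(table(la), table(lb))
  colnames(counts) <- comparison_names
  n <- length(la)
  percent <- if (n > 0) round_half_up(counts / n * 100) else counts
  list(
    counts = counts,
    percent = percent,
    n = n,
    paired = table(first = la, second = lb)
  )
}

#' Summarise a per-publication literature table into direction counts
#'
#' @param long Data frame with columns `miRNA` and `direction`
#'   (values `"Up"`/`"Down"`, case-insensitive), one row per publication.
#' @return Data frame with `miRNA`, `n_up`, `n_down`.
#' @export
literature_counts <- function(long) {
  stopifnot(all(c("miRNA", "direction") %in% names(long)))
  dir <- tolower(long$direction)
  if (!all(dir %in% c("up", "down"))) {
    stop("literature direction must be Up or Down")
  }
  tt <- table(long$miRNA, factor(dir, levels = c("up", "down")))
  data.frame(
    miRNA = rownames(tt),
    n_up = as.integer(tt[, "up"]),
    n_down = as.integer(tt[, "down"]),
    stringsAsFactors = FALSE
  )
}

#' Classify consistency between an expression trend and the literature
#'
#' Compares each miRNA's discretised trend (test versus reference cell
#' line) with literature direction counts (publications reporting the
#' miRNA Up or Down in cancer versus healthy tissue):
#' \itemize{
#'   \item no literature record (or zero publications): `not_available`;
#'   \item 1--2 publications in total: `minimal_support`;
#'   \item 3+ publications split between both directions: `mixed`;
#'   \item unanimous direction agreeing with the trend (`U` with Up,
#'     `D` with Down): `consistent`;
#'   \item unanimous direction opposing the trend: `opposite`;
#'   \item a stable (`S`) trend against a unanimous literature direction:
#'     `mixed` (neither confirmed nor contradicted; flagged in the
#'     output).
#' }
#'
#' @param trends Trend table from [call_trend()] with a `miRNA` column.
#' @param literature Data frame with `miRNA`, `n_up`, `n_down` (see
#'   [literature_counts()]), or `NULL`.
#' @return Data frame with `miRNA`, `sf_trend`, `n_up`, `n_down`,
#'   `verdict` (factor), and logical `stable_vs_unanimous`.
#' @export
consistency_classify <- function(trends, literature = NULL) {
  stopifnot("miRNA" %in% names(trends))
  n <- nrow(trends)
  if (is.null(literature)) {
    literature <- data.frame(miRNA = character(), n_up = integer(),
                             n_down = integer(), stringsAsFactors = FALSE)
  }
  if (any(literature$n_up < 0 | literature$n_down < 0)) {
    stop("negative publication counts")
  }
  idx <- match(trends$miRNA, literature$miRNA)
  n_up <- ifelse(is.na(idx), 0L, literature$n_up[idx])
  n_down <- ifelse(is.na(idx), 0L, literature$n_down[idx])
  total <- n_up + n_down
  sf <- as.character(trends$label)

  verdict <- rep("not_available", n)
  has_lit <- !is.na(idx) & total > 0
  verdict[has_lit & total <= 2] <- "minimal_support"
  strong <- has_lit & total >= 3
  both_dir <- strong & n_up > 0 & n_down > 0
  verdict[both_dir] <- "mixed"
  unanimous <- strong & !both_dir
  lit_dir <- ifelse(n_up > 0, "U", "D")
  verdict[unanimous & sf == lit_dir] <- "consistent"
  verdict[unanimous & sf != lit_dir & sf != "S"] <- "opposite"
  stable_vs_unanimous <- unanimous & sf == "S"
  verdict[stable_vs_unanimous] <- "mixed"

  data.frame(
    miRNA = trends$miRNA,
    sf_trend = factor(sf, levels = TREND_LEVELS),
    n_up = n_up,
    n_down = n_down,
    verdict = factor(verdict, levels = CONSISTENCY_VERDICTS),
    stable_vs_unanimous = stable_vs_unanimous,
    stringsAsFactors = FALSE
  )
}

#' Per-miRNA log2 expression ratio between two groups
#'
#' @param group_means Matrix from [group_means()].
#' @param ref,test Group (column) names.
#' @param pseudocount Added to both means before the ratio (default 0.5).
#' @return Data frame with `miRNA`, `ref_mean`, `test_mean`, `log2_ratio`.
#' @export
fold_change_table <- function(group_means, ref, test, pseudocount = 0.5) {
  unknown <- setdiff(c(ref, test), colnames(group_means))
  if (length(unknown) > 0) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  }
  r <- group_means[, ref]
  t <- group_means[, test]
  if (any(r < 0) || any(t < 0)) stop("negative mean expression")
  data.frame(
    miRNA = rownames(group_means),
    ref_mean = unname(r),
    test_mean = unname(t),
    log2_ratio = unname(log2((t + pseudocount) / (r + pseudocount))),
    stringsAsFactors = FALSE
  )
}
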