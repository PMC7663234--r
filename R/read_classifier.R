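# Read ingestion, quality filtering, and segmental classification.

#' Load aligned small-RNA reads
#'
#' Reads aligned read intervals from BED6, a tab-separated table, or a
#' minimal SAM file and returns one row per primary mapped alignment.
#'
#' Formats:
#' \describe{
#'   \item{bed}{BED6 via rtracklayer; 0-based half-open coordinates are
#'     converted to 1-based closed. The score column is interpreted as the
#'     alignment mismatch count (0 when absent).}
#'   \item{tsv}{A header-bearing table with columns `chrom`, `start`, `end`
#'     (1-based closed), `strand`, and optionally `read_id`, `mismatches`,
#'     `sample`.}
#'   \item{sam}{A minimal SAM file; unmapped and secondary/supplementary
#'     records are dropped (their number is reported in a message).
#'     Mismatches are taken from the `NM` tag when present.}
#' }
#' The per-read `identity` fraction is computed as
#' `1 - mismatches / length`.
#'
#' @param path Input file.
#' @param format One of `"bed"`, `"tsv"`, `"sam"`.
#' @param sample Optional sample identifier attached to every read.
#' @return Data frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`, `mismatches`, `identity` (and `sample` if known).
#' @export
load_reads <- function(path, format = c("bed", "tsv", "sam"), sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file not found: ", path)
  reads <- switch(format,
    bed = {
      if (file.size(path) == 0) {
        warning("empty read file: ", path)
        empty_reads()
      } else {
        gr <- rtracklayer::import(path, format = "BED")
        mm <- if (!is.null(gr$score)) as.integer(gr$score) else
          rep(0L, length(gr))
        mm[is.na(mm)] <- 0L
        nm <- if (!is.null(gr$name)) as.character(gr$name) else
          paste0("read_", seq_along(gr))
        data.frame(
          read_id = nm,
          chrom = as.character(GenomeInfoDb::seqnames(gr)),
          start = GenomicRanges::start(gr),
          end = GenomicRanges::end(gr),
          strand = as.character(GenomicRanges::strand(gr)),
          mismatches = mm,
          stringsAsFactors = FALSE
        )
      }
    },
    tsv = {
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      required <- c("chrom", "start", "end", "strand")
      missing <- setdiff(required, names(tab))
      if (length(missing) > 0) {
        stop("tsv read file lacks column(s): ",
             paste(missing, collapse = ", "))
      }
      if (nrow(tab) == 0) warning("empty read file: ", path)
      data.frame(
        read_id = if ("read_id" %in% names(tab)) as.character(tab$read_id)
                  else paste0("read_", seq_len(nrow(tab))),
        chrom = as.character(tab$chrom),
        start = as.integer(tab$start),
        end = as.integer(tab$end),
        strand = as.character(tab$strand),
        mismatches = if ("mismatches" %in% names(tab))
          as.integer(tab$mismatches) else rep(0L, nrow(tab)),
        sample = if ("sample" %in% names(tab)) as.character(tab$sample)
                 else NULL,
        stringsAsFactors = FALSE
      )
    },
    sam = load_reads_sam(path)
  )
  if (nrow(reads) > 0 && any(reads$start < 0 | reads$end < 0)) {
    stop("negative read coordinates in ", path)
  }
  reads$length <- as.integer(reads$end - reads$start + 1L)
  reads$identity <- ifelse(reads$length > 0,
                           1 - reads$mismatches / reads$length, 0)
  if (!is.null(sample)) reads$sample <- as.character(sample)
  cols <- c("read_id", "chrom", "start", "end", "strand", "length",
            "mismatches", "identity",
            if ("sample" %in% names(reads)) "sample")
  reads[, cols, drop = FALSE]
}

empty_reads <- function() {
  data.frame(
    read_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), mismatches = integer(),
    stringsAsFactors = FALSE
  )
}

# Minimal SAM ingestion through Rsamtools (SAM -> BAM -> scanBam).
load_reads_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "flag"),
    tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- length(x$flag)
  mapped <- !bitwAnd(x$flag, 4L) & !bitwAnd(x$flag, 256L) &
    !bitwAnd(x$flag, 2048L)
  if (sum(!mapped) > 0) {
    message(sum(!mapped), " unmapped/secondary record(s) dropped of ",
            n_total)
  }
  ref_width <- cigar_reference_width(x$cigar[mapped])
  nm <- x$tag$NM
  nm <- if (is.null(nm)) rep(0L, n_total) else as.integer(nm)
  nm[is.na(nm)] <- 0L
  data.frame(
    read_id = x$qname[mapped],
    chrom = as.character(x$rname[mapped]),
    start = x$pos[mapped],
    end = x$pos[mapped] + ref_width - 1L,
    strand = as.character(x$strand[mapped]),
    mismatches = nm[mapped],
    stringsAsFactors = FALSE
  )
}

# Width of the alignment on the reference: sum of M/D/N/=/X cigar runs.
cigar_reference_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter reads on length, mismatches, and identity
#'
#' Retains reads of length at least `min_length` nt, with at most
#' `max_mismatches` mismatches and at least `min_identity` fractional
#' identity. The three predicates are independent, so the filter is
#' order-independent and idempotent.
#'
#' @param reads Read table from [load_reads()].
#' @param min_length Minimum read length in nt (default 17).
#' @param max_mismatches Maximum mismatch count (default 2).
#' @param min_identity Minimum identity fraction (default 0.90).
#' @return The retained subset of `reads`.
#' @export
filter_reads <- function(reads, min_length = 17L, max_mismatches = 2L,
                         min_identity = 0.90) {
  keep <- reads$length >= min_length &
    reads$mismatches <= max_mismatches &
    reads$identity >= min_identity
  reads[keep, , drop = FALSE]
}

#' Assign reads to hairpins and segmental categories
#'
#' A read is assignable to a hairpin only when both its start and its end
#' fall inside that hairpin's window (precursor plus extension flanks) and,
#' under `strand_mode = "same"`, the read strand matches the hairpin
#' strand. An assignable read contained in a single labelled segment takes
#' that label; a read whose interval crosses a border between two or more
#' labelled segments is `overlap`; a read contained in no window is
#' `unassigned`.
#'
#' A read contained in the windows of several hairpins is resolved to the
#' hairpin whose window midpoint is closest to the read midpoint; exact
#' ties go to the lexicographically smallest `hairpin_id`.
#'
#' @param reads Filtered read table (see [filter_reads()]).
#' @param segment_maps List of `segment_map` objects from
#'   [build_segment_maps()].
#' @param strand_mode `"same"` (reads must match hairpin strand; default)
#'   or `"both"`.
#' @return Data frame of segment calls: `read_id`, `hairpin_id`,
#'   `category` (plus `sample` when present in `reads`), one row per read,
#'   in input order.
#' @export
assign_reads <- function(reads, segment_maps,
                         strand_mode = c("same", "both")) {
  strand_mode <- match.arg(strand_mode)
  seg <- segment_maps_table(segment_maps)

  windows <- do.call(rbind, lapply(split(seg, seg$hairpin_id), function(s) {
    data.frame(
      hairpin_id = s$hairpin_id[1], chrom = s$chrom[1],
      start = min(s$start), end = max(s$end), strand = s$strand[1],
      stringsAsFactors = FALSE
    )
  }))
  calls <- data.frame(
    read_id = reads$read_id,
    hairpin_id = NA_character_,
    category = "unassigned",
    stringsAsFactors = FALSE
  )
  if ("sample" %in% names(reads)) calls$sample <- reads$sample
  if (nrow(reads) == 0) return(calls)

  rgr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start, reads$end),
    strand = reads$strand
  )
  wgr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start, windows$end),
    strand = windows$strand
  )
  hits <- GenomicRanges::findOverlaps(rgr, wgr, type = "within",
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (strand_mode == "same") {
    ok <- reads$strand[q] == windows$strand[s]
    q <- q[ok]; s <- s[ok]
  }
  if (length(q) == 0) return(calls)

  # resolve multi-window reads: nearest window midpoint, then smallest id
  read_mid <- (reads$start[q] + reads$end[q]) / 2
  win_mid <- (windows$start[s] + windows$end[s]) / 2
  cand <- data.frame(q = q, s = s, dist = abs(read_mid - win_mid),
                     id = windows$hairpin_id[s])
  ord <- order(cand$q, cand$dist, cand$id)
  cand <- cand[ord, , drop = FALSE]
  first <- !duplicated(cand$q)
  ties <- sum(tapply(cand$dist, cand$q, function(d) {
    length(d) > 1 && sum(d == min(d)) > 1
  }))
  if (!is.na(ties) && ties > 0) {
    message(ties, " read(s) tied between hairpin windows; ",
            "resolved by hairpin_id order")
  }
  chosen <- cand[first, , drop = FALSE]
  calls$hairpin_id[chosen$q] <- chosen$id

  # count distinct labelled segments each read touches within its hairpin
  sgr <- GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start, seg$end)
  )
  shits <- GenomicRanges::findOverlaps(rgr[chosen$q], sgr,
                                       ignore.strand = TRUE)
  sq <- chosen$q[S4Vectors::queryHits(shits)]
  ss <- S4Vectors::subjectHits(shits)
  same_hp <- seg$hairpin_id[ss] == calls$hairpin_id[sq]
  sq <- sq[same_hp]; ss <- ss[same_hp]
  n_seg <- tapply(ss, sq, length)
  one_label <- tapply(ss, sq, function(i) seg$label[i][1])
  idx <- as.integer(names(n_seg))
  calls$category[idx] <- ifelse(n_seg >= 2, "overlap",
                                unlist(one_label))
  calls
}

#' Summarise segmental composition
#'
#' Tabulates segment calls by category, per miRNA, per sample, or per
#' miRNA-and-sample. Unassigned calls are dropped (their number is
#' reported in a message). With `normalized = TRUE` each row is converted
#' to fractions summing to 1.
#'
#' For `by = "sample"` two views are produced, mirroring raw versus
#' per-miRNA-normalised summaries: `pooled` fractions computed from summed
#' raw counts, and `mean_mirna` fractions averaging each miRNA's own
#' composition with equal weight.
#'
#' @param calls Segment calls from [assign_reads()].
#' @param by `"miRNA"`, `"sample"`, or `"miRNA_sample"`.
#' @param normalized Return per-row fractions instead of counts
#'   (default TRUE; counts are returned alongside in either case for
#'   `by = "miRNA"`).
#' @return For `by = "miRNA"` and `by = "miRNA_sample"`, a data frame with
#'   one row per unit, count columns `n_<category>`, total `n_total`, and
#'   (if `normalized`) fraction columns `frac_<category>`. For
#'   `by = "sample"`, a list with elements `pooled` and `mean_mirna`.
#' @export
segment_partition <- function(calls,
                              by = c("miRNA", "sample", "miRNA_sample"),
                              normalized = TRUE) {
  by <- match.arg(by)
  categories <- setdiff(READ_CATEGORIES, "unassigned")
  drop <- calls$category == "unassigned" | is.na(calls$hairpin_id)
  if (any(drop)) {
    message(sum(drop), " unassigned call(s) dropped")
    calls <- calls[!drop, , drop = FALSE]
  }
  if (nrow(calls) == 0) {
    warning("no assignable calls")
    return(data.frame(miRNA = character(), stringsAsFactors = FALSE))
  }
  if (by %in% c("sample", "miRNA_sample") && !"sample" %in% names(calls)) {
    stop("calls carry no sample column")
  }

  tab_by <- function(key) {
    tt <- table(key, factor(calls$category, levels = categories))
    counts <- as.data.frame.matrix(tt)
    names(counts) <- paste0("n_", names(counts))
    counts$n_total <- rowSums(counts)
    counts
  }
  add_fracs <- function(counts) {
    fr <- counts[, paste0("n_", categories), drop = FALSE] / counts$n_total
    names(fr) <- paste0("frac_", categories)
    cbind(counts, fr)
  }

  if (by == "miRNA") {
    counts <- tab_by(calls$hairpin_id)
    out <- cbind(data.frame(miRNA = rownames(counts),
                            stringsAsFactors = FALSE),
                 if (normalized) add_fracs(counts) else counts)
    rownames(out) <- NULL
    return(out)
  }
  if (by == "miRNA_sample") {
    key <- paste(calls$hairpin_id, calls$sample, sep = "\r")
    counts <- tab_by(key)
    parts <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))
    out <- cbind(data.frame(miRNA = parts[, 1], sample = parts[, 2],
                            stringsAsFactors = FALSE),
                 if (normalized) add_fracs(counts) else counts)
    rownames(out) <- NULL
    return(out)
  }

  # by sample: pooled counts and equal-weight mean of per-miRNA fractions
  counts <- tab_by(calls$sample)
  pooled <- cbind(data.frame(sample = rownames(counts),
                             stringsAsFactors = FALSE),
                  add_fracs(counts))
  rownames(pooled) <- NULL

  per_ms <- segment_partition(calls, by = "miRNA_sample", normalized = TRUE)
  fr_cols <- paste0("frac_", categories)
  mean_mirna <- do.call(rbind, lapply(split(per_ms, per_ms$sample),
    function(d) {
      data.frame(sample = d$sample[1], n_mirnas = nrow(d),
                 t(colMeans(d[, fr_cols, drop = FALSE])),
                 stringsAsFactors = FALSE)
    }))
  rownames(mean_mirna) <- NULL
  list(pooled = pooled, mean_mirna = mean_mirna)
}
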