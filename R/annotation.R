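# Annotation handling: miRBase-style GFF3 parsing, per-hairpin segment maps,
# and genomic cluster-neighbour detection.
#
# All internal coordinates are 1-based closed (GFF3 / GRanges convention);
# BED I/O is converted at the boundary. Hairpin-local coordinates run 5'->3'
# along the precursor with position 1 at the first hairpin base, so extension
# flanks have local positions <= 0 (upstream) or > hairpin length (downstream).

SEGMENT_LABELS <- c("mature_5p", "mature_3p", "undefined_complement", "extension")
READ_CATEGORIES <- c(SEGMENT_LABELS, "overlap", "unassigned")

#' Read miRBase-style hairpin and mature annotations
#'
#' Parses a GFF3 file in the miRBase dialect: hairpin precursors as
#' `miRNA_primary_transcript` features and mature products as `miRNA`
#' features carrying a `Derives_from` attribute that names their precursor.
#'
#' The arm of each mature product is assigned from its position on the
#' precursor: if the mature midpoint lies on the 5' half of the hairpin
#' (ties included) the arm is `5p`, otherwise `3p`. Matures whose
#' `Derives_from` does not resolve to a parsed hairpin are skipped with a
#' warning; a mature lying outside its parent's span is an error.
#'
#' @param gff3_path Path to a GFF3 file.
#' @return A list with two data frames:
#'   \describe{
#'     \item{hairpins}{`hairpin_id`, `chrom`, `start`, `end`, `strand`,
#'       `length` (1-based closed genomic coordinates).}
#'     \item{matures}{`mature_id`, `hairpin_id`, `chrom`, `start`, `end`,
#'       `strand`, `arm` (`"5p"` or `"3p"`).}
#'   }
#' @examples
#' ann <- make_annotation_fixture(simulation_spec(n_mirnas = 5), seed = 1)
#' gff <- tempfile(fileext = ".gff3")
#' write_annotation_gff3(ann, gff)
#' parsed <- read_hairpin_annotations(gff)
#' head(parsed$matures)
#' @export
read_hairpin_annotations <- function(gff3_path) {
  if (!file.exists(gff3_path)) {
    stop("annotation file not found: ", gff3_path)
  }
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  feature_name <- function(x) {
    nm <- if (!is.null(x$Name)) as.character(x$Name) else NA_character_
    id <- if (!is.null(x$ID)) as.character(x$ID) else NA_character_
    ifelse(is.na(nm) | nm == "", id, nm)
  }

  hp <- gr[type == "miRNA_primary_transcript"]
  if (length(hp) == 0) {
    stop("no miRNA_primary_transcript features in ", gff3_path)
  }
  hp_id_attr <- if (!is.null(hp$ID)) as.character(hp$ID) else feature_name(hp)
  hairpins <- data.frame(
    hairpin_id = feature_name(hp),
    chrom = as.character(GenomeInfoDb::seqnames(hp)),
    start = GenomicRanges::start(hp),
    end = GenomicRanges::end(hp),
    strand = as.character(GenomicRanges::strand(hp)),
    stringsAsFactors = FALSE
  )
  hairpins$length <- hairpins$end - hairpins$start + 1L
  if (anyDuplicated(hairpins$hairpin_id)) {
    stop("duplicated hairpin identifiers in ", gff3_path)
  }
  if (any(!hairpins$strand %in% c("+", "-"))) {
    stop("hairpin without a defined strand in ", gff3_path)
  }

  mt <- gr[type == "miRNA"]
  matures <- data.frame(
    mature_id = feature_name(mt),
    parent_attr = if (!is.null(mt$Derives_from)) {
      as.character(mt$Derives_from)
    } else {
      rep(NA_character_, length(mt))
    },
    chrom = as.character(GenomeInfoDb::seqnames(mt)),
    start = GenomicRanges::start(mt),
    end = GenomicRanges::end(mt),
    strand = as.character(GenomicRanges::strand(mt)),
    stringsAsFactors = FALSE
  )
  # Derives_from may reference the precursor's ID attribute or its Name
  idx <- match(matures$parent_attr, hp_id_attr)
  idx[is.na(idx)] <- match(matures$parent_attr[is.na(idx)], hairpins$hairpin_id)
  unresolved <- is.na(idx)
  if (any(unresolved)) {
    warning(
      sum(unresolved), " mature record(s) with unknown parent skipped: ",
      paste(utils::head(matures$mature_id[unresolved], 5), collapse = ", ")
    )
    matures <- matures[!unresolved, , drop = FALSE]
    idx <- idx[!unresolved]
  }
  matures$hairpin_id <- hairpins$hairpin_id[idx]

  hp_row <- hairpins[match(matures$hairpin_id, hairpins$hairpin_id), , drop = FALSE]
  outside <- matures$start < hp_row$start | matures$end > hp_row$end |
    matures$chrom != hp_row$chrom
  if (any(outside)) {
    stop(
      "mature record(s) outside parent hairpin span: ",
      paste(matures$mature_id[outside], collapse = ", ")
    )
  }

  loc <- genomic_to_local(matures$start, matures$end, hp_row)
  mid_local <- (loc$start + loc$end) / 2
  matures$arm <- ifelse(mid_local <= (hp_row$length + 1) / 2, "5p", "3p")
  dup_arm <- duplicated(paste(matures$hairpin_id, matures$arm))
  if (any(dup_arm)) {
    stop(
      "more than one mature annotated on the same arm for: ",
      paste(unique(matures$hairpin_id[dup_arm]), collapse = ", ")
    )
  }
  matures$parent_attr <- NULL
  matures <- matures[, c("mature_id", "hairpin_id", "chrom", "start", "end",
                         "strand", "arm")]
  list(hairpins = hairpins, matures = matures)
}

# Map genomic 1-based closed intervals to hairpin-local coordinates.
# hp is a data frame (recycled row-wise) with start/end/strand/length.
genomic_to_local <- function(start, end, hp) {
  minus <- hp$strand == "-"
  ls <- ifelse(minus, hp$end - end + 1L, start - hp$start + 1L)
  le <- ifelse(minus, hp$end - start + 1L, end - hp$start + 1L)
  list(start = as.integer(ls), end = as.integer(le))
}

# Inverse of genomic_to_local for a single hairpin row.
local_to_genomic <- function(ls, le, hp) {
  if (hp$strand == "-") {
    list(start = hp$end - le + 1L, end = hp$end - ls + 1L)
  } else {
    list(start = hp$start + ls - 1L, end = hp$start + le - 1L)
  }
}

#' Build the segmental map of one hairpin precursor
#'
#' Partitions the hairpin window (the precursor extended by
#' `extension_flank` nt on both sides) into disjoint labelled intervals:
#' the annotated mature products (`mature_5p`, `mature_3p`), an
#' `undefined_complement` interval on the arm opposite a single annotated
#' mature (the star-like region, placed by a duplex mirror rule with a 2-nt
#' 3' overhang and clipped to the precursor), and `extension` for every
#' remaining window position, including the loop between the arms.
#'
#' With hairpin-local 1-based positions and hairpin length `L`, a single
#' mature at `[s, e]` mirrors to a complement at
#' `[L - e + 1 + overhang, L - s + 1 + overhang]`, clipped to `[1, L]` and
#' truncated (with a warning) if it would overlap the mature itself. No
#' secondary-structure folding is performed.
#'
#' @param hairpin One row of the `hairpins` table from
#'   [read_hairpin_annotations()].
#' @param matures The mature table (rows for other hairpins are ignored);
#'   the hairpin must have 1 or 2 annotated matures.
#' @param extension_flank Width in nt of the genomic flanks added on each
#'   side of the precursor (default 50).
#' @param overhang 3' overhang in nt used by the mirror rule (default 2).
#' @return A `segment_map` data frame with columns `hairpin_id`, `label`,
#'   `local_start`, `local_end`, `chrom`, `start`, `end`, `strand`, ordered
#'   by local position, whose intervals are pairwise disjoint and cover the
#'   window exactly.
#' @export
build_segment_map <- function(hairpin, matures, extension_flank = 50L,
                              overhang = 2L) {
  stopifnot(nrow(hairpin) == 1, extension_flank >= 0)
  hp <- hairpin
  L <- hp$length
  mt <- matures[matures$hairpin_id == hp$hairpin_id, , drop = FALSE]
  if (nrow(mt) == 0) {
    stop("hairpin ", hp$hairpin_id,
         " has no annotated mature product; cannot orient arms")
  }
  if (nrow(mt) > 2) {
    stop("hairpin ", hp$hairpin_id, " has more than two mature products")
  }

  loc <- genomic_to_local(mt$start, mt$end, hp[rep(1, nrow(mt)), ])
  segs <- data.frame(
    label = paste0("mature_", mt$arm),
    local_start = loc$start,
    local_end = loc$end,
    stringsAsFactors = FALSE
  )
  if (nrow(segs) == 2) {
    segs <- segs[order(segs$local_start), ]
    if (segs$local_end[1] >= segs$local_start[2]) {
      stop("overlapping mature products on hairpin ", hp$hairpin_id)
    }
  } else {
    # single annotated arm: place the star-like undefined complement
    s <- segs$local_start[1]
    e <- segs$local_end[1]
    cs <- L - e + 1L + overhang
    ce <- L - s + 1L + overhang
    cs <- max(cs, 1L)
    ce <- min(ce, L)
    if (cs <= e && ce >= s) {
      if (mt$arm[1] == "5p") cs <- max(cs, e + 1L) else ce <- min(ce, s - 1L)
      warning("undefined complement truncated to avoid the mature product ",
              "on hairpin ", hp$hairpin_id)
    }
    if (cs <= ce) {
      segs <- rbind(segs, data.frame(
        label = "undefined_complement",
        local_start = cs, local_end = ce,
        stringsAsFactors = FALSE
      ))
    }
    segs <- segs[order(segs$local_start), ]
  }

  # extension = every window position not already labelled
  win_start <- 1L - as.integer(extension_flank)
  win_end <- L + as.integer(extension_flank)
  gap_start <- c(win_start, segs$local_end + 1L)
  gap_end <- c(segs$local_start - 1L, win_end)
  keep <- gap_start <= gap_end
  if (any(keep)) {
    segs <- rbind(segs, data.frame(
      label = "extension",
      local_start = gap_start[keep], local_end = gap_end[keep],
      stringsAsFactors = FALSE
    ))
  }
  segs <- segs[order(segs$local_start), ]

  gen <- local_to_genomic(segs$local_start, segs$local_end, hp)
  map <- data.frame(
    hairpin_id = hp$hairpin_id,
    label = segs$label,
    local_start = as.integer(segs$local_start),
    local_end = as.integer(segs$local_end),
    chrom = hp$chrom,
    start = as.integer(pmin(gen$start, gen$end)),
    end = as.integer(pmax(gen$start, gen$end)),
    strand = hp$strand,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(map,
    class = c("segment_map", "data.frame"),
    extension_flank = as.integer(extension_flank),
    overhang = as.integer(overhang),
    loop_in_extension = TRUE,
    window_local = c(win_start, win_end)
  )
}

#' Build segment maps for every hairpin in an annotation
#'
#' @param annotation A list with `hairpins` and `matures` as returned by
#'   [read_hairpin_annotations()].
#' @inheritParams build_segment_map
#' @return A named list of `segment_map` objects, one per hairpin.
#'   Hairpins without any annotated mature are skipped with a warning.
#' @export
build_segment_maps <- function(annotation, extension_flank = 50L,
                               overhang = 2L) {
  hp <- annotation$hairpins
  has_mature <- hp$hairpin_id %in% annotation$matures$hairpin_id
  if (any(!has_mature)) {
    warning(sum(!has_mature),
            " hairpin(s) without mature annotation skipped")
  }
  ids <- hp$hairpin_id[has_mature]
  maps <- lapply(ids, function(id) {
    build_segment_map(hp[hp$hairpin_id == id, , drop = FALSE],
                      annotation$matures, extension_flank, overhang)
  })
  names(maps) <- ids
  maps
}

# One flat data frame over a list of segment maps.
segment_maps_table <- function(segment_maps) {
  if (inherits(segment_maps, "segment_map")) {
    segment_maps <- list(segment_maps)
  }
  do.call(rbind, lapply(segment_maps, as.data.frame))
}

#' Find genomic cluster neighbours among hairpins
#'
#' Two miRNA precursors are cluster neighbours when they lie on the same
#' chromosome separated by strictly fewer than `max_distance` nt
#' (overlapping or adjacent precursors have distance 0). Each unordered
#' pair is reported once, with `mirna_a` < `mirna_b` lexicographically.
#'
#' @param hairpins Hairpin table from [read_hairpin_annotations()].
#' @param max_distance Strict upper bound on the inter-precursor gap in nt
#'   (default 10000).
#' @return Data frame with columns `mirna_a`, `mirna_b`, `distance`.
#' @export
find_cluster_neighbors <- function(hairpins, max_distance = 10000L) {
  empty <- data.frame(mirna_a = character(), mirna_b = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (is.null(hairpins) || nrow(hairpins) == 0) {
    return(empty)
  }
  gr <- GenomicRanges::GRanges(
    hairpins$chrom,
    IRanges::IRanges(hairpins$start, hairpins$end)
  )
  hits <- GenomicRanges::findOverlaps(
    gr,
    maxgap = max_distance - 1L,
    drop.self = TRUE, drop.redundant = TRUE,
    ignore.strand = TRUE
  )
  if (length(hits) == 0) {
    return(empty)
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(gr[q], gr[s], ignore.strand = TRUE)
  keep <- !is.na(d) & d < max_distance
  a <- hairpins$hairpin_id[q][keep]
  b <- hairpins$hairpin_id[s][keep]
  swap <- a > b
  pairs <- data.frame(
    mirna_a = ifelse(swap, b, a),
    mirna_b = ifelse(swap, a, b),
    distance = as.integer(d[keep]),
    stringsAsFactors = FALSE
  )
  pairs[order(pairs$mirna_a, pairs$mirna_b), , drop = FALSE]
}

#' Write segment maps to TSV and BED6
#'
#' The TSV lists one labelled interval per row in hairpin-local
#' coordinates; the BED6 file carries the same intervals in genomic
#' coordinates with `hairpin_id:label` in the name column.
#'
#' @param segment_maps A list of `segment_map` objects
#'   (see [build_segment_maps()]).
#' @param tsv_path,bed_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the combined segment table.
#' @export
export_segment_maps <- function(segment_maps, tsv_path = NULL,
                                bed_path = NULL) {
  tab <- segment_maps_table(segment_maps)
  if (!is.null(tsv_path)) {
    utils::write.table(
      tab[, c("hairpin_id", "label", "local_start", "local_end")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(
      tab$chrom,
      IRanges::IRanges(tab$start, tab$end),
      strand = tab$strand,
      name = paste(tab$hairpin_id, tab$label, sep = ":"),
      score = 0L
    )
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(tab)
}
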