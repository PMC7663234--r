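# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's vectorised code paths:
# plain nested loops and position-by-position label scans.

# Position-wise read classification oracle. For each read: find hairpin
# windows fully containing it (strand-matched), pick the nearest window
# midpoint (ties: smallest hairpin_id), then label every covered position
# from the segment table; one distinct touched segment -> its label,
# more -> "overlap", no window -> "unassigned".
oracle_classify <- function(reads, maps, strand_mode = "same") {
  tab <- do.call(rbind, lapply(maps, as.data.frame))
  wins <- do.call(rbind, lapply(maps, function(m) {
    data.frame(hairpin_id = m$hairpin_id[1], chrom = m$chrom[1],
               start = min(m$start), end = max(m$end),
               strand = m$strand[1], stringsAsFactors = FALSE)
  }))
  out <- character(nrow(reads))
  hp_out <- rep(NA_character_, nrow(reads))
  for (r in seq_len(nrow(reads))) {
    cand <- integer()
    for (w in seq_len(nrow(wins))) {
      if (wins$chrom[w] != reads$chrom[r]) next
      if (reads$start[r] < wins$start[w] || reads$end[r] > wins$end[w]) next
      if (strand_mode == "same" && reads$strand[r] != wins$strand[w]) next
      cand <- c(cand, w)
    }
    if (length(cand) == 0) {
      out[r] <- "unassigned"
      next
    }
    rm_mid <- (reads$start[r] + reads$end[r]) / 2
    dd <- abs((wins$start[cand] + wins$end[cand]) / 2 - rm_mid)
    best <- cand[dd == min(dd)]
    hp <- sort(wins$hairpin_id[best])[1]
    hp_out[r] <- hp
    seg <- tab[tab$hairpin_id == hp, , drop = FALSE]
    touched <- character()
    for (p in reads$start[r]:reads$end[r]) {
      row <- which(seg$start <= p & seg$end >= p)
      touched <- union(touched, paste0(seg$label[row], "#", row))
    }
    out[r] <- if (length(touched) == 1) sub("#.*", "", touched) else "overlap"
  }
  data.frame(hairpin_id = hp_out, category = out, stringsAsFactors = FALSE)
}

# O(n^2) all-pairs cluster-neighbour oracle.
oracle_cluster_pairs <- function(hairpins, max_distance = 10000) {
  res <- list()
  n <- nrow(hairpins)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (hairpins$chrom[i] != hairpins$chrom[j]) next
      d <- max(hairpins$start[i], hairpins$start[j]) -
        min(hairpins$end[i], hairpins$end[j]) - 1
      d <- max(d, 0)
      if (d < max_distance) {
        a <- hairpins$hairpin_id[i]; b <- hairpins$hairpin_id[j]
        res[[length(res) + 1]] <- data.frame(
          mirna_a = min(a, b), mirna_b = max(a, b), distance = as.integer(d),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(mirna_a = character(), mirna_b = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$mirna_a, out$mirna_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Minimal hand-built hairpin/mature tables (1-based closed genomic coords).
toy_hairpin <- function(id = "hp-a", chrom = "chr1", start = 1001L,
                        len = 80L, strand = "+") {
  data.frame(hairpin_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(start + len - 1L), strand = strand,
             length = as.integer(len), stringsAsFactors = FALSE)
}

toy_mature <- function(hp, arm, local_start, local_end) {
  gen <- if (hp$strand == "-") {
    c(hp$end - local_end + 1L, hp$end - local_start + 1L)
  } else {
    c(hp$start + local_start - 1L, hp$start + local_end - 1L)
  }
  data.frame(mature_id = paste0(hp$hairpin_id, "-", arm),
             hairpin_id = hp$hairpin_id, chrom = hp$chrom,
             start = gen[1], end = gen[2], strand = hp$strand, arm = arm,
             stringsAsFactors = FALSE)
}

toy_reads <- function(chrom, start, end, strand = "+", sample = NULL,
                      mismatches = 0L) {
  n <- max(length(start), length(end))
  r <- data.frame(
    read_id = paste0("r", seq_len(n)), chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    stringsAsFactors = FALSE
  )
  r$length <- r$end - r$start + 1L
  r$mismatches <- as.integer(mismatches)
  r$identity <- 1 - r$mismatches / r$length
  if (!is.null(sample)) r$sample <- sample
  r
}

write_gff_lines <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}
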