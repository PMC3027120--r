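# Fixture builders and independent brute-force oracles used across the
# suite. Oracles here deliberately avoid the package's own code paths.

sam_header <- function(chrom_sizes) {
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(chrom_sizes), "\tLN:", chrom_sizes))
}

# One SAM record line; pos1 is 1-based as in the format.
sam_record <- function(qname, flag, rname, pos1, mapq, cigar, nh = NULL) {
  base <- paste(qname, flag, rname, pos1, mapq, cigar, "*", 0L, 0L,
                "*", "*", sep = "\t")
  if (is.null(nh)) base else paste0(base, "\tNH:i:", nh)
}

write_sam_fixture <- function(records, chrom_sizes,
                              path = tempfile(fileext = ".sam")) {
  writeLines(c(sam_header(chrom_sizes), records), path)
  path
}

# Independent CIGAR interpreter: reference-consuming covered blocks
# (M/=/X cover; D/N advance without covering). Returns a 2-column matrix
# of 0-based half-open intervals.
oracle_cigar_blocks <- function(cigar, start0) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", m))
  op <- sub("^[0-9]+", "", m)
  pos <- start0
  blocks <- NULL
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      blocks <- rbind(blocks, c(pos, pos + len[i]))
      pos <- pos + len[i]
    } else if (op[i] %in% c("D", "N")) {
      pos <- pos + len[i]
    }
  }
  if (is.null(blocks)) matrix(integer(0L), 0L, 2L) else blocks
}

# Naive per-base pileup over [start, end) from (start0, cigar) pairs.
oracle_coverage <- function(starts, cigars, start, end) {
  v <- integer(end - start)
  for (i in seq_along(starts)) {
    b <- oracle_cigar_blocks(cigars[i], starts[i])
    for (j in seq_len(nrow(b))) {
      s <- max(b[j, 1L], start)
      e <- min(b[j, 2L], end)
      if (s < e) {
        idx <- (s - start + 1L):(e - start)
        v[idx] <- v[idx] + 1L
      }
    }
  }
  v
}

# Naive membership count: reads whose start lies in the exon union.
oracle_count_exon <- function(starts, exon_union) {
  total <- 0L
  for (s in starts) {
    for (j in seq_len(nrow(exon_union))) {
      if (s >= exon_union[j, 1L] && s < exon_union[j, 2L]) {
        total <- total + 1L
        break
      }
    }
  }
  total
}

# Naive junction attribution: both anchors must overlap some exon.
oracle_count_junction <- function(junctions, gene) {
  total <- 0L
  for (i in seq_len(nrow(junctions))) {
    if (junctions$chrom[i] != gene$chrom) next
    l <- FALSE; r <- FALSE
    for (j in seq_len(nrow(gene$exons))) {
      s <- gene$exons[j, 1L]; e <- gene$exons[j, 2L]
      if (junctions$left_start[i] < e && s < junctions$left_end[i]) l <- TRUE
      if (junctions$right_start[i] < e && s < junctions$right_end[i]) r <- TRUE
    }
    if (l && r) total <- total + junctions$count[i]
  }
  total
}

# A small two-gene annotation used in several files:
# geneA chr1 100-500, exons (100,200) and (400,500); geneB chr2 50-250,
# one exon.
toy_annotation <- function() {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\tgeneA\t0\t+\t100\t500\t0\t2\t100,100\t0,300",
    "chr2\t50\t250\tgeneB\t0\t-\t50\t250\t0\t1\t200,\t0,"), bed)
  parse_annotation(bed, "bed12")
}
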