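# Reading SAM/BAM exon alignments and BED junction alignments, plus
# coordinate sort/merge utilities with a stable-order contract.

FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

is_sam_path <- function(path) {
  tolower(tools::file_ext(path)) == "sam"
}

# Scan all records of a SAM or BAM file in file order, with the NH tag.
scan_alignment_records <- function(path) {
  bam <- path
  if (is_sam_path(path)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) {
        stop("failed to parse SAM file ", path, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is_sam_path(path)) {
    unlink(bam)
  }
  list(records = res, chrom_sizes = hdr)
}

#' Decide whether an alignment record is uniquely mapped
#'
#' Uniqueness follows the dominant aligner convention: when the `NH` tag
#' (number of reported hits) is present the record is unique iff
#' `NH == 1`; otherwise a positive mapping quality marks it unique.
#'
#' @param flag SAM flag (integer vector); the record must be mapped.
#' @param mapq mapping quality (integer vector).
#' @param nh value of the NH tag, or `NA` when absent.
#' @return Logical vector.
#' @export
is_unique <- function(flag, mapq, nh = NA_integer_) {
  n <- max(length(flag), length(mapq), length(nh))
  flag <- rep_len(as.integer(flag), n)
  mapq <- rep_len(as.integer(mapq), n)
  nh <- rep_len(as.integer(nh), n)
  ifelse(!is.na(nh), nh == 1L, mapq > 0L)
}

#' Load exon alignments from a SAM/BAM file
#'
#' Reads every record, drops unmapped (flag 0x4), secondary (0x100) and
#' supplementary (0x800) records, applies the uniqueness rule of
#' [is_unique()], and stores the surviving reads per chromosome in
#' start-sorted order (stable: equal starts keep file order). Positions
#' are converted from SAM's 1-based convention to 0-based internally.
#'
#' @param path path to a SAM or BAM file (extension decides).
#' @param sample_id identifier for the sample; defaults to the file name.
#' @return A `sample_alignment`: per-chromosome start-sorted data frames
#'   of unique reads (`start`, `cigar`, `mapq`, `flag`, `qname`), the
#'   total record count `n_total_records`, the unique-read count
#'   `n_unique`, and chromosome sizes from the header.
#' @export
load_exon_alignments <- function(path, sample_id = basename(path)) {
  sc <- scan_alignment_records(path)
  r <- sc$records
  n_total <- length(r$flag)
  if (n_total == 0L) {
    return(structure(
      list(sample_id = sample_id, reads_by_chrom = list(),
           n_total_records = 0L, n_unique = 0L,
           max_ref_width = integer(0L), chrom_sizes = sc$chrom_sizes),
      class = "sample_alignment"))
  }
  flag <- r$flag
  primary_mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(flag, FLAG_SECONDARY) == 0L &
    bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L
  nh <- if (is.null(r$tag$NH)) rep(NA_integer_, n_total) else r$tag$NH
  keep <- primary_mapped & is_unique(flag, r$mapq, nh)
  df <- data.frame(
    chrom = as.character(r$rname)[keep],
    start = r$pos[keep] - 1L,
    cigar = r$cigar[keep],
    mapq = r$mapq[keep],
    flag = flag[keep],
    qname = r$qname[keep],
    stringsAsFactors = FALSE)
  by_chrom <- split(df[-1L], factor(df$chrom, levels = unique(df$chrom)))
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start, method = "radix"), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  # Widest reference footprint per chromosome: lets coverage queries
  # exclude upstream reads with a single binary search.
  max_w <- vapply(by_chrom, function(d) {
    max(GenomicAlignments::cigarWidthAlongReferenceSpace(d$cigar))
  }, integer(1L))
  structure(
    list(sample_id = sample_id, reads_by_chrom = by_chrom,
         n_total_records = n_total, n_unique = sum(keep),
         max_ref_width = max_w, chrom_sizes = sc$chrom_sizes),
    class = "sample_alignment")
}

#' @export
print.sample_alignment <- function(x, ...) {
  cat(sprintf("<sample_alignment> %s: %d record(s), %d uniquely mapped on %d chromosome(s)\n",
              x$sample_id, x$n_total_records, x$n_unique,
              length(x$reads_by_chrom)))
  invisible(x)
}

#' Load junction reads from a BED file
#'
#' Junction-mapper output gives one BED record per exon-exon junction.
#' BED12 records must have exactly two blocks, which become the left and
#' right anchor intervals. The score column is interpreted as the number
#' of supporting reads (`count_mode = "score"`, the junction-mapper
#' convention); scores below 1 fall back to a count of 1, and
#' `count_mode = "one"` forces one read per record. Six-column BED input
#' has no blocks to anchor and is an error unless `six_column = TRUE`,
#' which uses degenerate one-base anchors at the junction ends.
#'
#' @param path path to the BED file.
#' @param count_mode `"score"` or `"one"`.
#' @param six_column allow BED6 input with degenerate anchors.
#' @return A data frame with columns `chrom`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `count` (0-based half-open anchors).
#' @export
load_junction_reads <- function(path, count_mode = c("score", "one"),
                                six_column = FALSE) {
  count_mode <- match.arg(count_mode)
  tl <- read_tab_lines(path)
  empty <- data.frame(chrom = character(0L), left_start = integer(0L),
                      left_end = integer(0L), right_start = integer(0L),
                      right_end = integer(0L), count = integer(0L))
  if (length(tl$fields) == 0L) return(empty)
  rows <- lapply(seq_along(tl$fields), function(i) {
    f <- tl$fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) < 3L) {
      stop("malformed BED line ", ln, " of ", path, call. = FALSE)
    }
    start <- parse_int_field(f[2L], "BED chromStart", ln, path)
    end <- parse_int_field(f[3L], "BED chromEnd", ln, path)
    score <- if (length(f) >= 5L) {
      suppressWarnings(as.numeric(f[5L]))
    } else NA_real_
    count <- if (count_mode == "score" && !is.na(score) && score >= 1) {
      as.integer(round(score))
    } else 1L
    if (length(f) >= 12L) {
      n_blocks <- parse_int_field(f[10L], "BED blockCount", ln, path)
      if (n_blocks != 2L) {
        stop("junction BED12 record at line ", ln, " of ", path,
             " has ", n_blocks, " blocks; exactly 2 required", call. = FALSE)
      }
      sizes <- parse_int_field(strsplit(f[11L], ",", fixed = TRUE)[[1L]],
                               "BED blockSizes", ln, path)
      offs <- parse_int_field(strsplit(f[12L], ",", fixed = TRUE)[[1L]],
                              "BED blockStarts", ln, path)
      if (length(sizes) < 2L || length(offs) < 2L) {
        stop("blockSizes/blockStarts arity mismatch at line ", ln, " of ",
             path, call. = FALSE)
      }
      ls <- start + offs[1L]; le <- ls + sizes[1L]
      rs <- start + offs[2L]; re <- rs + sizes[2L]
    } else {
      if (!six_column) {
        stop("junction BED record at line ", ln, " of ", path,
             " has no blocks to anchor (enable six_column mode for BED6)",
             call. = FALSE)
      }
      ls <- start; le <- start + 1L
      rs <- end - 1L; re <- end
    }
    if (le > rs) {
      stop("junction anchors overlap at line ", ln, " of ", path,
           " (no intron gap)", call. = FALSE)
    }
    data.frame(chrom = f[1L], left_start = ls, left_end = le,
               right_start = rs, right_end = re, count = count)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- SAM text sort/merge utilities ------------------------------------

# Read a SAM (or BAM, converted) file as header lines + record lines.
read_sam_text <- function(path) {
  if (!is_sam_path(path)) {
    dest <- tempfile(fileext = ".sam")
    path2 <- Rsamtools::asSam(path, destination = sub("\\.sam$", "", dest),
                              overwrite = TRUE)
    lines <- readLines(path2, warn = FALSE)
    unlink(path2)
  } else {
    lines <- readLines(path, warn = FALSE)
  }
  is_hdr <- startsWith(lines, "@")
  list(header = lines[is_hdr], records = lines[!is_hdr])
}

write_sam_text <- function(header, records, path) {
  if (!is_sam_path(path)) {
    tmp <- tempfile(fileext = ".sam")
    writeLines(c(header, records), tmp)
    Rsamtools::asBam(tmp, destination = sub("\\.bam$", "", path),
                     overwrite = TRUE, indexDestination = FALSE)
    unlink(tmp)
  } else {
    writeLines(c(header, records), path)
  }
  invisible(path)
}

sq_names <- function(header) {
  sq <- header[startsWith(header, "@SQ")]
  sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
}

# Stable coordinate order of SAM record lines: chromosome in header @SQ
# order, then position, input order breaking ties. Unmapped records sort
# last, keeping their input order.
sam_record_order <- function(records, chrom_levels) {
  f <- strsplit(records, "\t", fixed = TRUE)
  rname <- vapply(f, `[`, character(1L), 3L)
  pos <- as.integer(vapply(f, `[`, character(1L), 4L))
  ci <- match(rname, chrom_levels)
  ci[is.na(ci)] <- length(chrom_levels) + 1L
  order(ci, pos, method = "radix")
}

#' Coordinate-sort a SAM/BAM file
#'
#' Sorts records by (chromosome in header order, start position) with a
#' stable sort: records with equal coordinates keep their input order.
#' Sorting an already-sorted file reproduces it record-for-record.
#'
#' @param path_in input SAM or BAM.
#' @param path_out output path; `.sam` writes SAM text, otherwise BAM.
#' @return `path_out`, invisibly.
#' @export
sort_alignment_file <- function(path_in, path_out) {
  x <- read_sam_text(path_in)
  ord <- sam_record_order(x$records, sq_names(x$header))
  hdr <- sub("SO:[^\t]+", "SO:coordinate", x$header)
  write_sam_text(hdr, x$records[ord], path_out)
}

#' Merge coordinate-sorted SAM/BAM files
#'
#' Inputs must share an identical reference dictionary (`@SQ` lines).
#' The merge is a stable coordinate sort of the concatenated records, so
#' records with equal coordinates appear in input-file order.
#'
#' @param paths_in character vector of input SAM/BAM paths.
#' @param path_out output path; `.sam` writes SAM text, otherwise BAM.
#' @return `path_out`, invisibly.
#' @export
merge_alignment_files <- function(paths_in, path_out) {
  stopifnot(length(paths_in) >= 1L)
  xs <- lapply(paths_in, read_sam_text)
  sq0 <- xs[[1L]]$header[startsWith(xs[[1L]]$header, "@SQ")]
  for (i in seq_along(xs)[-1L]) {
    sq <- xs[[i]]$header[startsWith(xs[[i]]$header, "@SQ")]
    if (!identical(sq, sq0)) {
      stop("incompatible reference dictionaries: ", paths_in[1L], " vs ",
           paths_in[i], call. = FALSE)
    }
  }
  records <- unlist(lapply(xs, `[[`, "records"))
  ord <- sam_record_order(records, sq_names(xs[[1L]]$header))
  hdr <- sub("SO:[^\t]+", "SO:coordinate", xs[[1L]]$header)
  write_sam_text(hdr, records[ord], path_out)
}
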