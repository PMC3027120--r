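# Base-wise coverage ("signal map") computation: event-based sweep over
# start-sorted reads, group averages and differential maps.

new_coverage_track <- function(chrom, start, values) {
  structure(list(chrom = chrom, start = as.integer(start), values = values),
            class = "coverage_track")
}

#' Construct a coverage track
#'
#' A dense per-base signal over part of a chromosome: raw coverage
#' (integers) or an averaged/differential signal (reals). Mostly built
#' by [coverage_vector()] and [genome_signal_map()]; this constructor
#' serves externally computed signals.
#'
#' @param chrom chromosome name.
#' @param start 0-based offset of the first element.
#' @param values numeric vector of per-base signal.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(chrom, start, values) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom),
            start >= 0L, is.numeric(values), length(values) >= 1L)
  new_coverage_track(chrom, start, values)
}

#' @export
print.coverage_track <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat(sprintf("<coverage_track> %s:%d-%d (%d bases, %d nonzero, total %g)\n",
              x$chrom, x$start, x$start + length(x$values), length(x$values),
              nz, sum(x$values)))
  invisible(x)
}

# Reference-space aligned blocks of reads as a 2-column matrix of 0-based
# half-open intervals. Only M/=/X consume coverage; D and N gaps advance
# along the reference but are not covered.
cigar_ref_blocks <- function(cigar, start0) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = start0 + 1L, ops = c("M", "=", "X"))
  flat <- unlist(rl, use.names = FALSE)
  cbind(start = GenomicAlignments::start(flat) - 1L,
        end = GenomicAlignments::end(flat))
}

#' Per-base coverage over a genomic window
#'
#' Computes the pileup: `values[p - start + 1]` is the number of unique
#' reads whose aligned segments cover base `p`. Aligned segments are the
#' reference-consuming M/=/X CIGAR blocks; N (intron skip) and D gaps are
#' not covered. Candidate reads are located by binary search over the
#' start-sorted list, then counted with an event sweep (+1 at block
#' starts, -1 at block ends, prefix sum).
#'
#' @param sample a `sample_alignment`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return A `coverage_track` of integer per-base counts.
#' @export
coverage_vector <- function(sample, chrom, start, end) {
  stopifnot(inherits(sample, "sample_alignment"))
  if (start >= end) stop("empty window: start must be < end", call. = FALSE)
  width <- end - start
  reads <- sample$reads_by_chrom[[chrom]]
  if (is.null(reads) || nrow(reads) == 0L) {
    return(new_coverage_track(chrom, start, integer(width)))
  }
  starts <- reads$start
  hi <- findInterval(end - 0.5, starts)
  lo <- findInterval(start - sample$max_ref_width[[chrom]] - 0.5, starts) + 1L
  if (hi < lo) {
    return(new_coverage_track(chrom, start, integer(width)))
  }
  idx <- lo:hi
  blocks <- cigar_ref_blocks(reads$cigar[idx], starts[idx])
  bs <- pmax(blocks[, 1L], start)
  be <- pmin(blocks[, 2L], end)
  keep <- bs < be
  bs <- bs[keep]; be <- be[keep]
  delta_add <- tabulate(bs - start + 1L, nbins = width + 1L)
  delta_sub <- tabulate(be - start + 1L, nbins = width + 1L)
  values <- cumsum(delta_add - delta_sub)[seq_len(width)]
  new_coverage_track(chrom, start, as.integer(values))
}

#' Whole-genome signal map at base-wise resolution
#'
#' One dense coverage track per chromosome, each a single event-sweep
#' pass over that chromosome's start-sorted reads. Chromosome sizes
#' default to the alignment header's `@SQ LN` fields.
#'
#' @param sample a `sample_alignment`.
#' @param chrom_sizes named integer vector of chromosome lengths; default
#'   taken from the SAM/BAM header.
#' @return A `signal_map`: named list of `coverage_track`s, one per
#'   chromosome, in `chrom_sizes` order.
#' @export
genome_signal_map <- function(sample, chrom_sizes = NULL) {
  stopifnot(inherits(sample, "sample_alignment"))
  chrom_sizes <- chrom_sizes %||% sample$chrom_sizes
  missing_chroms <- setdiff(names(sample$reads_by_chrom), names(chrom_sizes))
  if (length(missing_chroms) > 0L) {
    stop("read chromosome(s) absent from declared sizes: ",
         paste(missing_chroms, collapse = ", "), call. = FALSE)
  }
  for (chrom in names(sample$reads_by_chrom)) {
    reads <- sample$reads_by_chrom[[chrom]]
    ends <- reads$start +
      GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
    bad <- which(ends > chrom_sizes[[chrom]])
    if (length(bad) > 0L) {
      stop("read '", reads$qname[bad[1L]], "' extends beyond declared size of ",
           chrom, " (", chrom_sizes[[chrom]], ")", call. = FALSE)
    }
  }
  tracks <- lapply(names(chrom_sizes), function(chrom) {
    coverage_vector(sample, chrom, 0L, chrom_sizes[[chrom]])
  })
  names(tracks) <- names(chrom_sizes)
  structure(tracks, class = "signal_map")
}

#' @export
print.signal_map <- function(x, ...) {
  cat(sprintf("<signal_map> %d chromosome(s)\n", length(x)))
  for (t in x) print(t)
  invisible(x)
}

check_same_interval <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  t0 <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(t$chrom, t0$chrom) || t$start != t0$start ||
        length(t$values) != length(t0$values)) {
      stop("tracks cover different intervals", call. = FALSE)
    }
  }
  t0
}

#' Base-wise average of replicate signal maps
#'
#' @param tracks list of `coverage_track`s over the identical interval
#'   (replicates of one condition).
#' @return A real-valued `coverage_track` of element-wise means.
#' @export
average_signal <- function(tracks) {
  t0 <- check_same_interval(tracks)
  vals <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "values")))
  new_coverage_track(t0$chrom, t0$start, vals)
}

#' Differential signal map between two groups
#'
#' Element-wise difference of the group averages
#' (`mean(group_a) - mean(group_b)`), e.g. treatment minus control; the
#' input for change-point screening of 3'-UTR coverage drop-outs.
#'
#' @param group_a,group_b lists of `coverage_track`s over one interval.
#' @return A real-valued `coverage_track`.
#' @export
differential_signal <- function(group_a, group_b) {
  a <- average_signal(group_a)
  b <- average_signal(group_b)
  check_same_interval(list(a, b))
  new_coverage_track(a$chrom, a$start, a$values - b$values)
}

#' Slice a coverage track to a sub-interval
#'
#' @param track a `coverage_track`.
#' @param start,end 0-based half-open interval, within the track.
#' @return A `coverage_track` over `[start, end)`.
#' @export
slice_track <- function(track, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (start < track$start || end > track$start + length(track$values) ||
      start >= end) {
    stop("slice [", start, ",", end, ") outside track extent", call. = FALSE)
  }
  off <- start - track$start
  new_coverage_track(track$chrom, start,
                     track$values[(off + 1L):(off + end - start)])
}
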