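# Alignment statistics report: mapping uniqueness and the genomic-region
# breakdown of uniquely mapped reads.

#' Alignment statistics report
#'
#' Computes the percentage of uniquely mapped records and classifies
#' every unique read by the genomic region at its start position
#' (exonic, intronic or intergenic; a read starting in an exon and
#' running into an intron counts as exonic). Region percentages are
#' taken over the unique reads, uniqueness over all records.
#'
#' @param sample a `sample_alignment`.
#' @param index an `annotation_index`, or `NULL` (all reads intergenic).
#' @return An `alignment_stats` object with counts and percentages.
#' @export
alignment_report <- function(sample, index = NULL) {
  stopifnot(inherits(sample, "sample_alignment"))
  n_ex <- 0L; n_in <- 0L; n_ig <- 0L
  for (chrom in names(sample$reads_by_chrom)) {
    starts <- sample$reads_by_chrom[[chrom]]$start
    cls <- if (is.null(index)) {
      rep("intergenic", length(starts))
    } else {
      classify_position(index, chrom, starts)
    }
    n_ex <- n_ex + sum(cls == "exonic")
    n_in <- n_in + sum(cls == "intronic")
    n_ig <- n_ig + sum(cls == "intergenic")
  }
  n_u <- sample$n_unique
  n_t <- sample$n_total_records
  pct <- function(num, den) if (den == 0L) 0 else 100 * num / den
  structure(
    list(sample_id = sample$sample_id,
         n_total = n_t, n_unique = n_u, pct_unique = pct(n_u, n_t),
         n_exonic = n_ex, n_intronic = n_in, n_intergenic = n_ig,
         pct_exonic = pct(n_ex, n_u), pct_intronic = pct(n_in, n_u),
         pct_intergenic = pct(n_ig, n_u)),
    class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.alignment_stats <- function(x, ...) {
  c(sprintf("sample: %s", x$sample_id),
    sprintf("total_records: %d", x$n_total),
    sprintf("uniquely_mapped: %d", x$n_unique),
    sprintf("pct_unique: %.1f", x$pct_unique),
    sprintf("exonic: %d", x$n_exonic),
    sprintf("intronic: %d", x$n_intronic),
    sprintf("intergenic: %d", x$n_intergenic),
    sprintf("pct_exonic: %.1f", x$pct_exonic),
    sprintf("pct_intronic: %.1f", x$pct_intronic),
    sprintf("pct_intergenic: %.1f", x$pct_intergenic))
}

#' Write an alignment statistics report to disk
#'
#' @param stats an `alignment_stats` object.
#' @param path output path.
#' @param format `"text"` for a key: value report, `"tsv"` for a
#'   two-row table.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(stats, path, format = c("text", "tsv")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(format(stats), path)
  } else {
    keys <- c("sample_id", "n_total", "n_unique", "pct_unique", "n_exonic",
              "n_intronic", "n_intergenic", "pct_exonic", "pct_intronic",
              "pct_intergenic")
    vals <- c(stats$sample_id,
              sprintf("%d", c(stats$n_total, stats$n_unique)),
              sprintf("%.1f", stats$pct_unique),
              sprintf("%d", c(stats$n_exonic, stats$n_intronic,
                              stats$n_intergenic)),
              sprintf("%.1f", c(stats$pct_exonic, stats$pct_intronic,
                                stats$pct_intergenic)))
    writeLines(c(paste(keys, collapse = "\t"), paste(vals, collapse = "\t")),
               path)
  }
  invisible(path)
}
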