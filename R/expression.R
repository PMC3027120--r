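# Gene-level expression scoring: exon and junction read counting and the
# RPKM/FPKM score combining both read classes.

#' Count exon reads for a gene
#'
#' Counts the unique reads whose start position lies within the gene's
#' exon union (overlapping exons counted once). The per-chromosome read
#' list is start-sorted, so each exon-union interval is resolved with two
#' binary searches rather than a scan.
#'
#' @param sample a `sample_alignment`.
#' @param gene a gene model from [parse_annotation()]/[index_genes()].
#' @return Integer read count.
#' @export
count_exon_reads <- function(sample, gene) {
  stopifnot(inherits(sample, "sample_alignment"))
  reads <- sample$reads_by_chrom[[gene$chrom]]
  if (is.null(reads) || nrow(reads) == 0L) return(0L)
  starts <- reads$start
  u <- gene$exon_union
  total <- 0L
  for (i in seq_len(nrow(u))) {
    total <- total + findInterval(u[i, 2L] - 0.5, starts) -
      findInterval(u[i, 1L] - 0.5, starts)
  }
  total
}

#' Count junction reads for a gene
#'
#' Sums the supporting-read counts of junctions on the gene's chromosome
#' whose left AND right anchor blocks each overlap (by at least one base)
#' some exon of the gene. Requiring both anchors prevents attributing
#' read-through junctions of neighbouring genes.
#'
#' @param junctions junction data frame from [load_junction_reads()].
#' @param gene a gene model.
#' @return Integer count (sum of junction read counts).
#' @export
count_junction_reads <- function(junctions, gene) {
  if (is.null(junctions) || nrow(junctions) == 0L) return(0L)
  j <- junctions[junctions$chrom == gene$chrom, , drop = FALSE]
  if (nrow(j) == 0L) return(0L)
  ex <- gene$exons
  left_ok <- rep(FALSE, nrow(j))
  right_ok <- rep(FALSE, nrow(j))
  for (i in seq_len(nrow(ex))) {
    s <- ex[i, 1L]; e <- ex[i, 2L]
    left_ok <- left_ok | (j$left_start < e & s < j$left_end)
    right_ok <- right_ok | (j$right_start < e & s < j$right_end)
  }
  sum(j$count[left_ok & right_ok])
}

#' RPKM/FPKM expression score
#'
#' The expression score for a gene combines exon-mapped reads `c_exon`
#' and junction-rescued reads `c_junction`:
#' `1e9 * (c_exon + c_junction) / (n_mapped * exon_length)`,
#' i.e. reads per kilobase of exon model per million mapped reads.
#'
#' @param c_exon unique exon read count.
#' @param c_junction unique junction read count.
#' @param n_mapped all uniquely mapped reads in the sample (exon +
#'   junction); must be at least 1.
#' @param exon_length summed exon-union length in bases; at least 1.
#' @return Numeric score (vectorised over its arguments).
#' @examples
#' rpkm(100, 0, 1e6, 1000)  # 100
#' @export
rpkm <- function(c_exon, c_junction, n_mapped, exon_length) {
  if (any(n_mapped == 0) || any(exon_length == 0)) {
    stop("RPKM undefined: n_mapped and exon_length must be positive",
         call. = FALSE)
  }
  1e9 * (c_exon + c_junction) / (n_mapped * exon_length)
}

#' Treat user-defined genomic intervals as scoring features
#'
#' Builds an annotation index whose "genes" are user intervals grouped by
#' `interval_id` (a multi-row group behaves like a multi-exon model), so
#' abundance scores can be computed for arbitrary genomic features with
#' the same machinery as annotated genes.
#'
#' @param intervals data frame with columns `interval_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `strand`.
#' @return An `annotation_index`.
#' @export
intervals_to_index <- function(intervals) {
  stopifnot(all(c("interval_id", "chrom", "start", "end") %in%
                  names(intervals)))
  if (is.null(intervals$strand)) intervals$strand <- "+"
  genes <- lapply(split(intervals, factor(intervals$interval_id,
                                          levels = unique(intervals$interval_id))),
                  function(d) {
                    stopifnot(length(unique(d$chrom)) == 1L)
                    new_gene_model(d$interval_id[1L], d$chrom[1L],
                                   d$strand[1L], cbind(d$start, d$end))
                  })
  build_annotation_index(unname(genes))
}

#' Compute the RPKM expression matrix across samples
#'
#' One column per sample, one row per gene (or user interval). For each
#' sample the mapped-read total `N` is its unique exon-read count plus
#' the sum of its junction read counts, so junction-rescued reads enter
#' both the numerator and the library size.
#'
#' @param samples a list, one element per sample, each a list with
#'   elements `alignment` (a `sample_alignment`) and optionally
#'   `junctions` (from [load_junction_reads()]).
#' @param index an `annotation_index` (from [parse_annotation()] or
#'   [intervals_to_index()]).
#' @return An `expression_matrix` object holding the `rpkm` matrix plus
#'   the per-cell exon/junction counts, per-sample `n_mapped` and
#'   per-gene `exon_length` used to compute it.
#' @export
expression_matrix <- function(samples, index) {
  stopifnot(length(samples) >= 1L, inherits(index, "annotation_index"))
  ids <- vapply(samples, function(s) s$alignment$sample_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  }
  genes <- index_genes(index)
  gene_ids <- vapply(genes, function(g) g$gene_id, character(1L))
  L <- vapply(genes, function(g) g$exon_union_length, numeric(1L))
  c_exon <- matrix(0L, length(genes), length(samples),
                   dimnames = list(gene_ids, ids))
  c_junc <- c_exon
  n_mapped <- numeric(length(samples))
  names(n_mapped) <- ids
  for (s in seq_along(samples)) {
    aln <- samples[[s]]$alignment
    jn <- samples[[s]]$junctions
    n_mapped[s] <- aln$n_unique + if (is.null(jn)) 0L else sum(jn$count)
    for (g in seq_along(genes)) {
      c_exon[g, s] <- count_exon_reads(aln, genes[[g]])
      c_junc[g, s] <- count_junction_reads(jn, genes[[g]])
    }
  }
  scores <- matrix(0, length(genes), length(samples),
                   dimnames = list(gene_ids, ids))
  for (s in seq_along(samples)) {
    scores[, s] <- rpkm(c_exon[, s], c_junc[, s], n_mapped[s], L)
  }
  structure(
    list(rpkm = scores, c_exon = c_exon, c_junction = c_junc,
         n_mapped = n_mapped, exon_length = stats::setNames(L, gene_ids)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d gene(s) x %d sample(s)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  print(utils::head(round(x$rpkm, 4L)))
  if (nrow(x$rpkm) > 6L) cat("...\n")
  invisible(x)
}

#' Write an expression matrix as spreadsheet-compatible TSV
#'
#' Genes as rows, a header row of sample ids, RPKM printed with four
#' decimal places; opens directly in spreadsheet software.
#'
#' @param em an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  m <- em$rpkm
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], sprintf("%.4f", m[i, ])),
                     collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Per-gene expression fold change between conditions
#'
#' Ratio of mean treatment RPKM to mean control RPKM, each offset by a
#' pseudocount to stabilise genes with zero expression.
#'
#' @param em an `expression_matrix` (or a plain RPKM matrix).
#' @param treatment_cols,control_cols disjoint, non-empty sets of sample
#'   (column) ids.
#' @param pseudocount score added to both means; default 0.5.
#' @return Named numeric vector of per-gene fold changes.
#' @export
fold_change <- function(em, treatment_cols, control_cols, pseudocount = 0.5) {
  m <- if (inherits(em, "expression_matrix")) em$rpkm else em
  all_cols <- c(treatment_cols, control_cols)
  unknown <- setdiff(all_cols, colnames(m))
  if (length(unknown) > 0L) {
    stop("unknown sample column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(treatment_cols) == 0L || length(control_cols) == 0L ||
      length(intersect(treatment_cols, control_cols)) > 0L) {
    stop("treatment and control column sets must be disjoint and non-empty",
         call. = FALSE)
  }
  t_mean <- rowMeans(m[, treatment_cols, drop = FALSE])
  c_mean <- rowMeans(m[, control_cols, drop = FALSE])
  (t_mean + pseudocount) / (c_mean + pseudocount)
}
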