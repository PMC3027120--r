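# Gene annotation parsing and position classification.
#
# Internally every coordinate is 0-based half-open; conversions to the
# 1-based conventions of SAM and wiggle happen only at file boundaries.

new_gene_model <- function(gene_id, chrom, strand, exons) {
  stopifnot(nrow(exons) >= 1L, all(exons[, 1L] < exons[, 2L]),
            all(exons[, 1L] >= 0L))
  exons <- exons[order(exons[, 1L], exons[, 2L]), , drop = FALSE]
  union <- reduce_intervals(exons)
  structure(
    list(
      gene_id = gene_id,
      chrom = chrom,
      strand = strand,
      exons = exons,
      exon_union = union,
      exon_union_length = sum(union[, 2L] - union[, 1L]),
      span = c(min(exons[, 1L]), max(exons[, 2L]))
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), union %d bp\n",
              x$gene_id, x$chrom, x$span[1L], x$span[2L], x$strand,
              nrow(x$exons), x$exon_union_length))
  invisible(x)
}

# Build the chromosome-keyed index from a list of gene models. Duplicate
# gene ids are kept as distinct loci with a "_locus<k>" suffix.
build_annotation_index <- function(genes) {
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  dup <- ave(seq_along(ids), ids, FUN = seq_along)
  has_dup <- ids %in% ids[duplicated(ids)]
  for (i in seq_along(genes)) {
    if (has_dup[i]) genes[[i]]$gene_id <- paste0(ids[i], "_locus", dup[i])
  }
  chroms <- vapply(genes, function(g) g$chrom, character(1L))
  by_chrom <- split(genes, factor(chroms, levels = unique(chroms)))
  by_chrom <- lapply(by_chrom, function(gl) {
    starts <- vapply(gl, function(g) g$span[1L], numeric(1L))
    gl[order(starts)]
  })
  # Precomputed per-chromosome disjoint interval sets for fast position
  # classification: exon unions and gene spans.
  exonic <- lapply(by_chrom, function(gl) {
    reduce_intervals(do.call(rbind, lapply(gl, function(g) g$exon_union)))
  })
  genic <- lapply(by_chrom, function(gl) {
    reduce_intervals(do.call(rbind, lapply(gl, function(g) {
      cbind(g$span[1L], g$span[2L])
    })))
  })
  structure(
    list(genes_by_chrom = by_chrom, exonic_by_chrom = exonic,
         genic_by_chrom = genic),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  n <- sum(vapply(x$genes_by_chrom, length, integer(1L)))
  cat(sprintf("<annotation_index> %d gene(s) on %d chromosome(s)\n",
              n, length(x$genes_by_chrom)))
  for (chrom in names(x$genes_by_chrom)) {
    cat(sprintf("  %s: %d gene(s)\n", chrom, length(x$genes_by_chrom[[chrom]])))
  }
  invisible(x)
}

#' All gene models in an annotation index
#'
#' @param index an `annotation_index` from [parse_annotation()].
#' @return A flat list of gene models in chromosome, then start, order.
#' @export
index_genes <- function(index) {
  stopifnot(inherits(index, "annotation_index"))
  unlist(unname(index$genes_by_chrom), recursive = FALSE)
}

check_strand <- function(strand, lineno, path) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol '", strand[which(bad)[1L]], "' at line ",
         lineno[which(bad)[1L]], " of ", path, call. = FALSE)
  }
  strand
}

parse_bed12_genes <- function(path) {
  tl <- read_tab_lines(path)
  genes <- vector("list", length(tl$fields))
  for (i in seq_along(tl$fields)) {
    f <- tl$fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) < 12L) {
      stop("malformed BED12 line ", ln, " of ", path,
           ": expected 12 fields, found ", length(f), call. = FALSE)
    }
    chrom <- f[1L]
    start <- parse_int_field(f[2L], "BED12 chromStart", ln, path)
    check_strand(f[6L], ln, path)
    n_blocks <- parse_int_field(f[10L], "BED12 blockCount", ln, path)
    sizes <- parse_int_field(strsplit(f[11L], ",", fixed = TRUE)[[1L]],
                             "BED12 blockSizes", ln, path)
    offs <- parse_int_field(strsplit(f[12L], ",", fixed = TRUE)[[1L]],
                            "BED12 blockStarts", ln, path)
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop("blockSizes/blockStarts arity mismatch at line ", ln, " of ", path,
           ": blockCount=", n_blocks, " but ", length(sizes), " sizes and ",
           length(offs), " starts", call. = FALSE)
    }
    exons <- cbind(start + offs, start + offs + sizes)
    genes[[i]] <- new_gene_model(f[4L], chrom, f[6L], exons)
  }
  genes
}

parse_refflat_genes <- function(path) {
  tl <- read_tab_lines(path)
  genes <- vector("list", length(tl$fields))
  for (i in seq_along(tl$fields)) {
    f <- tl$fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) < 11L) {
      stop("malformed refFlat line ", ln, " of ", path,
           ": expected 11 fields, found ", length(f), call. = FALSE)
    }
    check_strand(f[4L], ln, path)
    n_exons <- parse_int_field(f[9L], "refFlat exonCount", ln, path)
    starts <- parse_int_field(strsplit(f[10L], ",", fixed = TRUE)[[1L]],
                              "refFlat exonStarts", ln, path)
    ends <- parse_int_field(strsplit(f[11L], ",", fixed = TRUE)[[1L]],
                            "refFlat exonEnds", ln, path)
    if (length(starts) != n_exons || length(ends) != n_exons) {
      stop("exonStarts/exonEnds arity mismatch at line ", ln, " of ", path,
           call. = FALSE)
    }
    genes[[i]] <- new_gene_model(f[1L], f[3L], f[4L], cbind(starts, ends))
  }
  genes
}

#' Parse a gene annotation file into a chromosome-keyed index
#'
#' Reads gene models from a BED12 file (one transcript per line, exon
#' structure in the block fields) or a refFlat-style tab-delimited file
#' (columns geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds with comma-terminated exon
#' lists). Coordinates are normalised to 0-based half-open internally.
#' Lines starting with `#` are skipped. Duplicate gene identifiers are
#' kept as distinct loci suffixed `_locus<k>`.
#'
#' @param path path to the annotation file.
#' @param format `"bed12"` or `"refflat"`.
#' @return An `annotation_index`: gene models grouped by chromosome, each
#'   list sorted by gene span start, with the per-gene exon union and its
#'   length (the RPKM denominator `L`) precomputed.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t500\tgeneA\t0\t+\t100\t500\t0\t2\t100,100\t0,300", bed)
#' idx <- parse_annotation(bed, "bed12")
#' index_genes(idx)[[1]]$exon_union_length  # 200
#' @export
parse_annotation <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  genes <- switch(format,
                  bed12 = parse_bed12_genes(path),
                  refflat = parse_refflat_genes(path))
  if (length(genes) == 0L) {
    stop("no gene records found in ", path, call. = FALSE)
  }
  build_annotation_index(genes)
}

#' Write an annotation index back to BED12
#'
#' Inverse of [parse_annotation()] for the BED12 dialect; exon blocks are
#' emitted from each model's stored exons.
#'
#' @param index an `annotation_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(index, path) {
  stopifnot(inherits(index, "annotation_index"))
  lines <- character(0L)
  for (gl in index$genes_by_chrom) {
    for (g in gl) {
      sizes <- g$exons[, 2L] - g$exons[, 1L]
      offs <- g$exons[, 1L] - g$span[1L]
      lines <- c(lines, paste(
        g$chrom, g$span[1L], g$span[2L], g$gene_id, 0L, g$strand,
        g$span[1L], g$span[2L], 0L, nrow(g$exons),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(offs, collapse = ","), ","),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 interval file
#'
#' Used for 3'-UTR interval annotations. Accepts 3 to 6 columns; missing
#' name/score/strand default to `"."`, `0`, `"+"`.
#'
#' @param path path to the BED file.
#' @return A data frame with columns `interval_id`, `chrom`, `start`,
#'   `end`, `score`, `strand` (0-based half-open coordinates).
#' @export
read_bed6 <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$fields) == 0L) {
    return(data.frame(interval_id = character(0L), chrom = character(0L),
                      start = integer(0L), end = integer(0L),
                      score = numeric(0L), strand = character(0L)))
  }
  rows <- lapply(seq_along(tl$fields), function(i) {
    f <- tl$fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) < 3L) {
      stop("malformed BED line ", ln, " of ", path, call. = FALSE)
    }
    data.frame(
      interval_id = if (length(f) >= 4L) f[4L] else ".",
      chrom = f[1L],
      start = parse_int_field(f[2L], "BED start", ln, path),
      end = parse_int_field(f[3L], "BED end", ln, path),
      score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0,
      strand = if (length(f) >= 6L) f[6L] else "+"
    )
  })
  do.call(rbind, rows)
}

#' Classify genomic positions as exonic, intronic or intergenic
#'
#' A position is exonic if it falls inside any gene's exon union, else
#' intronic if it falls inside any gene's span (i.e. in an intron), else
#' intergenic. Exonic takes precedence over intronic where genes overlap.
#' Unknown chromosomes classify as intergenic.
#'
#' @param index an `annotation_index`.
#' @param chrom chromosome name (scalar).
#' @param pos integer vector of 0-based positions.
#' @return Character vector in `{"exonic","intronic","intergenic"}`,
#'   one element per position.
#' @export
classify_position <- function(index, chrom, pos) {
  stopifnot(inherits(index, "annotation_index"), all(pos >= 0))
  out <- rep("intergenic", length(pos))
  ex <- index$exonic_by_chrom[[chrom]]
  gn <- index$genic_by_chrom[[chrom]]
  if (is.null(ex)) return(out)
  in_gene <- positions_in_intervals(pos, gn)
  in_exon <- positions_in_intervals(pos, ex)
  out[in_gene] <- "intronic"
  out[in_exon] <- "exonic"
  out
}
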