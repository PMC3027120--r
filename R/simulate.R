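# Deterministic synthetic-data generator: a toy genome annotation with
# multi-exon genes, exon reads (unique/multi-mapped/unmapped) with CIGAR
# strings, junction reads spanning exon boundaries, replicate samples,
# and an optional planted 3'-UTR coverage drop-out. Every output is a
# plain-text standard format so all downstream modules can be exercised
# end to end with no external data.

#' Simulation configuration
#'
#' Defaults emulate a small short-read RNA-seq experiment: 50-base reads,
#' roughly 10 percent of reads originating from exon-exon junctions, and
#' a few percent each of multi-mapped and unmapped records.
#'
#' @param seed master seed; all per-file pseudo-random streams derive
#'   from it, so one seed fixes every output byte.
#' @param n_chromosomes,chrom_length toy genome shape.
#' @param n_genes,exons_per_gene,exon_length,intron_length gene layout
#'   (bases); genes are placed without overlap and the layout must fit
#'   the chromosomes.
#' @param n_reads,read_length reads per sample and their length (bases).
#' @param frac_junction fraction of reads spanning exon-exon junctions
#'   (emitted as junction BED, not SAM).
#' @param frac_multimapped,frac_unmapped fractions of SAM records that
#'   are multi-mapped (`NH:i:2`, MAPQ 0) or unmapped (flag 0x4).
#' @param n_samples,n_treatment replicate samples; the last
#'   `n_treatment` samples form the treatment group.
#' @param dropout optional planted 3'-UTR coverage drop-out: a list with
#'   `gene_id`, `utr_fraction` (distal fraction of the 3'-UTR affected)
#'   and `amplitude` (probability a treatment read starting there is
#'   lost).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 100000L,
                       n_genes = 20L, exons_per_gene = 3L, exon_length = 200L,
                       intron_length = 300L, n_reads = 10000L,
                       read_length = 50L, frac_junction = 0.1,
                       frac_multimapped = 0.05, frac_unmapped = 0.05,
                       n_samples = 1L, n_treatment = 0L, dropout = NULL) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              frac_junction = frac_junction,
              frac_multimapped = frac_multimapped,
              frac_unmapped = frac_unmapped,
              n_samples = as.integer(n_samples),
              n_treatment = as.integer(n_treatment),
              dropout = dropout)
  stopifnot(cfg$n_chromosomes >= 1L, cfg$n_genes >= 1L,
            cfg$exons_per_gene >= 1L, cfg$exon_length >= 1L,
            cfg$intron_length >= 1L, cfg$n_reads >= 1L,
            cfg$read_length >= 1L, cfg$n_samples >= 1L,
            cfg$n_treatment >= 0L, cfg$n_treatment <= cfg$n_samples,
            cfg$frac_junction >= 0, cfg$frac_junction <= 1,
            cfg$frac_multimapped >= 0, cfg$frac_multimapped <= 1,
            cfg$frac_unmapped >= 0, cfg$frac_unmapped <= 1)
  if (cfg$frac_junction > 0 && cfg$exons_per_gene < 2L) {
    stop("junction reads require exons_per_gene >= 2", call. = FALSE)
  }
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout),
              all(c("gene_id", "utr_fraction", "amplitude") %in%
                    names(dropout)),
              dropout$utr_fraction > 0, dropout$utr_fraction <= 1,
              dropout$amplitude >= 0, dropout$amplitude <= 1)
  }
  structure(cfg, class = "sim_config")
}

# Deterministic gene layout: genes round-robin across chromosomes,
# placed left to right with a fixed inter-gene gap.
sim_gene_layout <- function(cfg) {
  gap <- 1000L
  margin <- 1000L
  span_len <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  chrom_of <- ((seq_len(cfg$n_genes) - 1L) %% cfg$n_chromosomes) + 1L
  per_chrom <- tabulate(chrom_of, cfg$n_chromosomes)
  need <- margin + max(per_chrom) * (span_len + gap) + cfg$read_length
  if (need > cfg$chrom_length) {
    stop("infeasible layout: ", max(per_chrom), " gene(s) of span ",
         span_len, " do not fit a chromosome of length ", cfg$chrom_length,
         call. = FALSE)
  }
  pos_in_chrom <- stats::ave(seq_len(cfg$n_genes), chrom_of, FUN = seq_along)
  start <- margin + (pos_in_chrom - 1L) * (span_len + gap)
  data.frame(
    gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
    chrom = sprintf("chr%d", chrom_of),
    start = start,
    end = start + span_len,
    strand = rep_len(c("+", "-"), cfg$n_genes))
}

sim_gene_models <- function(cfg, layout) {
  step <- cfg$exon_length + cfg$intron_length
  lapply(seq_len(nrow(layout)), function(i) {
    es <- layout$start[i] + (seq_len(cfg$exons_per_gene) - 1L) * step
    new_gene_model(layout$gene_id[i], layout$chrom[i], layout$strand[i],
                   cbind(es, es + cfg$exon_length))
  })
}

# Map per-gene exon-union offsets to genomic positions under the regular
# layout (exon index, then offset within the exon).
sim_offset_to_pos <- function(cfg, layout, gene_idx, offset) {
  step <- cfg$exon_length + cfg$intron_length
  exon_idx <- offset %/% cfg$exon_length
  within <- offset %% cfg$exon_length
  layout$start[gene_idx] + exon_idx * step + within
}

derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 48271 + stream * 16807) %% 2147483647)
}

#' Generate a synthetic dataset on disk
#'
#' Writes, under `out_dir`: `annotation.bed` (BED12 gene models),
#' `utrs.bed` (BED6; each gene's last exon as its 3'-UTR interval),
#' `chrom_sizes.tsv`, one `<sample>.sam` and `<sample>.junctions.bed`
#' per sample, and `truth.tsv` with the realised per-gene unique exon
#' and junction read counts per sample (the bookkeeping oracle for the
#' counting modules) plus the planted drop-out amplitude. Identical
#' seeds give byte-identical outputs. Read allocation is exact:
#' `round(frac * n_reads)` reads per class.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the file paths (`annotation`, `utrs`,
#'   `chrom_sizes`, `truth`, per-sample `sam` and `junctions`), the gene
#'   `layout` and the sample sheet (`samples` with `sample_id`,
#'   `group`).
#' @export
generate_synthetic_dataset <- function(config, out_dir) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  layout <- sim_gene_layout(cfg)  # errors before writing if infeasible
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  models <- sim_gene_models(cfg, layout)
  index <- build_annotation_index(models)
  ann_path <- file.path(out_dir, "annotation.bed")
  write_bed12(index, ann_path)

  step <- cfg$exon_length + cfg$intron_length
  utr_start <- layout$start + (cfg$exons_per_gene - 1L) * step
  utr_path <- file.path(out_dir, "utrs.bed")
  writeLines(paste(layout$chrom, utr_start, utr_start + cfg$exon_length,
                   layout$gene_id, 0L, layout$strand, sep = "\t"), utr_path)

  sizes_path <- file.path(out_dir, "chrom_sizes.tsv")
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  writeLines(paste(chroms, cfg$chrom_length, sep = "\t"), sizes_path)

  n_junc <- as.integer(round(cfg$frac_junction * cfg$n_reads))
  n_unm <- as.integer(round(cfg$frac_unmapped * cfg$n_reads))
  n_multi <- as.integer(round(cfg$frac_multimapped * cfg$n_reads))
  n_exon <- cfg$n_reads - n_junc - n_unm - n_multi
  if (n_exon < 0L) {
    stop("infeasible read fractions: junction + unmapped + multimapped ",
         "exceed 1", call. = FALSE)
  }

  L_union <- cfg$exons_per_gene * cfg$exon_length
  dg <- if (is.null(cfg$dropout)) NA_integer_ else {
    match(cfg$dropout$gene_id, layout$gene_id)
  }
  if (!is.null(cfg$dropout) && is.na(dg)) {
    stop("dropout gene_id not in the generated layout", call. = FALSE)
  }
  drop_len <- if (is.null(cfg$dropout)) 0L else {
    max(1L, as.integer(floor(cfg$dropout$utr_fraction * cfg$exon_length)))
  }
  drop_start <- if (is.null(cfg$dropout)) NA_integer_ else {
    utr_start[dg] + cfg$exon_length - drop_len
  }

  sample_ids <- sprintf("sample_%02d", seq_len(cfg$n_samples))
  group <- c(rep("control", cfg$n_samples - cfg$n_treatment),
             rep("treatment", cfg$n_treatment))
  seq_str <- strrep("A", cfg$read_length)
  qual_str <- strrep("I", cfg$read_length)
  cigar_str <- sprintf("%dM", cfg$read_length)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", chroms, "\tLN:", cfg$chrom_length))

  truth_rows <- list()
  sam_paths <- character(cfg$n_samples)
  bed_paths <- character(cfg$n_samples)

  for (s in seq_len(cfg$n_samples)) {
    set.seed(derive_seed(cfg$seed, s))
    # exon reads (unique)
    g_ex <- sample.int(cfg$n_genes, n_exon, replace = TRUE)
    off <- sample.int(L_union, n_exon, replace = TRUE) - 1L
    pos <- sim_offset_to_pos(cfg, layout, g_ex, off)
    if (group[s] == "treatment" && !is.null(cfg$dropout)) {
      in_drop <- g_ex == dg & pos >= drop_start
      lost <- in_drop & stats::runif(n_exon) < cfg$dropout$amplitude
      g_ex <- g_ex[!lost]; pos <- pos[!lost]
    }
    # multi-mapped records (excluded from unique counts downstream)
    g_mu <- sample.int(cfg$n_genes, n_multi, replace = TRUE)
    off_mu <- sample.int(L_union, n_multi, replace = TRUE) - 1L
    pos_mu <- sim_offset_to_pos(cfg, layout, g_mu, off_mu)
    # junction reads, anchored on adjacent exon pairs
    g_jn <- if (n_junc > 0L) sample.int(cfg$n_genes, n_junc, replace = TRUE)
            else integer(0L)
    pair <- if (n_junc > 0L) {
      sample.int(cfg$exons_per_gene - 1L, n_junc, replace = TRUE)
    } else integer(0L)

    n_kept <- length(pos)
    rec <- c(
      if (n_kept > 0L) paste(
        sprintf("r%06d", seq_len(n_kept)), 0L, layout$chrom[g_ex], pos + 1L,
        60L, cigar_str, "*", 0L, 0L, seq_str, qual_str, "NH:i:1", sep = "\t"),
      if (n_multi > 0L) paste(
        sprintf("m%06d", seq_len(n_multi)), 0L, layout$chrom[g_mu],
        pos_mu + 1L, 0L, cigar_str, "*", 0L, 0L, seq_str, qual_str, "NH:i:2",
        sep = "\t"),
      if (n_unm > 0L) paste(
        sprintf("u%06d", seq_len(n_unm)), 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
        seq_str, qual_str, sep = "\t"))
    rec <- rec[sample.int(length(rec))]
    sam_paths[s] <- file.path(out_dir, paste0(sample_ids[s], ".sam"))
    writeLines(c(header, rec), sam_paths[s])

    # aggregate junction reads per (gene, exon pair) into BED12 records
    bed_paths[s] <- file.path(out_dir,
                              paste0(sample_ids[s], ".junctions.bed"))
    a <- cfg$read_length %/% 2L
    b <- cfg$read_length - a
    if (n_junc > 0L) {
      key <- paste(g_jn, pair)
      agg <- table(key)
      parts <- strsplit(names(agg), " ", fixed = TRUE)
      jg <- as.integer(vapply(parts, `[`, character(1L), 1L))
      jp <- as.integer(vapply(parts, `[`, character(1L), 2L))
      left_end <- layout$start[jg] + (jp - 1L) * step + cfg$exon_length
      left_start <- left_end - a
      right_start <- layout$start[jg] + jp * step
      right_end <- right_start + b
      ord <- order(match(layout$chrom[jg], chroms), left_start,
                   method = "radix")
      lines <- paste(layout$chrom[jg], left_start, right_end,
                     sprintf("JUNC%05d", seq_along(jg)), as.integer(agg),
                     "+", left_start, right_end, 0L, 2L,
                     paste(a, b, sep = ","),
                     paste(0L, right_start - left_start, sep = ","),
                     sep = "\t")[ord]
      writeLines(lines, bed_paths[s])
      j_count <- tapply(as.integer(agg), jg, sum)
      junc_per_gene <- integer(cfg$n_genes)
      junc_per_gene[as.integer(names(j_count))] <- as.integer(j_count)
    } else {
      writeLines(character(0L), bed_paths[s])
      junc_per_gene <- integer(cfg$n_genes)
    }

    exon_per_gene <- tabulate(g_ex, cfg$n_genes)
    truth_rows[[s]] <- data.frame(
      sample_id = sample_ids[s], gene_id = layout$gene_id,
      exon_reads = exon_per_gene, junction_reads = junc_per_gene,
      dropout_amplitude = if (!is.null(cfg$dropout) &&
                              group[s] == "treatment") {
        ifelse(seq_len(cfg$n_genes) == dg, cfg$dropout$amplitude, 0)
      } else 0)
  }

  truth <- do.call(rbind, truth_rows)
  truth_path <- file.path(out_dir, "truth.tsv")
  writeLines(c(paste(names(truth), collapse = "\t"),
               do.call(paste, c(truth, sep = "\t"))), truth_path)

  invisible(list(
    annotation = ann_path, utrs = utr_path, chrom_sizes = sizes_path,
    truth = truth_path,
    sam = stats::setNames(sam_paths, sample_ids),
    junctions = stats::setNames(bed_paths, sample_ids),
    layout = layout,
    samples = data.frame(sample_id = sample_ids, group = group),
    config = cfg))
}
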