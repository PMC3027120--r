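test_that("exon read counting respects the half-open exon union", {
  sizes <- c(chr1 = 1000L)
  recs <- sam_record(c("r1", "r2", "r3"), 0, "chr1", c(151, 200, 201), 60,
                    "4M", nh = 1)
  aln <- load_exon_alignments(write_sam_fixture(recs, sizes), "s")
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg\t0\t+\t100\t200\t0\t1\t100,\t0,", bed)
  g <- index_genes(parse_annotation(bed, "bed12"))[[1L]]
  # starts 150 and 199 inside [100,200); 200 is exclusive
  expect_equal(count_exon_reads(aln, g), 2L)
  # no reads on the gene's chromosome
  g2 <- g; g2$chrom <- "chr9"
  expect_equal(count_exon_reads(aln, g2), 0L)
})

test_that("junction reads need both anchors on the gene's exons", {
  idx <- toy_annotation()
  geneA <- index_genes(idx)[[1L]]
  j_both <- data.frame(chrom = "chr1", left_start = 90L, left_end = 110L,
                       right_start = 390L, right_end = 410L, count = 5L)
  expect_equal(count_junction_reads(j_both, geneA), 5L)
  j_half <- data.frame(chrom = "chr1", left_start = 150L, left_end = 170L,
                       right_start = 900L, right_end = 920L, count = 3L)
  expect_equal(count_junction_reads(j_half, geneA), 0L)
  expect_equal(count_junction_reads(j_both[0L, ], geneA), 0L)
})

test_that("random exon and junction counts match brute-force oracles", {
  set.seed(31)
  sizes <- c(chr1 = 50000L)
  n <- 2000L
  starts1 <- sample(0:49000, n, replace = TRUE)
  recs <- sam_record(sprintf("r%04d", 1:n), 0, "chr1", starts1 + 1L, 60,
                     "4M", nh = 1)
  aln <- load_exon_alignments(write_sam_fixture(recs, sizes), "s")
  lines <- character(0L)
  for (g in 1:20) {
    n_ex <- sample(1:4, 1L)
    s <- sort(sample(0:48000, n_ex))
    e <- s + sample(100:800, n_ex, replace = TRUE)
    lines <- c(lines, paste("chr1", min(s), max(e), sprintf("g%02d", g), 0,
                            "+", min(s), max(e), 0, n_ex,
                            paste0(paste(e - s, collapse = ","), ","),
                            paste0(paste(s - min(s), collapse = ","), ","),
                            sep = "\t"))
  }
  bed <- tempfile(fileext = ".bed")
  writeLines(lines, bed)
  genes <- index_genes(parse_annotation(bed, "bed12"))
  jn <- data.frame(chrom = "chr1",
                   left_start = sample(0:48000, 50L, replace = TRUE))
  jn$left_end <- jn$left_start + 20L
  jn$right_start <- jn$left_end + sample(100:2000, 50L, replace = TRUE)
  jn$right_end <- jn$right_start + 20L
  jn$count <- sample(1:5, 50L, replace = TRUE)
  for (g in genes) {
    expect_equal(count_exon_reads(aln, g),
                 oracle_count_exon(starts1, g$exon_union))
    expect_equal(count_junction_reads(jn, g), oracle_count_junction(jn, g))
  }
})

test_that("the RPKM score is the depth- and length-normalised combination", {
  expect_equal(rpkm(100, 0, 1e6, 1000), 100)
  expect_equal(rpkm(0, 0, 1e6, 1000), 0)
  expect_equal(rpkm(50, 50, 2e6, 500), 100)
  expect_error(rpkm(1, 0, 0, 1000), "undefined")
  expect_error(rpkm(1, 0, 1e6, 0), "undefined")
  # scale invariance: doubling counts and N leaves the score unchanged
  expect_equal(rpkm(2 * 7, 2 * 3, 2 * 1e5, 250), rpkm(7, 3, 1e5, 250))
  # linear in the combined count, with exon/junction reads exchangeable
  expect_equal(rpkm(4, 6, 1e5, 250), rpkm(6, 4, 1e5, 250))
  expect_equal(rpkm(10, 0, 1e5, 250), 10 * rpkm(1, 0, 1e5, 250))
})

test_that("the expression matrix is deterministic per sample column", {
  idx <- toy_annotation()
  sizes <- c(chr1 = 1000L, chr2 = 1000L)
  recs <- sam_record(c("r1", "r2", "r3"), 0, "chr1", c(120, 150, 420), 60,
                    "4M", nh = 1)
  f <- write_sam_fixture(recs, sizes)
  s1 <- list(alignment = load_exon_alignments(f, "s1"), junctions = NULL)
  s2 <- list(alignment = load_exon_alignments(f, "s2"), junctions = NULL)
  em <- expression_matrix(list(s1, s2), idx)
  expect_equal(unname(em$rpkm[, "s1"]), unname(em$rpkm[, "s2"]))
  # geneB's chromosome has no reads -> zero score
  expect_equal(unname(em$rpkm["geneB", "s1"]), 0)
  expect_error(expression_matrix(list(s1, s1), idx), "duplicate sample ids")
})

test_that("custom intervals reproduce gene-mode scores exactly", {
  sizes <- c(chr1 = 1000L, chr2 = 1000L)
  set.seed(5)
  recs <- sam_record(sprintf("r%03d", 1:300), 0,
                     sample(c("chr1", "chr2"), 300, replace = TRUE),
                     sample(1:900, 300, replace = TRUE), 60, "4M", nh = 1)
  aln <- load_exon_alignments(write_sam_fixture(recs, sizes), "s1")
  idx <- toy_annotation()
  em_gene <- expression_matrix(list(list(alignment = aln)), idx)
  ivs <- do.call(rbind, lapply(index_genes(idx), function(g) {
    data.frame(interval_id = g$gene_id, chrom = g$chrom,
               start = g$exons[, 1L], end = g$exons[, 2L])
  }))
  em_iv <- expression_matrix(list(list(alignment = aln)),
                             intervals_to_index(ivs))
  expect_equal(em_iv$rpkm[rownames(em_gene$rpkm), , drop = FALSE],
               em_gene$rpkm)
})

test_that("fold changes are pseudocounted ratios of group means", {
  m <- matrix(c(10, 0, 5, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("t1", "c1")))
  fc <- fold_change(m, "t1", "c1", pseudocount = 0)
  expect_equal(unname(fc["g1"]), 2)
  fc2 <- fold_change(m, "t1", "c1")  # default pseudocount 0.5
  expect_equal(unname(fc2["g2"]), 1)  # all-zero gene is neutral
  expect_error(fold_change(m, "t1", "zz"), "unknown sample column")
  expect_error(fold_change(m, "t1", "t1"), "disjoint")
  set.seed(17)
  m2 <- matrix(runif(40, 0, 50), 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  fc3 <- fold_change(m2, c("s1", "s2"), c("s3", "s4"), pseudocount = 0.5)
  manual <- (rowMeans(m2[, 1:2]) + 0.5) / (rowMeans(m2[, 3:4]) + 0.5)
  expect_equal(fc3, manual)
})

test_that("the matrix serializes as spreadsheet-compatible TSV", {
  idx <- toy_annotation()
  sizes <- c(chr1 = 1000L)
  recs <- sam_record("r1", 0, "chr1", 120, 60, "4M", nh = 1)
  aln <- load_exon_alignments(write_sam_fixture(recs, sizes), "s1")
  em <- expression_matrix(list(list(alignment = aln)), idx)
  out <- tempfile(fileext = ".tsv")
  write_expression_matrix(em, out)
  lines <- readLines(out)
  expect_equal(lines[1L], "gene_id\ts1")
  tab <- utils::read.delim(out)
  expect_equal(tab$gene_id, rownames(em$rpkm))
  expect_equal(tab$s1, unname(round(em$rpkm[, 1L], 4L)))
})
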