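test_that("loading keeps unique mapped reads and counts all records", {
  sizes <- c(chr1 = 1000L)
  recs <- c(sam_record("r1", 0, "chr1", 51, 60, "4M", nh = 1),
            sam_record("r2", 0, "chr1", 11, 60, "4M", nh = 1),
            sam_record("r3", 0, "chr1", 31, 60, "4M", nh = 1),
            sam_record("u1", 4, "*", 0, 0, "*"))
  aln <- load_exon_alignments(write_sam_fixture(recs, sizes), "s")
  expect_equal(aln$n_total_records, 4L)
  expect_equal(aln$n_unique, 3L)
  # start-sorted, 0-based
  expect_equal(aln$reads_by_chrom$chr1$start, c(10L, 30L, 50L))

  empty <- write_sam_fixture(character(0L), sizes)
  e <- load_exon_alignments(empty, "e")
  expect_equal(e$n_total_records, 0L)
  expect_equal(e$n_unique, 0L)
})

test_that("uniqueness follows NH tag with MAPQ fallback", {
  expect_true(is_unique(0L, 0L, nh = 1L))    # NH takes precedence
  expect_false(is_unique(0L, 37L, nh = 3L))
  expect_true(is_unique(0L, 37L, nh = NA))
  expect_false(is_unique(0L, 0L, nh = NA))
})

test_that("unique counts match a brute-force flag scan on 1000 records", {
  set.seed(7)
  sizes <- c(chr1 = 100000L)
  n <- 1000L
  multi <- sample(n, 200L)
  nh <- ifelse(seq_len(n) %in% multi, 2L, 1L)
  recs <- sam_record(sprintf("r%04d", 1:n), 0, "chr1",
                     sample(1:99000, n, replace = TRUE),
                     ifelse(nh == 1L, 60L, 0L), "4M", nh = nh)
  aln <- load_exon_alignments(write_sam_fixture(recs, sizes), "s")
  expect_equal(aln$n_unique, sum(nh == 1L))
  expect_equal(aln$n_unique, 800L)
  expect_equal(aln$n_total_records, n)

  # secondary records never count as unique
  recs2 <- c(recs, sam_record("sec", 256, "chr1", 5, 60, "4M", nh = 1))
  aln2 <- load_exon_alignments(write_sam_fixture(recs2, sizes), "s")
  expect_equal(aln2$n_unique, 800L)
  expect_equal(aln2$n_total_records, n + 1L)
})

test_that("junction BED12 blocks become anchor intervals with score counts", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t90\t410\tJUNC1\t5\t+\t90\t410\t0\t2\t20,20\t0,300", bed)
  j <- load_junction_reads(bed)
  expect_equal(j$left_start, 90L)
  expect_equal(j$left_end, 110L)
  expect_equal(j$right_start, 390L)
  expect_equal(j$right_end, 410L)
  expect_equal(j$count, 5L)
  expect_equal(load_junction_reads(bed, count_mode = "one")$count, 1L)

  three_blocks <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tJ\t1\t+\t0\t100\t0\t3\t10,10,10\t0,40,90",
             three_blocks)
  expect_error(load_junction_reads(three_blocks), "line 1.*3 blocks")
})

test_that("BED6 junctions need six-column mode for degenerate anchors", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t400\tj\t1\t+", bed)
  expect_error(load_junction_reads(bed), "no blocks to anchor")
  j <- load_junction_reads(bed, six_column = TRUE)
  expect_equal(j$left_start, 100L)
  expect_equal(j$left_end, 101L)
  expect_equal(j$right_start, 399L)
  expect_equal(j$right_end, 400L)
  expect_equal(j$count, 1L)

  empty <- tempfile(fileext = ".bed")
  writeLines(character(0L), empty)
  expect_equal(nrow(load_junction_reads(empty)), 0L)
})

test_that("coordinate sort is correct, stable and idempotent", {
  sizes <- c(chr1 = 1000L, chr2 = 1000L)
  # equal-coordinate records must keep input order (stability)
  recs <- c(sam_record("a", 0, "chr2", 10, 60, "4M"),
            sam_record("b", 0, "chr1", 20, 60, "4M"),
            sam_record("c", 0, "chr1", 20, 60, "4M"),
            sam_record("d", 0, "chr1", 5, 60, "4M"))
  f <- write_sam_fixture(recs, sizes)
  out <- tempfile(fileext = ".sam")
  sort_alignment_file(f, out)
  got <- readLines(out)
  body <- got[!startsWith(got, "@")]
  qn <- vapply(strsplit(body, "\t"), `[`, character(1L), 1L)
  expect_equal(qn, c("d", "b", "c", "a"))
  # idempotence: sorting the sorted file reproduces it
  out2 <- tempfile(fileext = ".sam")
  sort_alignment_file(out, out2)
  expect_identical(readLines(out2), readLines(out))
})

test_that("shuffled records sort like an oracle sort of key triples", {
  set.seed(11)
  sizes <- c(chr1 = 10000L, chr2 = 10000L, chr3 = 10000L)
  n <- 500L
  chrom <- sample(names(sizes), n, replace = TRUE)
  pos <- sample(1:9000, n, replace = TRUE)
  recs <- sam_record(sprintf("r%03d", 1:n), 0, chrom, pos, 60, "4M")
  f <- write_sam_fixture(recs, sizes)
  out <- tempfile(fileext = ".sam")
  sort_alignment_file(f, out)
  body <- readLines(out)
  body <- body[!startsWith(body, "@")]
  # oracle: full sort of (chrom_index, start, input_index)
  key <- order(match(chrom, names(sizes)), pos, seq_len(n))
  expect_identical(body, recs[key])
})

test_that("merging sorted files yields a sorted whole and checks headers", {
  sizes <- c(chr1 = 1000L)
  f1 <- write_sam_fixture(sam_record(c("a1", "a2", "a3"), 0, "chr1",
                                     c(10, 30, 50), 60, "4M"), sizes)
  f2 <- write_sam_fixture(sam_record(c("b1", "b2", "b3"), 0, "chr1",
                                     c(20, 30, 60), 60, "4M"), sizes)
  out <- tempfile(fileext = ".sam")
  merge_alignment_files(c(f1, f2), out)
  body <- readLines(out)
  body <- body[!startsWith(body, "@")]
  qn <- vapply(strsplit(body, "\t"), `[`, character(1L), 1L)
  # 6 records in coordinate order; equal keys keep file order (a2 < b2)
  expect_equal(qn, c("a1", "b1", "a2", "b2", "a3", "b3"))

  f3 <- write_sam_fixture(sam_record("c", 0, "chrX", 1, 60, "4M"),
                          c(chrX = 500L))
  expect_error(merge_alignment_files(c(f1, f3), tempfile(fileext = ".sam")),
               "incompatible reference dictionaries")
})

test_that("alignment content is invariant under record order", {
  set.seed(23)
  sizes <- c(chr1 = 5000L, chr2 = 5000L)
  n <- 200L
  recs <- sam_record(sprintf("r%03d", 1:n), 0,
                     sample(names(sizes), n, replace = TRUE),
                     sample(1:4900, n, replace = TRUE), 60, "4M",
                     nh = sample(1:2, n, replace = TRUE))
  a1 <- load_exon_alignments(write_sam_fixture(recs, sizes), "s")
  a2 <- load_exon_alignments(write_sam_fixture(sample(recs), sizes), "s")
  expect_equal(a2$n_unique, a1$n_unique)
  for (chrom in names(a1$reads_by_chrom)) {
    expect_equal(a2$reads_by_chrom[[chrom]]$start,
                 a1$reads_by_chrom[[chrom]]$start)
  }
  # load(sort(x)) gives the same content as load(x)
  f <- write_sam_fixture(sample(recs), sizes)
  fs <- tempfile(fileext = ".sam")
  sort_alignment_file(f, fs)
  a3 <- load_exon_alignments(fs, "s")
  expect_equal(a3$n_unique, a1$n_unique)
  for (chrom in names(a1$reads_by_chrom)) {
    expect_equal(a3$reads_by_chrom[[chrom]]$start,
                 a1$reads_by_chrom[[chrom]]$start)
  }
})
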