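test_that("GenBank round-trip preserves features, strands and coordinates", {
  rec <- toy_record()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  back <- read_genome(path, "genbank")
  expect_length(back, 1L)
  r2 <- back[[1]]
  expect_equal(r2$record_id, "toy1")
  expect_equal(r2$sequence, rec$sequence)
  expect_equal(nrow(r2$features), 2L)
  expect_equal(r2$features$gene_id, rec$features$gene_id)
  expect_equal(r2$features$start, rec$features$start)
  expect_equal(r2$features$end, rec$features$end)
  expect_equal(r2$features$strand, rec$features$strand)
})

test_that("GFF3+FASTA reading handles strands and rejects overrun features", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  gff <- file.path(dir, "g.gff3")
  set.seed(3)
  sq <- random_dna(300, gc = 0.5)
  writeLines(c(">ctgA", sq), fa)
  writeLines(c(
    "##gff-version 3",
    "ctgA\ttest\tCDS\t51\t110\t.\t-\t0\tID=gm1",
    "ctgA\ttest\tCDS\t151\t240\t.\t+\t0\tID=gp1"), gff)
  recs <- read_genome(gff, "gff3+fasta", fasta = fa)
  f <- recs[[1]]$features
  expect_equal(f$strand[f$gene_id == "gm1"], "-")
  expect_equal(f$start[f$gene_id == "gm1"], 50L)  # 1-based 51 -> 0-based 50

  writeLines(c(
    "##gff-version 3",
    "ctgA\ttest\tCDS\t251\t400\t.\t+\t0\tID=gbad"), gff)
  expect_error(read_genome(gff, "gff3+fasta", fasta = fa), "gbad")
})

test_that("sequence validation rejects stray ambiguity codes unless normalized", {
  expect_error(genome_record("x", "ACGRT"), "invalid")
  dir <- withr::local_tempdir()
  rec <- genome_record("x", "ACGTN")
  path <- file.path(dir, "amb.gbk")
  write_genbank(genome_record("x", "ACGTA"), path)
  # patch an R into the ORIGIN block
  txt <- readLines(path)
  txt <- sub("acgta", "acgra", txt)
  writeLines(txt, path)
  expect_error(read_genome(path, "genbank"), "invalid")
  rec2 <- read_genome(path, "genbank", normalize_ambiguous = TRUE)[[1]]
  expect_equal(rec2$sequence, "ACGNA")
})

test_that("intergenic extraction returns the interval complement of CDS", {
  set.seed(5)
  rec <- genome_record(
    "r", random_dna(500, gc = 0.5),
    data.frame(gene_id = c("a", "b"), start = c(100L, 300L),
               end = c(200L, 400L), strand = "+", stringsAsFactors = FALSE))
  ig <- extract_intergenic(rec, min_length = 1L)
  expect_equal(ig$start, c(0L, 200L, 400L))
  expect_equal(ig$end, c(100L, 300L, 500L))
  expect_equal(ig$flank_left_gene, c(NA, "a", "b"))
  expect_equal(ig$flank_right_gene, c("a", "b", NA))
  expect_equal(ig$sequence[2], substring(rec$sequence, 201, 300))

  # overlapping CDS leave no region between them
  rec2 <- genome_record(
    "r2", random_dna(500, gc = 0.5),
    data.frame(gene_id = c("a", "b"), start = c(100L, 200L),
               end = c(250L, 400L), strand = "+", stringsAsFactors = FALSE))
  ig2 <- extract_intergenic(rec2, 1L)
  expect_equal(ig2$start, c(0L, 400L))
  expect_equal(ig2$end, c(100L, 500L))

  # zero CDS: one region spanning the replicon
  rec3 <- genome_record("r3", random_dna(120, gc = 0.5))
  ig3 <- extract_intergenic(rec3, 1L)
  expect_equal(nrow(ig3), 1L)
  expect_equal(c(ig3$start, ig3$end), c(0L, 120L))
})

test_that("intergenic complement matches a per-base coverage oracle", {
  set.seed(17)
  for (trial in 1:20) {
    L <- sample(80:400, 1)
    n <- sample(0:6, 1)
    feats <- NULL
    if (n > 0) {
      s <- sort(sample(0:(L - 10), n))
      e <- pmin(L, s + sample(5:60, n, replace = TRUE))
      feats <- data.frame(gene_id = sprintf("g%d", seq_len(n)),
                          start = s, end = e, strand = "+",
                          stringsAsFactors = FALSE)
    }
    rec <- genome_record(sprintf("t%d", trial), random_dna(L, gc = 0.5), feats)
    ig <- extract_intergenic(rec, 1L)
    mask <- rep(FALSE, L)
    for (i in seq_len(nrow(ig))) mask[(ig$start[i] + 1):ig$end[i]] <- TRUE
    expect_identical(mask, brute_intergenic_mask(rec))
  }
})

test_that("promoter windows follow strand and clipping conventions", {
  set.seed(23)
  sq <- random_dna(2000, gc = 0.5)
  rec <- genome_record(
    "p", sq,
    data.frame(gene_id = "g", start = 1000L, end = 1600L, strand = "+",
               stringsAsFactors = FALSE))
  w <- promoter_window(rec, "g", 182L)
  expect_equal(c(w$start, w$end), c(818L, 1000L))
  expect_equal(w$sequence, substring(sq, 819, 1000))

  rec_m <- genome_record(
    "p", sq,
    data.frame(gene_id = "g", start = 1000L, end = 1600L, strand = "-",
               stringsAsFactors = FALSE))
  wm <- promoter_window(rec_m, "g", 100L)
  expect_equal(c(wm$start, wm$end), c(1600L, 1700L))
  expect_equal(wm$sequence, revcomp(substring(sq, 1601, 1700)))

  rec_e <- genome_record(
    "p", random_dna(400, gc = 0.5),
    data.frame(gene_id = "g", start = 50L, end = 300L, strand = "+",
               stringsAsFactors = FALSE))
  we <- promoter_window(rec_e, "g", 182L)
  expect_equal(c(we$start, we$end), c(0L, 50L))
  expect_equal(nchar(we$sequence), 50L)

  rec_n <- genome_record(
    "p", sq,
    data.frame(gene_id = c("up", "g"), start = c(500L, 1000L),
               end = c(900L, 1600L), strand = "+", stringsAsFactors = FALSE))
  wc <- promoter_window(rec_n, "g", 350L, clip_at_neighbor = TRUE)
  expect_equal(c(wc$start, wc$end), c(900L, 1000L))
  wnc <- promoter_window(rec_n, "g", 350L, clip_at_neighbor = FALSE)
  expect_equal(c(wnc$start, wnc$end), c(650L, 1000L))

  expect_error(promoter_window(rec, "nope", 100L), "not found")
})

test_that("promoter windows are reverse-complement symmetric", {
  set.seed(29)
  for (trial in 1:10) {
    L <- 600L
    sq <- random_dna(L, gc = 0.5)
    s <- sample(200:300, 1); e <- s + sample(50:150, 1)
    fwd <- genome_record("f", sq, data.frame(
      gene_id = "g", start = s, end = e, strand = "+",
      stringsAsFactors = FALSE))
    # the same gene on the reverse-complemented replicon
    rev <- genome_record("r", revcomp(sq), data.frame(
      gene_id = "g", start = L - e, end = L - s, strand = "-",
      stringsAsFactors = FALSE))
    wf <- promoter_window(fwd, "g", 100L, clip_at_neighbor = FALSE)
    wr <- promoter_window(rev, "g", 100L, clip_at_neighbor = FALSE)
    expect_equal(wf$sequence, wr$sequence)
  }
})

test_that("intergenic BED export is 0-based with flanking-gene names", {
  rec <- toy_record()
  path <- withr::local_tempfile(fileext = ".bed")
  intergenic_to_bed(extract_intergenic(rec, 1L), path)
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  expect_equal(bed$V2, c(0L, 200L, 400L))
  expect_equal(bed$V4, c(".|gA", "gA|gB", "gB|."))
  expect_true(all(bed$V6 == "."))
})
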