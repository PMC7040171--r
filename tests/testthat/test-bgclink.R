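test_that("region loading handles BED and antiSMASH-style GenBank", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("contig1\t100\t900\tnrps", bed)
  regs <- load_regions(bed, "bed")
  expect_equal(nrow(regs), 1L)
  expect_equal(c(regs$start, regs$end), c(100L, 900L))
  expect_equal(regs$product_type, "nrps")
  expect_equal(regs$record_id, "contig1")

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(load_regions(empty, "bed")), 0L)

  gbk <- withr::local_tempfile(fileext = ".gbk")
  set.seed(73)
  rec <- genome_record("ctgZ", random_dna(3000, gc = 0.6))
  write_genbank(rec, gbk, extra_features = data.frame(
    record_id = "ctgZ", key = "region", start = c(100L, 1500L),
    end = c(1200L, 2800L), strand = "+",
    product = c("NRPS", "terpene"), region_number = c("1", "2"),
    stringsAsFactors = FALSE))
  regs2 <- load_regions(gbk, "antismash-genbank")
  expect_equal(nrow(regs2), 2L)
  expect_equal(regs2$product_type, c("NRPS", "terpene"))
  expect_equal(regs2$cluster_id, c("ctgZ_region1", "ctgZ_region2"))
  expect_equal(regs2$start, c(100L, 1500L))
})

test_that("gene similarity applies strict thresholds on all three axes", {
  # 8-case boundary grid around (1e-5, 30, 25)
  cases <- data.frame(
    evalue  = c(1e-6, 1e-5, 1e-6, 1e-6, 1e-5, 1e-5, 1e-6, 1e-4),
    ident   = c(35,   35,   30,   35,   30,   35,   30.01, 95),
    cov     = c(30,   30,   30,   25,   25,   25,   25.01, 99),
    expected = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  got <- gene_similar(cases$evalue, cases$ident, cases$cov)
  expect_equal(got, cases$expected)

  # relaxing any threshold never turns a true into a false
  relaxed <- similarity_rule(evalue_max = 1e-3, identity_min_percent = 20,
                             coverage_min_percent = 10)
  got_rel <- gene_similar(cases$evalue, cases$ident, cases$cov, relaxed)
  expect_true(all(got_rel[got]))
})

test_that("cluster similarity is the rounded fraction of found reference genes", {
  mk_hits <- function(refs) {
    n <- length(refs)
    data.frame(ref_gene = refs, query_gene = sprintf("q%d", seq_len(n)),
               evalue = rep(1e-20, n), identity_percent = rep(80, n),
               coverage_percent_shortest = rep(90, n),
               stringsAsFactors = FALSE)
  }
  refs <- c("r1", "r2", "r3", "r4")
  expect_equal(cluster_similarity(refs, mk_hits(refs)), 100L)
  expect_equal(cluster_similarity(refs, mk_hits(refs[1:3])), 75L)
  expect_equal(cluster_similarity(refs, mk_hits(character(0))), 0L)
  # one query gene may support several reference genes
  h <- mk_hits(c("r1", "r2")); h$query_gene <- "q1"
  expect_equal(cluster_similarity(refs, h), 50L)
  # failing hits do not count
  h2 <- mk_hits(refs); h2$identity_percent <- 30
  expect_equal(cluster_similarity(refs, h2), 0L)
  expect_error(cluster_similarity(character(0), mk_hits(refs)), "nonempty")
  # monotone non-decreasing in the hit set
  expect_lte(cluster_similarity(refs, mk_hits(refs[1:2])),
             cluster_similarity(refs, mk_hits(refs[1:3])))
})

make_assoc_fixture <- function() {
  regions <- data.frame(
    cluster_id = c("c1", "c2"), record_id = "ctg",
    start = c(100L, 2000L), end = c(1500L, 3500L),
    product_type = c("NRPS", "T2PKS"), stringsAsFactors = FALSE)
  intergenic <- data.frame(
    record_id = "ctg", start = c(400L, 2400L), end = c(600L, 2600L),
    flank_left_gene = NA, flank_right_gene = NA, sequence = "",
    stringsAsFactors = FALSE)
  motif_hits <- data.frame(
    record_id = "ctg",
    start = c(450L, 700L, 2500L, 5000L),  # 700 sits inside CDS space
    end = c(457L, 707L, 2507L, 5007L),
    strand = "+", identity = c(1, 1, 6 / 7, 1),
    site_sequence = "GTCAGCC", repeat_count_matched = 1L,
    stringsAsFactors = FALSE)
  sarp_genes <- data.frame(
    gene_id = c("s1", "s2", "s3", "s4"),
    record_id = "ctg",
    start = c(200L, 2100L, 2700L, 3000L),
    end = c(380L, 2380L, 2980L, 3300L),
    architecture = "small",
    identity_percent = c(44, 30, 35, 20),
    similarity_percent = c(60, 40, 45, 25),
    stringsAsFactors = FALSE)
  list(regions = regions, intergenic = intergenic,
       motif_hits = motif_hits, sarp_genes = sarp_genes)
}

test_that("associate counts cluster-situated SARP genes and intergenic motifs", {
  fx <- make_assoc_fixture()
  ann <- associate_clusters(fx$regions, fx$intergenic, fx$motif_hits,
                            fx$sarp_genes)
  c1 <- ann[ann$cluster_id == "c1", ]
  expect_equal(c1$sarp_gene_count, 1L)
  expect_equal(c1$motif_hit_count, 1L)  # the 700-hit is not intergenic
  expect_equal(c1$best_ref_similarity, 60)
  c2 <- ann[ann$cluster_id == "c2", ]
  expect_equal(c2$sarp_gene_count, 3L)  # three SARP genes in one cluster
  expect_equal(c2$best_ref_similarity, 45)
  expect_equal(c2$best_motif_identity, 6 / 7)
  # the hit at 5000 lies in no region
  kept <- attr(ann, "motif_hits")
  expect_equal(nrow(kept), 2L)
  expect_false(5000L %in% kept$start)
  # every kept hit is assigned to exactly one (non-overlapping) region
  expect_equal(anyDuplicated(paste(kept$start, kept$cluster_id)), 0L)
})

test_that("associate flags partial overlaps and validates record ids", {
  fx <- make_assoc_fixture()
  straddler <- data.frame(
    gene_id = "sx", record_id = "ctg", start = 1400L, end = 1700L,
    architecture = "small", identity_percent = 50, similarity_percent = 70,
    stringsAsFactors = FALSE)
  ann <- associate_clusters(fx$regions, fx$intergenic, fx$motif_hits,
                            rbind(fx$sarp_genes, straddler))
  c1 <- ann[ann$cluster_id == "c1", ]
  expect_equal(c1$sarp_gene_count, 2L)
  expect_equal(c1$sarp_partial_count, 1L)

  bad_hits <- fx$motif_hits
  bad_hits$record_id[1] <- "other_ctg"
  expect_error(
    associate_clusters(fx$regions, fx$intergenic, bad_hits, fx$sarp_genes),
    "other_ctg")
})

test_that("annotation TSV mirrors the screening-table column order", {
  fx <- make_assoc_fixture()
  ann <- associate_clusters(fx$regions, fx$intergenic, fx$motif_hits,
                            fx$sarp_genes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, fx$regions, path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(tab), c("cluster", "type", "known_cluster_similarity",
                             "localization", "sarp_gene_count",
                             "homology_I_S", "motif"))
  expect_equal(tab$motif, c("+", "+"))
  expect_equal(tab$homology_I_S[1], "44/60")
  expect_equal(tab$localization[1], "ctg:101-1500")
})
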