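write_simple_hits <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

test_that("domain-hit parsing normalizes accessions and filters by e-value", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_simple_hits(list(
    c("p1", "PF00486.27", "1e-30", "5", "60"),
    c("p1", "PF03704.16", "1e-12", "70", "200"),
    c("p2", "PF00931", "0.5", "10", "100")), path)
  hits <- parse_domain_hits(path, evalue_cutoff = 1e-5)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$profile_id, c("PF00486", "PF03704"))
  expect_equal(attr(hits, "n_skipped"), 0L)
  # idempotent under re-normalization
  expect_identical(normalize_accession(hits$profile_id), hits$profile_id)
})

test_that("malformed rows are skipped with a counted warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_simple_hits(list(
    c("p1", "PF00486.27", "1e-30", "5", "60"),
    c("p2", "PF03704", "not_a_number", "1", "10"),
    c("p3", "PF03704", "1e-9", "60", "5")), path)  # from > to
  expect_warning(hits <- parse_domain_hits(path), "2 malformed")
  expect_equal(nrow(hits), 1L)
  expect_equal(attr(hits, "n_skipped"), 2L)
})

test_that("empty tables parse to empty hit frames without warnings", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  expect_no_warning(hits <- parse_domain_hits(path))
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "n_skipped"), 0L)
})

test_that("hmmscan domtblout layout is accepted", {
  path <- withr::local_tempfile(fileext = ".domtbl")
  line <- paste("Trans_reg_C", "PF00486.27", "111", "prot7", "-", "280",
                "2.1e-28", "99.1", "0.1", "1", "2", "1.3e-30", "4.1e-27",
                "95.2", "0.1", "2", "110", "12", "118", "10", "120",
                "0.98", "winged HTH domain")
  writeLines(c("# comment line", line), path)
  hits <- parse_domain_hits(path)
  expect_equal(hits$protein_id, "prot7")
  expect_equal(hits$profile_id, "PF00486")
  expect_equal(hits$evalue, 4.1e-27)
  expect_equal(c(hits$ali_from, hits$ali_to), c(12L, 118L))
})

test_that("architecture classification matches the decision table", {
  expect_equal(classify_architecture(c("PF00486", "PF03704")), "small")
  expect_equal(classify_architecture(c("PF00486", "PF03704", "PF13424")),
               "large")
  expect_equal(classify_architecture(c("PF00486", "PF03704", "PF00931")),
               "large")
  expect_equal(classify_architecture("PF03704"), "btad_only")
  expect_equal(classify_architecture("PF00486"), "hth_only")
  expect_equal(classify_architecture(character(0)), "incomplete")
  expect_equal(classify_architecture("PF99999"), "incomplete")
  # the BTAD accession typo alias is accepted
  expect_equal(classify_architecture(c("PF00486.27", "PF93704.16")), "small")
})

test_that("census counts, shares and rounding recompute from populations", {
  pop <- simulate_census(data.frame(
    group = c("Streptomycetales", "Streptomycetales", "Pseudonocardiales",
              "Pseudonocardiales", "Other"),
    architecture = c("small", "large", "small", "large", "small"),
    count = c(60, 40, 31, 69, 50), stringsAsFactors = FALSE))
  tab <- census(pop, "taxon_order")
  expect_equal(sum(tab$total), nrow(pop))
  strep <- tab[tab$taxon_order == "Streptomycetales", ]
  expect_equal(strep$total, 100L)
  expect_equal(strep$small, 60L)
  expect_equal(strep$pct_small, 60)
  expect_equal(strep$pct_of_all, 40)  # 100/250
  # class counts partition each row total
  arch_cols <- c("small", "large", "btad_only", "hth_only", "incomplete")
  expect_equal(rowSums(tab[, arch_cols]), tab$total,
               ignore_attr = TRUE)
  # empty group handling
  empty <- census(simulate_census(NULL), "taxon_order")
  expect_equal(nrow(empty), 0L)
})

test_that("genome-denominator census marks a genome positive once", {
  prot <- data.frame(
    genome_id = c("g1", "g1", "g2", "g3"),
    taxon_genus = "Streptomyces",
    architecture = c("small", "large", "incomplete", "btad_only"),
    stringsAsFactors = FALSE)
  tab <- census(prot, "taxon_genus", denominator = "genomes")
  expect_equal(tab$total, 3L)
  expect_equal(tab$positive, 2L)  # g2 has only an incomplete protein
  expect_equal(tab$pct_positive, 67)
})

test_that("prevalence percentages use round-half-up", {
  gt <- data.frame(
    genus = c(rep("A", 625), rep("B", 72), rep("C", 10)),
    sarp_positive = c(rep(TRUE, 611), rep(FALSE, 14),
                      rep(TRUE, 72), rep(FALSE, 10)),
    stringsAsFactors = FALSE)
  out <- genome_prevalence(gt)
  expect_equal(out$percent[out$genus == "A"], 98)
  expect_equal(out$percent[out$genus == "B"], 100)
  expect_equal(out$percent[out$genus == "C"], 0)
})

test_that("pairwise similarity is symmetric, reflexive and oracle-consistent", {
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  expect_equal(pairwise_similarity(a, a)$identity_percent, 100)
  expect_equal(pairwise_similarity(a, a)$similarity_percent, 100)

  # one substitution with a positive BLOSUM62 score: V->I scores 3
  r <- pairwise_similarity("MKLVR", "MKLIR")
  expect_equal(r$identity_percent, 80)
  expect_equal(r$similarity_percent, 100)

  set.seed(61)
  for (i in 1:10) {
    x <- random_protein(sample(8:30, 1))
    y <- random_protein(sample(8:30, 1))
    rx <- pairwise_similarity(x, y)
    ry <- pairwise_similarity(y, x)
    expect_equal(rx$identity_percent, ry$identity_percent)
    expect_equal(rx$similarity_percent, ry$similarity_percent)
    expect_lte(rx$identity_percent, rx$similarity_percent + 1e-9)
    expect_lte(rx$similarity_percent, 100)
  }

  # optimal score agrees with an independent affine-gap DP oracle
  submat <- get(data("BLOSUM62", package = "Biostrings",
                     envir = environment()))
  set.seed(67)
  for (i in 1:8) {
    x <- random_protein(sample(4:12, 1))
    y <- random_protein(sample(4:12, 1))
    got <- pairwise_similarity(x, y)$score
    expect_equal(got, gotoh_score(x, y, submat))
  }

  expect_error(pairwise_similarity("", "MK"), "nonempty")
})

test_that("similarity_to_reference reports one row per query", {
  set.seed(71)
  ref <- random_protein(50)
  qs <- list(q1 = ref, q2 = random_protein(50))
  out <- similarity_to_reference(qs, ref)
  expect_equal(out$protein_id, c("q1", "q2"))
  expect_equal(out$identity_percent[1], 100)
  expect_true(out$identity_percent[2] < 100)
})
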