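# Synthetic-genome simulator with planted ground truth.
#
# The generator emits the full set of screening inputs -- annotated
# GenBank genome, BGC region BED, domain-hit TSV, SARP protein FASTA and
# a synthetic reference SARP -- with every planted element recorded in a
# truth table, so the whole pipeline is testable without downloads. The
# stated world: Streptomyces-like GC of 0.72, 900 bp genes, 150 bp
# intergenic gaps, clusters of 4 genes, a 280-residue reference SARP.
# All randomness flows from one integer seed through R's RNG; the same
# seed gives byte-identical files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# one GC-rich codon per residue, for reverse-translating planted SARPs
CODON_OF <- c(A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC",
              Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
              L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCG",
              S = "TCC", T = "ACC", W = "TGG", Y = "TAC", V = "GTC")

#' Random i.i.d. background DNA
#'
#' @param n bases
#' @param gc GC fraction
#' @return DNA string
#' @export
random_dna <- function(n, gc = 0.72) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Synthetic reference SARP protein
#'
#' A random 280-residue sequence standing in for a reference SARP
#' activator; it is synthetic, not any real protein, and only its
#' alignment relationships to the simulator's mutated copies carry
#' meaning.
#'
#' @param length residues
#' @return amino-acid string
#' @export
synthetic_reference_sarp <- function(length = 280L) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

# Mutate a fraction of residues to BLOSUM62-nonpositive replacements, so
# that the gapless global alignment to the original has identity =
# similarity = target_percent by construction.
mutate_to_similarity <- function(seq, target_percent) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  k <- round_half_up(n * (1 - target_percent / 100))
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  submat <- get(data("BLOSUM62", package = "Biostrings",
                     envir = environment()))
  for (p in pos) {
    cand <- AA20[submat[chars[p], AA20] <= 0 & AA20 != chars[p]]
    chars[p] <- sample(cand, 1L)
  }
  paste(chars, collapse = "")
}

# concrete instance of an IUPAC consensus with exactly `mismatches`
# positions mutated to bases OUTSIDE the allowed set, so the planted
# identity is (span - mismatches)/span exactly
concretize_motif <- function(consensus, mismatches = 0L) {
  sets <- iupac_matcher(consensus)
  bases <- vapply(sets, function(s) s[sample.int(length(s), 1L)],
                  character(1))
  if (mismatches > 0L) {
    pos <- sample.int(length(sets), mismatches)
    for (p in pos) {
      outside <- setdiff(c("A", "C", "G", "T"), sets[[p]])
      if (!length(outside)) {
        stop("cannot plant a mismatch at an N consensus position",
             call. = FALSE)
      }
      bases[p] <- outside[sample.int(length(outside), 1L)]
    }
  }
  paste(bases, collapse = "")
}

# Remove chance motif occurrences from an intergenic gap so that planted
# sites are the only ones reaching the scan threshold there. Windows equal
# to a protected (planted) interval are kept; other qualifying windows get
# one base outside all protected spans mutated, iterating until clean.
scrub_gap <- function(seq_chars, gs, ge, model, min_identity,
                      protected = NULL) {
  if (ge - gs < model$span) return(seq_chars)
  for (iter in 1:50) {
    gseq <- paste(seq_chars[(gs + 1L):ge], collapse = "")
    hits <- scan_motifs(gseq, model, "both", min_identity = min_identity)
    if (!nrow(hits)) return(seq_chars)
    hits$abs_start <- gs + hits$start
    hits$abs_end <- gs + hits$end
    is_planted <- rep(FALSE, nrow(hits))
    if (!is.null(protected) && nrow(protected)) {
      for (k in seq_len(nrow(protected))) {
        is_planted <- is_planted | (hits$abs_start == protected$start[k] &
                                      hits$abs_end == protected$end[k])
      }
    }
    hits <- hits[!is_planted, , drop = FALSE]
    if (!nrow(hits)) return(seq_chars)
    for (k in seq_len(nrow(hits))) {
      cand <- setdiff(hits$abs_start[k]:(hits$abs_end[k] - 1L),
                      if (!is.null(protected) && nrow(protected))
                        unlist(mapply(seq, protected$start,
                                      protected$end - 1L,
                                      SIMPLIFY = FALSE))
                      else integer(0))
      if (!length(cand)) next
      p <- cand[sample.int(length(cand), 1L)]
      cur <- seq_chars[p + 1L]
      seq_chars[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seq_chars
}

ARCH_PROFILES <- list(
  small = c("PF00486", "PF03704"),
  large = c("PF00486", "PF03704", "PF13424"),
  btad_only = c("PF03704"),
  hth_only = c("PF00486"),
  incomplete = c("PF99999"))

#' Simulate a genome with planted clusters, motifs and SARP genes
#'
#' Builds one replicon of `n_clusters` gene clusters (each
#' `genes_per_cluster` CDS of `gene_length` bp separated by
#' `intergenic_length` bp gaps), plants consensus-motif instances with a
#' chosen number of mismatches into intergenic gaps of designated
#' clusters, and plants SARP genes whose protein products are mutated
#' copies of a synthetic reference at chosen similarity levels. Writes
#' GenBank, region BED, domain-hit TSV and protein FASTA files that parse
#' under the package's own readers, plus a truth table.
#'
#' @param outdir output directory (created)
#' @param n_clusters number of clusters
#' @param genes_per_cluster CDS per cluster
#' @param gc_fraction background GC content (0.72, Streptomyces-like)
#' @param planted_motifs data frame with columns `cluster`, `mismatches`
#'   (0-7), `strand`; one motif planted per row into an intergenic gap of
#'   that cluster
#' @param planted_sarps data frame with columns `cluster`, `architecture`,
#'   `similarity_percent`; the first gene of the cluster becomes a SARP
#'   CDS
#' @param consensus motif consensus planted
#' @param gene_length,intergenic_length layout parameters (bases)
#' @param scrub_min_identity chance occurrences of the consensus in
#'   intergenic gaps reaching this scan identity are mutated away, so the
#'   planted sites are the only motifs at or above it (`NULL` disables
#'   scrubbing); default 6/7, matching the default scan threshold
#' @param seed integer seed driving all randomness
#' @return invisibly, a list with file `paths` and the `truth` table
#'   (planted motif coordinates/strands/mismatches, planted SARP ids with
#'   architectures and similarities, cluster intervals, the seed)
#' @export
simulate_genome <- function(outdir,
                            n_clusters = 3L,
                            genes_per_cluster = 4L,
                            gc_fraction = 0.72,
                            planted_motifs = data.frame(
                              cluster = c(1L, 2L), mismatches = c(0L, 0L),
                              strand = c("+", "+")),
                            planted_sarps = data.frame(
                              cluster = c(1L, 2L, 3L),
                              architecture = c("small", "small", "large"),
                              similarity_percent = c(60, 40, 60)),
                            consensus = "GTCAGSS",
                            gene_length = 900L,
                            intergenic_length = 150L,
                            scrub_min_identity = 6 / 7,
                            seed = 42L) {
  stopifnot(n_clusters >= 1L, genes_per_cluster >= 2L)
  if (!is.null(planted_motifs) && nrow(planted_motifs)) {
    stopifnot(all(planted_motifs$cluster %in% seq_len(n_clusters)),
              all(planted_motifs$mismatches >= 0L),
              all(planted_motifs$mismatches <= nchar(consensus)))
  }
  if (!is.null(planted_sarps) && nrow(planted_sarps)) {
    stopifnot(all(planted_sarps$cluster %in% seq_len(n_clusters)),
              all(planted_sarps$architecture %in% names(ARCH_PROFILES)))
  }
  set.seed(as.integer(seed))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  reference <- synthetic_reference_sarp()

  # layout: lead gap, then clusters of genes with intergenic gaps,
  # separated by 500 bp; cluster region = genes +/- 50 bp margin
  lead <- 300L
  sep <- 500L
  margin <- 50L
  pos <- lead
  genes <- list()
  clusters <- list()
  sarp_rows <- list()
  proteins <- list()
  for (ci in seq_len(n_clusters)) {
    gstarts <- integer(genes_per_cluster)
    gends <- integer(genes_per_cluster)
    gids <- character(genes_per_cluster)
    sarp_here <- if (!is.null(planted_sarps))
      which(planted_sarps$cluster == ci) else integer(0)
    for (gi in seq_len(genes_per_cluster)) {
      gid <- sprintf("c%d_g%d", ci, gi)
      glen <- gene_length
      if (gi == 1L && length(sarp_here)) {
        ps <- planted_sarps[sarp_here[1], ]
        gid <- sprintf("c%d_sarp", ci)
        prot <- mutate_to_similarity(reference, ps$similarity_percent)
        glen <- 3L * nchar(prot) + 6L  # ATG ... stop
        proteins[[gid]] <- prot
        for (pf in ARCH_PROFILES[[ps$architecture]]) {
          sarp_rows[[length(sarp_rows) + 1L]] <- data.frame(
            protein_id = gid, profile_id = paste0(pf, ".1"),
            evalue = 1e-30, from = 5L, to = nchar(prot) - 5L,
            stringsAsFactors = FALSE)
        }
      }
      gstarts[gi] <- pos
      gends[gi] <- pos + glen
      gids[gi] <- gid
      pos <- gends[gi] + intergenic_length
    }
    clusters[[ci]] <- data.frame(
      cluster = ci, start = gstarts[1] - margin,
      end = gends[genes_per_cluster] + margin,
      product_type = c("NRPS", "T2PKS", "terpene", "T1PKS",
                       "other")[(ci - 1L) %% 5L + 1L],
      stringsAsFactors = FALSE)
    genes[[ci]] <- data.frame(gene_id = gids, start = gstarts, end = gends,
                              strand = "+", cluster = ci,
                              stringsAsFactors = FALSE)
    pos <- pos - intergenic_length + sep
  }
  genes <- do.call(rbind, genes)
  clusters <- do.call(rbind, clusters)
  L <- pos + lead

  seq_chars <- strsplit(random_dna(L, gc_fraction), "")[[1]]

  # reverse-translate planted SARP CDS into the sequence
  for (gid in names(proteins)) {
    g <- genes[genes$gene_id == gid, ]
    cds <- paste0("ATG", paste(CODON_OF[strsplit(proteins[[gid]], "")[[1]]],
                               collapse = ""), "TGA")
    stopifnot(nchar(cds) == g$end - g$start)
    seq_chars[(g$start + 1L):g$end] <- strsplit(cds, "")[[1]]
  }

  # intergenic gaps = complement of gene spans over [0, L)
  gene_ir <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
  gap_ir <- IRanges::gaps(gene_ir, start = 1L, end = L)
  gaps0 <- data.frame(start = IRanges::start(gap_ir) - 1L,
                      end = IRanges::end(gap_ir))

  scrub_model <- motif_model(consensus, min_identity = 0)
  if (!is.null(scrub_min_identity)) {
    for (k in seq_len(nrow(gaps0))) {
      seq_chars <- scrub_gap(seq_chars, gaps0$start[k], gaps0$end[k],
                             scrub_model, scrub_min_identity)
    }
  }

  # plant motifs midway in the gap after gene `slot` of the cluster
  truth_motifs <- list()
  if (!is.null(planted_motifs) && nrow(planted_motifs)) {
    span <- nchar(consensus)
    slot_used <- integer(0)
    for (mi in seq_len(nrow(planted_motifs))) {
      pm <- planted_motifs[mi, ]
      slot <- sum(slot_used == pm$cluster) + 1L
      slot_used <- c(slot_used, pm$cluster)
      cg <- genes[genes$cluster == pm$cluster, ]
      if (slot >= nrow(cg)) {
        stop(sprintf("cluster %d has no free intergenic gap for motif %d",
                     pm$cluster, mi), call. = FALSE)
      }
      gap_start <- cg$end[slot]
      gap_end <- cg$start[slot + 1L]
      if (gap_end - gap_start < span) {
        stop("planted motif longer than the available intergenic gap",
             call. = FALSE)
      }
      at <- gap_start + (gap_end - gap_start - span) %/% 2L
      site <- concretize_motif(consensus, pm$mismatches)
      planted <- if (pm$strand == "-") revcomp(site) else site
      seq_chars[(at + 1L):(at + span)] <- strsplit(planted, "")[[1]]
      truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
        cluster = pm$cluster, start = at, end = at + span,
        strand = pm$strand, mismatches = pm$mismatches,
        site_sequence = site,
        identity = (span - pm$mismatches) / span,
        stringsAsFactors = FALSE)
    }
  }
  # re-scrub gaps holding planted sites: junction windows created by the
  # insertion are mutated away without touching the planted spans
  if (!is.null(scrub_min_identity) && length(truth_motifs)) {
    planted_df <- do.call(rbind, truth_motifs)
    for (k in seq_len(nrow(gaps0))) {
      inside <- planted_df[planted_df$start >= gaps0$start[k] &
                             planted_df$end <= gaps0$end[k], , drop = FALSE]
      if (!nrow(inside)) next
      seq_chars <- scrub_gap(seq_chars, gaps0$start[k], gaps0$end[k],
                             scrub_model, scrub_min_identity,
                             protected = inside)
    }
  }

  sequence <- paste(seq_chars, collapse = "")

  rec <- genome_record("ctg1", sequence,
                       data.frame(gene_id = genes$gene_id,
                                  start = genes$start, end = genes$end,
                                  strand = genes$strand, kind = "CDS",
                                  product = ifelse(
                                    genes$gene_id %in% names(proteins),
                                    "SARP family transcriptional regulator",
                                    "hypothetical protein"),
                                  stringsAsFactors = FALSE),
                       source_taxon = "synthetic Streptomyces-like")

  paths <- list(genome = file.path(outdir, "genome.gbk"),
                regions = file.path(outdir, "regions.bed"),
                domains = file.path(outdir, "domain_hits.tsv"),
                proteins = file.path(outdir, "sarp_proteins_synthetic.faa"),
                reference = file.path(outdir, "reference_sarp_synthetic.faa"))
  write_genbank(rec, paths$genome)
  utils::write.table(
    data.frame("ctg1", clusters$start, clusters$end, clusters$product_type),
    paths$regions, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  dom <- if (length(sarp_rows)) do.call(rbind, sarp_rows) else
    data.frame(protein_id = character(), profile_id = character(),
               evalue = numeric(), from = integer(), to = integer())
  utils::write.table(dom, paths$domains, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_fasta(proteins, paths$proteins)
  write_fasta(list(ref_sarp_synthetic = reference), paths$reference)

  truth <- list(
    seed = as.integer(seed),
    record_id = "ctg1",
    length = L,
    motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs) else NULL,
    sarps = if (!is.null(planted_sarps) && nrow(planted_sarps)) {
      ids <- sprintf("c%d_sarp", planted_sarps$cluster)
      cbind(planted_sarps, gene_id = ids,
            stringsAsFactors = FALSE)
    } else NULL,
    clusters = clusters,
    genes = genes,
    reference = reference)
  invisible(list(paths = paths, truth = truth))
}

write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(sprintf(">%s", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1L, nchar(s), 60L),
                         pmin(seq(60L, nchar(s) + 59L, 60L), nchar(s))), con)
  }
  invisible(path)
}

#' Simulate a protein population with exact per-group architecture counts
#'
#' Emits exactly the specified number of protein records per (group,
#' architecture) cell, with consistent synthetic domain-hit profiles, so
#' census aggregation can be tested against count-exact populations.
#'
#' @param spec data frame with columns `group`, `architecture`, `count`
#' @param group_name name for the grouping column in the output (default
#'   `"taxon_order"`)
#' @return data frame of protein records with `protein_id`, the grouping
#'   column, `architecture`, and `profiles` (comma-joined accessions)
#' @export
simulate_census <- function(spec, group_name = "taxon_order") {
  if (is.null(spec) || !nrow(spec)) {
    out <- data.frame(protein_id = character(), g = character(),
                      architecture = character(), profiles = character(),
                      stringsAsFactors = FALSE)
    names(out)[2] <- group_name
    return(out)
  }
  stopifnot(all(c("group", "architecture", "count") %in% names(spec)),
            all(spec$count >= 0), all(spec$architecture %in% names(ARCH_PROFILES)))
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$count[i]
    if (n == 0) return(NULL)
    data.frame(
      protein_id = sprintf("%s_%s_%06d", spec$group[i], spec$architecture[i],
                           seq_len(n)),
      g = spec$group[i],
      architecture = spec$architecture[i],
      profiles = paste(ARCH_PROFILES[[spec$architecture[i]]], collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(simulate_census(NULL, group_name))
  names(out)[2] <- group_name
  rownames(out) <- NULL
  out
}
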