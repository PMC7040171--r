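# End-to-end screening pipeline: files in, prioritization report out.

#' Run the SARP-guided screening pipeline
#'
#' Reads an annotated genome, BGC regions, a protein domain-hit table, a
#' reference SARP and candidate protein sequences; scans all replicons
#' for the consensus motif, filters hits to intergenic positions within
#' clusters, classifies SARP architectures, computes reference
#' similarity, and gates every cluster through the prioritization
#' strategy.
#'
#' @param genome path to the annotated genome (GenBank, or GFF3 with
#'   `fasta=`)
#' @param regions path to BGC regions (`.bed` treated as BED, anything
#'   else as antiSMASH-style GenBank)
#' @param domains path to the protein domain-hit table
#'   (hmmscan domtblout or 5-column TSV)
#' @param reference path to the reference SARP FASTA (first sequence used)
#' @param proteins path to a FASTA of the genome's candidate protein
#'   sequences; ids must match gene ids. Proteins present in the
#'   domain-hit table but absent here get no similarity value.
#' @param model a [motif_model()]
#' @param thresholds a [prioritization_thresholds()]
#' @param fasta optional contig FASTA when `genome` is GFF3
#' @return list with `records`, `regions`, `intergenic`, `motif_hits`,
#'   `sarp_genes`, `annotations`, `report`, `strain_prioritized`
#' @export
sarp_scan <- function(genome, regions, domains, reference, proteins = NULL,
                      model = motif_model(),
                      thresholds = prioritization_thresholds(),
                      fasta = NULL) {
  records <- if (is.null(fasta)) read_genome(genome, "genbank")
             else read_genome(genome, "gff3+fasta", fasta = fasta)
  fmt <- if (grepl("\\.bed$", regions, ignore.case = TRUE)) "bed"
         else "antismash-genbank"
  regs <- load_regions(regions, fmt)

  hits <- parse_domain_hits(domains)
  arch <- classify_proteins(hits)
  sarp_arch <- arch[arch$architecture %in%
                      c("small", "large", "btad_only", "hth_only"), ,
                    drop = FALSE]

  sims <- NULL
  if (!is.null(proteins) && nrow(sarp_arch)) {
    aaset <- Biostrings::readAAStringSet(proteins)
    names(aaset) <- sub("\\s.*$", "", names(aaset))
    refset <- Biostrings::readAAStringSet(reference)
    ref <- as.character(refset[[1]])
    have <- intersect(sarp_arch$protein_id, names(aaset))
    qs <- as.list(as.character(aaset[have]))
    sims <- similarity_to_reference(qs, ref)
  }

  # SARP gene coordinates: protein ids are gene ids
  feats <- do.call(rbind, lapply(records, function(r) {
    f <- r$features
    if (!nrow(f)) return(NULL)
    f$record_id <- r$record_id
    f
  }))
  sarp_genes <- NULL
  if (nrow(sarp_arch) && !is.null(feats)) {
    m <- match(sarp_arch$protein_id, feats$gene_id)
    found <- !is.na(m)
    if (any(!found)) {
      warning(sprintf("SARP protein(s) without a matching gene: %s",
                      paste(sarp_arch$protein_id[!found], collapse = ", ")),
              call. = FALSE)
    }
    sarp_genes <- data.frame(
      gene_id = sarp_arch$protein_id[found],
      record_id = feats$record_id[m[found]],
      start = feats$start[m[found]], end = feats$end[m[found]],
      architecture = sarp_arch$architecture[found],
      stringsAsFactors = FALSE)
    if (!is.null(sims) && nrow(sims)) {
      sm <- match(sarp_genes$gene_id, sims$protein_id)
      sarp_genes$identity_percent <- sims$identity_percent[sm]
      sarp_genes$similarity_percent <- sims$similarity_percent[sm]
    }
  }

  intergenic <- do.call(rbind, lapply(records, extract_intergenic))
  motif_hits <- scan_genome(records, model)

  ann <- associate_clusters(regs, intergenic, motif_hits, sarp_genes)
  report <- rank_candidates(gate_candidates(ann, thresholds))

  list(records = records, regions = regs, intergenic = intergenic,
       motif_hits = motif_hits, sarp_genes = sarp_genes,
       annotations = ann, report = report,
       strain_prioritized = strain_prioritized(report))
}
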