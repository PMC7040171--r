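# The three-step SARP-guided activation strategy as computable gates:
# (1) the cluster carries a SARP gene, (2) that SARP is highly similar to
# the reference activator (> 55% amino-acid similarity by default), and
# (3) a consensus binding motif sits in an intergenic/promoter position
# within the cluster. Clusters passing all enabled gates are candidates
# for activation by heterologous expression of the reference SARP.

#' Prioritization thresholds
#'
#' @param similarity_gate_percent minimum reference similarity; the
#'   comparison is strict `>` by default (a cluster at exactly the gate is
#'   rejected), switchable to `>=` with `strict = FALSE`
#' @param require_motif_in_promoter require at least one intergenic motif
#'   hit inside the cluster
#' @param require_cluster_situated_sarp require the SARP gene inside the
#'   cluster; when FALSE the SARP gates (presence and similarity) are
#'   skipped, supporting strains whose activating SARP acts in trans
#' @param min_motif_identity minimum identity of a qualifying motif hit
#' @param strict use strict `>` on the similarity gate
#' @return an object of class `prioritization_thresholds`
#' @export
prioritization_thresholds <- function(similarity_gate_percent = 55,
                                      require_motif_in_promoter = TRUE,
                                      require_cluster_situated_sarp = TRUE,
                                      min_motif_identity = 6 / 7,
                                      strict = TRUE) {
  stopifnot(similarity_gate_percent > 0, similarity_gate_percent <= 100)
  structure(list(similarity_gate_percent = similarity_gate_percent,
                 require_motif_in_promoter = require_motif_in_promoter,
                 require_cluster_situated_sarp = require_cluster_situated_sarp,
                 min_motif_identity = min_motif_identity,
                 strict = strict),
            class = "prioritization_thresholds")
}

#' Gate clusters through the prioritization strategy
#'
#' @param annotations data frame from [associate_clusters()]
#' @param thresholds a [prioritization_thresholds()]
#' @return data frame with per-gate booleans (`has_sarp`, `sarp_similar`,
#'   `has_promoter_motif`), ranking keys and a `verdict` of `"candidate"`
#'   or `"rejected"`; verdict is `"candidate"` iff all enabled gates pass
#' @export
gate_candidates <- function(annotations,
                            thresholds = prioritization_thresholds()) {
  stopifnot(inherits(thresholds, "prioritization_thresholds"))
  sim <- annotations$best_ref_similarity
  has_sarp <- annotations$sarp_gene_count >= 1L
  sarp_similar <- !is.na(sim) &
    (if (thresholds$strict) sim > thresholds$similarity_gate_percent
     else sim >= thresholds$similarity_gate_percent)
  best_mid <- annotations$best_motif_identity
  has_motif <- annotations$motif_hit_count >= 1L & !is.na(best_mid) &
    best_mid >= thresholds$min_motif_identity - 1e-12

  enabled <- c(has_sarp = thresholds$require_cluster_situated_sarp,
               sarp_similar = thresholds$require_cluster_situated_sarp,
               has_promoter_motif = thresholds$require_motif_in_promoter)
  gates <- cbind(has_sarp = has_sarp, sarp_similar = sarp_similar,
                 has_promoter_motif = has_motif)
  pass <- apply(gates[, enabled, drop = FALSE], 1L, all)
  if (!any(enabled)) pass <- rep(TRUE, nrow(annotations))

  data.frame(cluster_id = annotations$cluster_id,
             product_type = annotations$product_type,
             has_sarp = has_sarp, sarp_similar = sarp_similar,
             has_promoter_motif = has_motif,
             best_motif_identity = ifelse(is.na(best_mid), 0, best_mid),
             best_similarity = ifelse(is.na(sim), 0, sim),
             verdict = ifelse(pass, "candidate", "rejected"),
             stringsAsFactors = FALSE)
}

#' Rank gated clusters into the final report
#'
#' Candidates first, ordered by best motif identity (descending), then
#' best reference similarity (descending), then cluster id (ascending);
#' rejected clusters follow in the same order with their failed gates
#' listed. Ordering and float formatting are fixed, so identical inputs
#' give byte-identical reports.
#'
#' @param scores data frame from [gate_candidates()]
#' @return the input reordered, with `rank` and `failed_gates` columns
#' @export
rank_candidates <- function(scores) {
  if (!nrow(scores)) {
    scores$rank <- integer(0)
    scores$failed_gates <- character(0)
    return(scores)
  }
  key <- order(scores$verdict != "candidate", -scores$best_motif_identity,
               -scores$best_similarity, scores$cluster_id)
  out <- scores[key, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  gate_cols <- c("has_sarp", "sarp_similar", "has_promoter_motif")
  out$failed_gates <- vapply(seq_len(nrow(out)), function(i) {
    failed <- gate_cols[!unlist(out[i, gate_cols])]
    paste(failed, collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Write the prioritization report as TSV
#'
#' @param report data frame from [rank_candidates()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(report, path) {
  out <- report
  out$best_motif_identity <- sprintf("%.3f", out$best_motif_identity)
  out$best_similarity <- sprintf("%.1f", out$best_similarity)
  cols <- c("rank", "cluster_id", "product_type", "verdict",
            "best_motif_identity", "best_similarity", "has_sarp",
            "sarp_similar", "has_promoter_motif", "failed_gates")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Strain-level roll-up
#'
#' A strain is prioritized if at least one of its clusters is a candidate.
#'
#' @param report data frame from [rank_candidates()]
#' @return logical scalar
#' @export
strain_prioritized <- function(report) {
  any(report$verdict == "candidate")
}
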