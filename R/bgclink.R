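# BGC regions, the cluster-similarity rule, and Table-style annotations.

#' Load BGC region definitions
#'
#' Reads antiSMASH-style GenBank files (one `region`/`cluster` feature per
#' BGC, product class in the `/product` qualifier) or BED (4+ columns,
#' name field = product class).
#'
#' @param path input file
#' @param format `"antismash-genbank"` or `"bed"`
#' @return data frame with columns `cluster_id`, `record_id`, `start`,
#'   `end` (0-based half-open), `product_type`
#' @export
load_regions <- function(path, format = c("antismash-genbank", "bed")) {
  format <- match.arg(format)
  empty <- data.frame(cluster_id = character(), record_id = character(),
                      start = integer(), end = integer(),
                      product_type = character(), stringsAsFactors = FALSE)
  if (format == "bed") {
    if (!file.exists(path)) {
      stop(sprintf("cannot read BED file: %s", path), call. = FALSE)
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
    if (!length(lines)) return(empty)
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 3L) {
        stop(sprintf("BED line %d has fewer than 3 fields", i),
             call. = FALSE)
      }
      data.frame(cluster_id = sprintf("%s_c%d", f[1], i),
                 record_id = f[1],
                 start = as.integer(f[2]), end = as.integer(f[3]),
                 product_type = if (length(f) >= 4L) f[4] else "unknown",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    raw <- parse_genbank(path)
    rows <- list()
    for (r in raw) {
      f <- r$features
      reg <- f[f$key %in% c("region", "cluster"), , drop = FALSE]
      n_before <- length(rows)
      for (k in seq_len(nrow(reg))) {
        if (is.na(reg$start[k]) || is.na(reg$end[k])) {
          stop(sprintf("region feature in %s lacks coordinates",
                       r$record_id), call. = FALSE)
        }
        num <- if ("region_number" %in% names(reg) &&
                   !is.na(reg$region_number[k])) reg$region_number[k]
               else as.character(length(rows) - n_before + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = sprintf("%s_region%s", r$record_id, num),
          record_id = r$record_id,
          start = reg$start[k], end = reg$end[k],
          product_type = if ("product" %in% names(reg) &&
                             !is.na(reg$product[k])) reg$product[k]
                         else "unknown",
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' The strict gene-similarity rule
#'
#' Two genes count as similar if their alignment has e-value strictly
#' below `evalue_max`, identity strictly above `identity_min_percent`, and
#' the alignment covers strictly more than `coverage_min_percent` of the
#' shorter sequence. Defaults are e-value < 1e-5, identity > 30%,
#' coverage > 25%.
#'
#' @param evalue_max,identity_min_percent,coverage_min_percent thresholds
#' @return an object of class `similarity_rule`
#' @export
similarity_rule <- function(evalue_max = 1e-5, identity_min_percent = 30,
                            coverage_min_percent = 25) {
  stopifnot(evalue_max > 0, identity_min_percent > 0,
            coverage_min_percent > 0)
  structure(list(evalue_max = evalue_max,
                 identity_min_percent = identity_min_percent,
                 coverage_min_percent = coverage_min_percent),
            class = "similarity_rule")
}

#' Apply the gene-similarity rule
#'
#' All three comparisons are strict, so a hit exactly at a threshold does
#' not pass. Vectorized over hits.
#'
#' @param evalue alignment e-value(s)
#' @param identity_percent percent identity in \[0, 100\]
#' @param coverage_percent_shortest alignment coverage of the shorter
#'   sequence, percent
#' @param rule a [similarity_rule()]
#' @return logical vector
#' @export
gene_similar <- function(evalue, identity_percent, coverage_percent_shortest,
                         rule = similarity_rule()) {
  evalue < rule$evalue_max &
    identity_percent > rule$identity_min_percent &
    coverage_percent_shortest > rule$coverage_min_percent
}

#' Similarity of a query cluster to a known cluster
#'
#' The fraction of the known cluster's genes for which the query cluster
#' holds at least one similar counterpart, as a round-half-up integer
#' percentage; 100 when every reference gene is found. One query gene may
#' support multiple reference genes.
#'
#' @param ref_genes character vector of reference-cluster gene ids
#'   (nonempty)
#' @param hits data frame with columns `ref_gene`, `query_gene`, `evalue`,
#'   `identity_percent`, `coverage_percent_shortest`
#' @param rule a [similarity_rule()]
#' @return integer percent in \[0, 100\]
#' @export
cluster_similarity <- function(ref_genes, hits, rule = similarity_rule()) {
  if (!length(ref_genes)) {
    stop("cluster_similarity requires a nonempty reference gene set",
         call. = FALSE)
  }
  found <- 0L
  if (!is.null(hits) && nrow(hits)) {
    pass <- gene_similar(hits$evalue, hits$identity_percent,
                         hits$coverage_percent_shortest, rule)
    found <- sum(ref_genes %in% unique(hits$ref_gene[pass]))
  }
  as.integer(round_half_up(100 * found / length(ref_genes)))
}

#' Build per-cluster annotations
#'
#' For each BGC region: counts SARP genes whose span lies inside the
#' region (partial overlaps are counted separately and flagged), attaches
#' the best reference identity/similarity among them, and attaches motif
#' hits that fall both inside the region and inside an intergenic region
#' (sites inside coding sequence are discarded as biologically
#' implausible).
#'
#' @param regions data frame from [load_regions()]
#' @param intergenic data frame from [extract_intergenic()] (rows from all
#'   records concatenated)
#' @param motif_hits data frame from [scan_motifs()]/[scan_genome()]
#' @param sarp_genes data frame with columns `gene_id`, `record_id`,
#'   `start`, `end`, `architecture`, and optionally `identity_percent`,
#'   `similarity_percent` (vs the reference SARP); may be empty
#' @param known_cluster_similarity optional named vector,
#'   cluster_id -> percent similarity to a known cluster
#' @return data frame, one row per region, with columns `cluster_id`,
#'   `product_type`, `known_cluster_similarity_percent`,
#'   `sarp_gene_count`, `sarp_partial_count`, `sarp_gene_ids`,
#'   `best_ref_identity`, `best_ref_similarity`, `motif_hit_count`,
#'   `best_motif_identity`; the filtered per-cluster motif hits are
#'   attached as attribute `"motif_hits"` (with a `cluster_id` column)
#' @export
associate_clusters <- function(regions, intergenic, motif_hits,
                               sarp_genes = NULL,
                               known_cluster_similarity = NULL) {
  check_record_ids(regions, intergenic, motif_hits, sarp_genes)
  n <- nrow(regions)
  out <- data.frame(cluster_id = regions$cluster_id,
                    product_type = regions$product_type,
                    known_cluster_similarity_percent = NA_real_,
                    sarp_gene_count = 0L, sarp_partial_count = 0L,
                    sarp_gene_ids = "", best_ref_identity = NA_real_,
                    best_ref_similarity = NA_real_, motif_hit_count = 0L,
                    best_motif_identity = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(known_cluster_similarity)) {
    m <- match(out$cluster_id, names(known_cluster_similarity))
    out$known_cluster_similarity_percent <- known_cluster_similarity[m]
  }
  # motif hits must sit inside an intergenic interval of the same record
  hit_ok <- rep(FALSE, if (is.null(motif_hits)) 0L else nrow(motif_hits))
  if (length(hit_ok) && !is.null(intergenic) && nrow(intergenic)) {
    hg <- GenomicRanges::GRanges(motif_hits$record_id,
                                 IRanges::IRanges(motif_hits$start + 1L,
                                                  motif_hits$end))
    ig <- GenomicRanges::GRanges(intergenic$record_id,
                                 IRanges::IRanges(intergenic$start + 1L,
                                                  intergenic$end))
    hit_ok <- IRanges::overlapsAny(hg, ig, type = "within")
  }
  kept_hits <- list()
  for (k in seq_len(n)) {
    rg <- regions[k, ]
    if (!is.null(sarp_genes) && nrow(sarp_genes)) {
      same <- sarp_genes$record_id == rg$record_id
      within <- same & sarp_genes$start >= rg$start &
        sarp_genes$end <= rg$end
      partial <- same & !within & sarp_genes$start < rg$end &
        sarp_genes$end > rg$start
      out$sarp_gene_count[k] <- sum(within) + sum(partial)
      out$sarp_partial_count[k] <- sum(partial)
      inside <- sarp_genes[within | partial, , drop = FALSE]
      out$sarp_gene_ids[k] <- paste(inside$gene_id, collapse = ",")
      if (nrow(inside) && "similarity_percent" %in% names(inside)) {
        best <- which.max(inside$similarity_percent)
        out$best_ref_similarity[k] <- inside$similarity_percent[best]
        if ("identity_percent" %in% names(inside)) {
          out$best_ref_identity[k] <- inside$identity_percent[best]
        }
      }
    }
    if (length(hit_ok)) {
      inreg <- motif_hits$record_id == rg$record_id &
        motif_hits$start >= rg$start & motif_hits$end <= rg$end & hit_ok
      out$motif_hit_count[k] <- sum(inreg)
      if (any(inreg)) {
        mh <- motif_hits[inreg, , drop = FALSE]
        mh$cluster_id <- rg$cluster_id
        kept_hits[[length(kept_hits) + 1L]] <- mh
        out$best_motif_identity[k] <- max(mh$identity)
      }
    }
  }
  attr(out, "motif_hits") <- if (length(kept_hits)) {
    kh <- do.call(rbind, kept_hits); rownames(kh) <- NULL; kh
  } else {
    NULL
  }
  out
}

check_record_ids <- function(regions, ...) {
  known <- unique(regions$record_id)
  for (tbl in list(...)) {
    if (is.null(tbl) || !nrow(tbl) || !"record_id" %in% names(tbl)) next
    bad <- setdiff(unique(tbl$record_id), known)
    if (length(bad)) {
      stop(sprintf("record id(s) not present in the region table: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write cluster annotations as TSV
#'
#' Column order mirrors the per-cluster screening table: cluster, product
#' type, similarity to a known cluster, localization, SARP gene count,
#' reference homology (identity/similarity), motif flag.
#'
#' @param annotations data frame from [associate_clusters()]
#' @param regions region table (for localization)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation_tsv <- function(annotations, regions, path) {
  m <- match(annotations$cluster_id, regions$cluster_id)
  loc <- sprintf("%s:%d-%d", regions$record_id[m],
                 regions$start[m] + 1L, regions$end[m])
  fmt_is <- ifelse(is.na(annotations$best_ref_identity), "-",
                   sprintf("%d/%d",
                           round_half_up(annotations$best_ref_identity),
                           round_half_up(annotations$best_ref_similarity)))
  tab <- data.frame(
    cluster = annotations$cluster_id,
    type = annotations$product_type,
    known_cluster_similarity =
      ifelse(is.na(annotations$known_cluster_similarity_percent), "-",
             sprintf("%d",
                     round_half_up(annotations$known_cluster_similarity_percent))),
    localization = loc,
    sarp_gene_count = annotations$sarp_gene_count,
    homology_I_S = fmt_is,
    motif = ifelse(annotations$motif_hit_count > 0, "+", "-"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
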