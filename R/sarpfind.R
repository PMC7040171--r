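# SARP regulator identification and census.
#
# Membership in the SARP family is decided from hits against four PFAM
# profiles: Trans_reg_C (PF00486, the winged HTH DNA-binding domain), BTAD
# (PF03704, the transcriptional activation domain), NB-ARC (PF00931) and
# TPR_12 (PF13424). "Small" SARPs carry only HTH + BTAD; "large" SARPs add
# NB-ARC and/or TPR at the C-terminus. PF93704 is accepted as a BTAD alias
# (a widely circulated typo for PF03704).

#' Default profile-to-role map for SARP architecture calling
#'
#' @return named character vector, PFAM accession (version-stripped) to
#'   role in {HTH, BTAD, NB-ARC, TPR}
#' @export
canonical_profile_map <- function() {
  c(PF00486 = "HTH", PF03704 = "BTAD", PF93704 = "BTAD",
    PF00931 = "NB-ARC", PF13424 = "TPR")
}

#' Parse a protein domain-hit table
#'
#' Accepts the hmmscan per-domain tabular layout (`--domtblout`, 23
#' whitespace-delimited columns, target = profile / query = protein, the
#' independent per-domain e-value and `ali` coordinates are used) or a
#' simplified 5-column TSV (`protein_id`, `profile_id`, `evalue`, `from`,
#' `to`). Profile accessions are normalized by stripping version suffixes
#' ("PF00486.27" becomes "PF00486"). Malformed rows are skipped with one
#' warning giving the count (also in attribute `n_skipped`).
#'
#' @param path tabular file
#' @param evalue_cutoff drop hits with e-value above this (default 1e-5)
#' @return data frame with columns `protein_id`, `profile_id`, `evalue`,
#'   `ali_from`, `ali_to`, `score`
#' @export
parse_domain_hits <- function(path, evalue_cutoff = 1e-5) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read domain-hit table: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), profile_id = character(),
                      evalue = numeric(), ali_from = integer(),
                      ali_to = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  n_skipped <- 0L
  rows <- lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    parsed <- if (length(f) >= 22L) {
      # domtblout: 1 target(profile) 2 acc 4 query(protein) 13 i-Evalue
      # 14 dom score 18-19 ali_from/to
      acc <- if (f[2] != "-") f[2] else f[1]
      list(protein_id = f[4], profile_id = acc,
           evalue = suppressWarnings(as.numeric(f[13])),
           ali_from = suppressWarnings(as.integer(f[18])),
           ali_to = suppressWarnings(as.integer(f[19])),
           score = suppressWarnings(as.numeric(f[14])))
    } else if (length(f) == 5L) {
      list(protein_id = f[1], profile_id = f[2],
           evalue = suppressWarnings(as.numeric(f[3])),
           ali_from = suppressWarnings(as.integer(f[4])),
           ali_to = suppressWarnings(as.integer(f[5])),
           score = NA_real_)
    } else {
      NULL
    }
    if (is.null(parsed) || is.na(parsed$evalue) || is.na(parsed$ali_from) ||
        is.na(parsed$ali_to) || parsed$ali_from > parsed$ali_to ||
        parsed$evalue < 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    as.data.frame(parsed, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d malformed row(s) in %s", n_skipped, path),
            call. = FALSE)
  }
  if (!length(rows)) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$profile_id <- normalize_accession(out$profile_id)
  out <- out[out$evalue <= evalue_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Strip PFAM version suffixes from accessions
#' @param x character vector of accessions
#' @return accessions without trailing ".NN"
#' @export
normalize_accession <- function(x) {
  sub("\\.[0-9]+$", "", x)
}

#' Classify the SARP architecture of one protein
#'
#' Total, deterministic function of which canonical domain roles are
#' present among the protein's profile hits:
#' \itemize{
#'   \item \code{small}: HTH and BTAD present, neither NB-ARC nor TPR
#'   \item \code{large}: HTH and BTAD present, plus NB-ARC and/or TPR
#'   \item \code{btad_only}: BTAD present without HTH
#'   \item \code{hth_only}: HTH present without BTAD
#'   \item \code{incomplete}: none of the four roles present
#' }
#'
#' @param profile_ids profile accessions hit by the protein (versions
#'   tolerated), or a data frame from [parse_domain_hits()] restricted to
#'   one protein
#' @param canonical_map profile-to-role map, see [canonical_profile_map()]
#' @return one of `"small"`, `"large"`, `"btad_only"`, `"hth_only"`,
#'   `"incomplete"`
#' @export
classify_architecture <- function(profile_ids,
                                  canonical_map = canonical_profile_map()) {
  if (is.data.frame(profile_ids)) profile_ids <- profile_ids$profile_id
  roles <- unique(stats::na.omit(canonical_map[normalize_accession(profile_ids)]))
  hth <- "HTH" %in% roles
  btad <- "BTAD" %in% roles
  extra <- any(c("NB-ARC", "TPR") %in% roles)
  if (hth && btad) {
    if (extra) "large" else "small"
  } else if (btad) {
    "btad_only"
  } else if (hth) {
    "hth_only"
  } else {
    "incomplete"
  }
}

ARCHITECTURES <- c("small", "large", "btad_only", "hth_only", "incomplete")

#' Classify all proteins in a domain-hit table
#'
#' @param hits data frame from [parse_domain_hits()]
#' @param protein_ids optional full roster; proteins without any hit are
#'   classed `incomplete`
#' @param canonical_map see [canonical_profile_map()]
#' @return data frame `protein_id`, `architecture`
#' @export
classify_proteins <- function(hits, protein_ids = NULL,
                              canonical_map = canonical_profile_map()) {
  ids <- unique(c(hits$protein_id, protein_ids))
  arch <- vapply(ids, function(p) {
    classify_architecture(hits$profile_id[hits$protein_id == p],
                          canonical_map)
  }, character(1))
  data.frame(protein_id = ids, architecture = unname(arch),
             stringsAsFactors = FALSE)
}

#' Architecture census over a grouping variable
#'
#' Counts proteins per group and architecture class, with integer
#' percentages by round-half-up: each class's share within its group and
#' each group's share of the full data set. With
#' `denominator = "genomes"` a genome counts once and is positive if at
#' least one of its proteins is SARP-classified (see [sarp_positive()]).
#'
#' @param proteins data frame with an `architecture` column, the grouping
#'   column, and (for genome denominators) a `genome_id` column
#' @param group_by name of the grouping column (e.g. `"taxon_order"`,
#'   `"taxon_genus"`, `"cluster_type"`); missing values go to an
#'   `"unknown"` bucket
#' @param denominator `"proteins"` or `"genomes"`
#' @return data frame, one row per group, with `total`, one count and one
#'   `pct_` column per architecture class, and `pct_of_all`
#' @export
census <- function(proteins, group_by, denominator = c("proteins", "genomes")) {
  denominator <- match.arg(denominator)
  stopifnot(group_by %in% names(proteins),
            "architecture" %in% names(proteins))
  g <- proteins[[group_by]]
  g[is.na(g)] <- "unknown"
  if (denominator == "genomes") {
    stopifnot("genome_id" %in% names(proteins))
    per_genome <- stats::aggregate(
      list(positive = proteins$architecture %in% ARCHITECTURES[1:4]),
      by = list(group = g, genome_id = proteins$genome_id), FUN = any)
    groups <- sort(unique(per_genome$group))
    out <- data.frame(group = groups, stringsAsFactors = FALSE)
    out$total <- vapply(groups, function(x)
      sum(per_genome$group == x), integer(1))
    out$positive <- vapply(groups, function(x)
      sum(per_genome$positive[per_genome$group == x]), integer(1))
    out$pct_positive <- round_half_up(100 * out$positive / out$total)
    names(out)[1] <- group_by
    return(out)
  }
  groups <- sort(unique(g))
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  out$total <- vapply(groups, function(x) sum(g == x), integer(1))
  for (a in ARCHITECTURES) {
    out[[a]] <- vapply(groups, function(x)
      sum(g == x & proteins$architecture == a), integer(1))
  }
  for (a in ARCHITECTURES) {
    out[[paste0("pct_", a)]] <-
      ifelse(out$total > 0, round_half_up(100 * out[[a]] / out$total), 0)
  }
  grand <- nrow(proteins)
  out$pct_of_all <- if (grand > 0) round_half_up(100 * out$total / grand)
                    else rep(0, nrow(out))
  names(out)[1] <- group_by
  rownames(out) <- NULL
  out
}

#' Is a genome SARP-positive?
#'
#' A genome counts as harboring a SARP-type regulator if at least one of
#' its proteins hits one of the four canonical domains and carries HTH or
#' BTAD; family-profile hits lacking both DNA-binding and activation
#' domains (as seen outside Actinobacteria) do not qualify.
#'
#' @param architectures character vector of per-protein architecture calls
#' @return logical scalar
#' @export
sarp_positive <- function(architectures) {
  any(architectures %in% c("small", "large", "btad_only", "hth_only"))
}

#' Per-genus prevalence of SARP-positive genomes
#'
#' @param genome_table data frame with columns `genus` and logical
#'   `sarp_positive` (one row per genome)
#' @return data frame `genus`, `positive`, `total`, `percent`
#'   (round-half-up integer); genera with zero genomes are excluded with a
#'   warning
#' @export
genome_prevalence <- function(genome_table) {
  stopifnot(all(c("genus", "sarp_positive") %in% names(genome_table)))
  genera <- sort(unique(genome_table$genus))
  rows <- lapply(genera, function(gn) {
    sub <- genome_table[genome_table$genus == gn, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(genus = gn, positive = sum(sub$sarp_positive),
               total = nrow(sub),
               percent = round_half_up(100 * sum(sub$sarp_positive) /
                                         nrow(sub)),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep)) warning("genus with zero genomes excluded", call. = FALSE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out
}

#' Global pairwise protein identity and similarity
#'
#' Needleman-Wunsch global alignment (end gaps penalized) with BLOSUM62,
#' gap open 10, gap extension 0.5. Identity is identical columns over all
#' alignment columns; similarity additionally counts columns whose
#' substitution score is positive. Gap columns enter the denominator only,
#' so identity <= similarity <= 100 always holds.
#'
#' @param a,b amino-acid sequences (nonempty; 20 standard residues plus X)
#' @param matrix substitution matrix name (a Biostrings data set)
#' @param gap_open,gap_extend gap penalties
#' @param ids optional length-2 character vector of sequence identifiers
#' @return list with `identity_percent`, `similarity_percent`,
#'   `alignment_length`, `score`, `ids`
#' @export
pairwise_similarity <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                                gap_extend = 0.5, ids = c("a", "b")) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("pairwise_similarity requires two nonempty sequences",
         call. = FALSE)
  }
  submat <- get(data(list = matrix, package = "Biostrings",
                     envir = environment()))
  # canonicalize the pair order: co-optimal alignments may differ between
  # argument orders, and the column statistics are order-independent, so
  # aligning the lexicographically smaller sequence first makes the
  # reported percentages exactly symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol <- length(pa)
  both <- pa != "-" & pb != "-"
  ident <- both & pa == pb
  pos <- both
  pos[both] <- submat[cbind(pa[both], pb[both])] > 0
  list(identity_percent = 100 * sum(ident) / ncol,
       similarity_percent = 100 * sum(ident | pos) / ncol,
       alignment_length = ncol,
       score = Biostrings::score(aln),
       ids = ids)
}

#' Best similarity of each query protein to a reference SARP
#'
#' @param queries named character vector of protein sequences
#' @param reference reference SARP sequence (e.g. PapR2)
#' @param ... passed to [pairwise_similarity()]
#' @return data frame `protein_id`, `identity_percent`,
#'   `similarity_percent`, `alignment_length`
#' @export
similarity_to_reference <- function(queries, reference, ...) {
  rows <- lapply(names(queries), function(id) {
    r <- pairwise_similarity(queries[[id]], reference,
                             ids = c(id, "reference"), ...)
    data.frame(protein_id = id, identity_percent = r$identity_percent,
               similarity_percent = r$similarity_percent,
               alignment_length = r$alignment_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), identity_percent = numeric(),
                      similarity_percent = numeric(),
                      alignment_length = integer(), stringsAsFactors = FALSE)
  }
  out
}
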