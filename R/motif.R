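# SARP-binding consensus scanning.
#
# The binding site of PapR2-like SARPs is the degenerate heptamer
# 5'-GTCAGSS-3' (S = G or C), occurring singly or as direct repeats
# separated by 4 bp spacers. Scoring is fraction-of-consensus identity: a
# base matching the IUPAC-allowed set at its position scores 1 (so a G at
# an S position is a full match), N in the scanned sequence matches
# nothing. Spacer positions are unscored by default; the tri-heptamer
# preset counts them as always-matching positions in the denominator,
# which is the reading under which site identities like 28/29 = 96.6%
# and 19/29 = 65.5% arise.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Per-position allowed-base sets for an IUPAC consensus
#'
#' A site base matches position i iff it is in the allowed set at i. `N`
#' in the consensus allows all four bases; `N` in the scanned site matches
#' nothing (it is never a member of an allowed set).
#'
#' @param consensus IUPAC degenerate string
#' @return list of character vectors, one per consensus position
#' @export
iupac_matcher <- function(consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  if (!nzchar(consensus)) stop("consensus must be nonempty", call. = FALSE)
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' at consensus position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  IUPAC_SETS[chars]
}

#' Build a SARP-binding motif model
#'
#' @param consensus IUPAC heptamer consensus (default the PapR2 consensus
#'   `"GTCAGSS"`)
#' @param repeat_count number of tandem heptamer units in a site
#' @param spacer_length bases between consecutive units (direct repeats
#'   with 4 bp spacers in characterized SARP sites)
#' @param score_spacers if TRUE, spacer positions count as always-matching
#'   positions in both numerator and denominator of the identity
#' @param min_identity minimum identity for a scan hit; the default 6/7
#'   allows at most one mismatch in a single heptamer
#' @return an object of class `motif_model`
#' @export
motif_model <- function(consensus = "GTCAGSS", repeat_count = 1L,
                        spacer_length = 4L, score_spacers = FALSE,
                        min_identity = 6 / 7) {
  sets <- iupac_matcher(consensus)
  hlen <- length(sets)
  repeat_count <- as.integer(repeat_count)
  spacer_length <- as.integer(spacer_length)
  stopifnot(repeat_count >= 1L, spacer_length >= 0L,
            min_identity >= 0, min_identity <= 1)
  span <- repeat_count * hlen + (repeat_count - 1L) * spacer_length
  # expand to the full site span: heptamer sets at unit positions, NULL at
  # spacers; scored mask marks positions entering the identity
  site_sets <- vector("list", span)
  scored <- logical(span)
  unit_of <- integer(span)
  for (r in seq_len(repeat_count)) {
    off <- (r - 1L) * (hlen + spacer_length)
    site_sets[off + seq_len(hlen)] <- sets
    scored[off + seq_len(hlen)] <- TRUE
    unit_of[off + seq_len(hlen)] <- r
    if (r < repeat_count && spacer_length > 0L) {
      sp <- off + hlen + seq_len(spacer_length)
      site_sets[sp] <- list(c("A", "C", "G", "T"))
      scored[sp] <- score_spacers
      unit_of[sp] <- 0L
    }
  }
  structure(list(consensus = toupper(consensus), heptamer_length = hlen,
                 repeat_count = repeat_count, spacer_length = spacer_length,
                 score_spacers = score_spacers, min_identity = min_identity,
                 span = as.integer(span), site_sets = site_sets,
                 scored = scored, unit_of = unit_of),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s x%d (spacer %d bp%s), span %d, min identity %.3f\n",
              x$consensus, x$repeat_count, x$spacer_length,
              if (x$score_spacers) ", spacers scored" else "",
              x$span, x$min_identity))
  invisible(x)
}

#' Named motif presets
#'
#' `"heptamer"` is the default genome-scanning model: the single PapR2
#' heptamer with at most one mismatch. `"tri_heptamer"` models the full
#' three-unit direct-repeat site with two 4 bp spacers scored as
#' always-matching positions (29 scored positions), the mode under which
#' reported site identities of 96.6% and 65.5% arise; its threshold 19/29
#' admits the weakest site still considered a SARP motif.
#'
#' @param name `"heptamer"` or `"tri_heptamer"`
#' @return a [motif_model()]
#' @export
motif_preset <- function(name = c("heptamer", "tri_heptamer")) {
  name <- match.arg(name)
  switch(name,
    heptamer = motif_model(),
    tri_heptamer = motif_model(repeat_count = 3L, score_spacers = TRUE,
                               min_identity = 19 / 29))
}

#' Identity of one site against a motif model
#'
#' @param site DNA string of exactly the model's site span
#' @param model a [motif_model()]
#' @return identity fraction in \[0, 1\]
#' @export
score_site <- function(site, model) {
  stopifnot(inherits(model, "motif_model"))
  site <- normalize_dna(site, what = "site")
  if (nchar(site) != model$span) {
    stop(sprintf("site length %d does not equal model span %d",
                 nchar(site), model$span), call. = FALSE)
  }
  chars <- strsplit(site, "")[[1]]
  idx <- which(model$scored)
  hits <- vapply(idx, function(i) chars[i] %in% model$site_sets[[i]],
                 logical(1))
  sum(hits) / length(idx)
}

#' Scan a sequence for motif sites
#'
#' Every window of the model's span on each requested strand is scored;
#' windows reaching `min_identity` are returned sorted by plus-strand
#' start, `+` before `-` at ties. Minus-strand hits carry plus-strand
#' coordinates but `site_sequence` as read 5' to 3' on the hit strand.
#' Overlapping hits are all reported.
#'
#' @param sequence DNA string over A,C,G,T,N
#' @param model a [motif_model()]
#' @param strands `"both"`, `"+"` or `"-"`
#' @param record_id identifier copied into the hit table
#' @param min_identity override the model threshold
#' @return data frame with columns `record_id`, `start`, `end` (0-based
#'   half-open), `strand`, `identity`, `site_sequence`,
#'   `repeat_count_matched` (units whose own identity reaches the
#'   threshold)
#' @export
scan_motifs <- function(sequence, model = motif_model(),
                        strands = c("both", "+", "-"),
                        record_id = NA_character_, min_identity = NULL) {
  strands <- match.arg(strands)
  stopifnot(inherits(model, "motif_model"))
  sequence <- normalize_dna(sequence)
  if (is.null(min_identity)) min_identity <- model$min_identity
  L <- nchar(sequence)

  hits <- list()
  if (strands %in% c("both", "+")) {
    hits[["+"]] <- scan_one_strand(sequence, model, min_identity)
  }
  if (strands %in% c("both", "-")) {
    h <- scan_one_strand(revcomp(sequence), model, min_identity)
    if (nrow(h)) {
      # map reverse-complement coordinates back to the plus strand
      rc_start <- h$start
      h$start <- L - (rc_start + model$span)
      h$end <- h$start + model$span
    }
    hits[["-"]] <- h
  }
  out <- do.call(rbind, lapply(names(hits), function(s) {
    h <- hits[[s]]
    if (nrow(h)) h$strand <- s
    h
  }))
  if (is.null(out) || !nrow(out)) {
    return(data.frame(record_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), site_sequence = character(),
                      repeat_count_matched = integer(),
                      stringsAsFactors = FALSE))
  }
  out$record_id <- record_id
  out <- out[order(out$start, out$strand, -out$identity),
             c("record_id", "start", "end", "strand", "identity",
               "site_sequence", "repeat_count_matched")]
  rownames(out) <- NULL
  out
}

# vectorized single-strand scan; coordinates 0-based on the given strand
scan_one_strand <- function(sequence, model, min_identity) {
  L <- nchar(sequence)
  span <- model$span
  empty <- data.frame(start = integer(), end = integer(),
                      identity = numeric(), site_sequence = character(),
                      repeat_count_matched = integer(),
                      stringsAsFactors = FALSE)
  if (L < span) return(empty)
  nwin <- L - span + 1L
  chars <- strsplit(sequence, "")[[1]]
  denom <- sum(model$scored)
  counts <- integer(nwin)
  unit_counts <- matrix(0L, nrow = nwin, ncol = model$repeat_count)
  for (i in seq_len(span)) {
    if (!model$scored[i]) next
    m <- chars[i:(i + nwin - 1L)] %in% model$site_sets[[i]]
    counts <- counts + m
    u <- model$unit_of[i]
    if (u > 0L) unit_counts[, u] <- unit_counts[, u] + m
  }
  identity <- counts / denom
  keep <- which(identity >= min_identity - 1e-12)
  if (!length(keep)) return(empty)
  hlen <- model$heptamer_length
  rcm <- rowSums(unit_counts[keep, , drop = FALSE] / hlen >=
                   min(min_identity, 1) - 1e-12)
  data.frame(start = keep - 1L, end = keep - 1L + span,
             identity = identity[keep],
             site_sequence = substring(sequence, keep, keep + span - 1L),
             repeat_count_matched = as.integer(rcm),
             stringsAsFactors = FALSE)
}

#' Scan all records of a genome
#'
#' @param records a `genome_record` or list of them
#' @param model a [motif_model()]
#' @param ... passed to [scan_motifs()]
#' @return combined hit data frame
#' @export
scan_genome <- function(records, model = motif_model(), ...) {
  if (inherits(records, "genome_record")) records <- list(records)
  out <- lapply(records, function(r) {
    scan_motifs(r$sequence, model, record_id = r$record_id, ...)
  })
  do.call(rbind, out)
}

#' Group heptamer hits into direct-repeat arrays
#'
#' Characterized SARP sites are direct heptamer repeats separated by 4 bp
#' spacers, i.e. a start-to-start period of heptamer + spacer bases.
#' Maximal runs of same-strand hits at that period (within `tolerance`
#' bases) are grouped; each array reports the mean identity of its
#' members.
#'
#' @param hits hit data frame from [scan_motifs()] (single-heptamer model)
#' @param heptamer_length unit length
#' @param spacer_length expected spacer
#' @param tolerance allowed deviation of the start-to-start distance
#' @return data frame with one row per array: `record_id`, `strand`,
#'   `start`, `end`, `n_members`, `mean_identity`, `member_starts`
#'   (comma-joined)
#' @export
find_repeat_arrays <- function(hits, heptamer_length = 7L, spacer_length = 4L,
                               tolerance = 0L) {
  period <- heptamer_length + spacer_length
  out <- list()
  for (key in unique(paste(hits$record_id, hits$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    h <- hits[paste(hits$record_id, hits$strand, sep = "\r") == key, ,
              drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    d <- diff(h$start)
    chained <- abs(d - period) <= tolerance
    grp <- cumsum(c(TRUE, !chained))
    for (g in unique(grp)) {
      m <- h[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        record_id = parts[1], strand = parts[2],
        start = min(m$start), end = max(m$end),
        n_members = nrow(m), mean_identity = mean(m$identity),
        member_starts = paste(m$start, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(record_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), mean_identity = numeric(),
                      member_starts = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$record_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export motif hits as BED6
#'
#' Score column is `round(identity * 1000)`.
#'
#' @param hits hit data frame from [scan_motifs()]
#' @param path output path
#' @return `path`, invisibly
#' @export
hits_to_bed <- function(hits, path) {
  bed <- data.frame(hits$record_id, hits$start, hits$end,
                    hits$site_sequence, round_half_up(hits$identity * 1000),
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
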