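# Annotated-genome I/O and coordinate conventions.
#
# Coordinates are 0-based half-open internally; user-facing exports (BED is
# natively 0-based, GenBank 1-based inclusive) convert at the boundary.
# Sequences are upper-cased on read; ambiguity codes other than N are
# rejected unless normalize_ambiguous = TRUE, in which case they become N.

#' Construct a genome record
#'
#' A replicon sequence plus strand-aware gene intervals: the substrate for
#' intergenic-region and promoter-window extraction.
#'
#' @param record_id replicon identifier
#' @param sequence DNA string over A,C,G,T,N
#' @param features data frame with columns `gene_id`, `start` (0-based
#'   inclusive), `end` (exclusive), `strand` (`"+"`/`"-"`), and optionally
#'   `kind` and `product`
#' @param source_taxon optional organism name
#' @return an object of class `genome_record`
#' @export
genome_record <- function(record_id, sequence, features = NULL,
                          source_taxon = NA_character_) {
  sequence <- normalize_dna(sequence, what = sprintf("record %s", record_id))
  len <- nchar(sequence)
  if (is.null(features) || !nrow(features)) {
    features <- data.frame(gene_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           kind = character(), product = character(),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    if (!"kind" %in% names(features)) features$kind <- "CDS"
    if (!"product" %in% names(features)) features$product <- NA_character_
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    bad <- which(!(features$start >= 0L & features$start < features$end &
                     features$end <= len))
    if (length(bad)) {
      stop(sprintf("feature(s) %s have coordinates outside [0, %d)",
                   paste(features$gene_id[bad], collapse = ", "), len),
           call. = FALSE)
    }
    if (!all(features$strand %in% c("+", "-"))) {
      stop("feature strand must be '+' or '-'", call. = FALSE)
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(record_id = record_id, sequence = sequence, length = len,
                 features = features, source_taxon = source_taxon),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d CDS feature(s)\n",
              x$record_id, x$length, sum(x$features$kind == "CDS")))
  invisible(x)
}

#' Read an annotated genome
#'
#' Reads GenBank flat files or a GFF3 + FASTA pair into a list of
#' [genome_record()]s. Every CDS feature becomes a gene feature with its
#' strand; compound (join) locations are flattened to their span with a
#' warning. Sequences are upper-cased.
#'
#' @param path GenBank file, or the GFF3 file when `format = "gff3+fasta"`
#' @param format `"genbank"` or `"gff3+fasta"`
#' @param fasta FASTA path holding the contig sequences (gff3+fasta only)
#' @param normalize_ambiguous if TRUE, IUPAC ambiguity codes other than N
#'   in the sequence are converted to N instead of raising an error
#' @return list of `genome_record`
#' @export
read_genome <- function(path, format = c("genbank", "gff3+fasta"),
                        fasta = NULL, normalize_ambiguous = FALSE) {
  format <- match.arg(format)
  if (format == "genbank") {
    raw <- parse_genbank(path)
    lapply(raw, function(r) {
      if (is.na(r$sequence)) {
        stop(sprintf("record %s has no ORIGIN sequence", r$record_id),
             call. = FALSE)
      }
      sq <- maybe_normalize(r$sequence, normalize_ambiguous, r$record_id)
      f <- r$features
      cds <- f[f$key == "CDS", , drop = FALSE]
      feats <- NULL
      if (nrow(cds)) {
        ids <- pick_gene_ids(cds)
        feats <- data.frame(gene_id = ids, start = cds$start, end = cds$end,
                            strand = cds$strand, kind = "CDS",
                            product = if ("product" %in% names(cds))
                              cds$product else NA_character_,
                            stringsAsFactors = FALSE)
      }
      genome_record(r$record_id, sq, feats, r$source_taxon)
    })
  } else {
    if (is.null(fasta)) {
      stop("format 'gff3+fasta' requires the fasta= argument", call. = FALSE)
    }
    gff <- rtracklayer::import(path, format = "gff3")
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    cds <- gff[gff$type == "CDS"]
    lapply(names(seqs), function(ctg) {
      sq <- maybe_normalize(as.character(seqs[[ctg]]), normalize_ambiguous, ctg)
      sub <- cds[as.character(GenomicRanges::seqnames(cds)) == ctg]
      feats <- NULL
      if (length(sub)) {
        ends <- GenomicRanges::end(sub)
        if (any(ends > nchar(sq))) {
          bad <- which(ends > nchar(sq))[1]
          stop(sprintf("feature '%s' on %s ends at %d beyond contig length %d",
                       feature_id_of(sub[bad]), ctg, ends[bad], nchar(sq)),
               call. = FALSE)
        }
        feats <- data.frame(
          gene_id = vapply(seq_along(sub),
                           function(i) feature_id_of(sub[i]), character(1)),
          start = GenomicRanges::start(sub) - 1L,
          end = ends,
          strand = as.character(GenomicRanges::strand(sub)),
          kind = "CDS",
          product = if (!is.null(sub$product)) as.character(sub$product)
                    else NA_character_,
          stringsAsFactors = FALSE)
        feats$strand[!feats$strand %in% c("+", "-")] <- "+"
      }
      genome_record(ctg, sq, feats)
    })
  }
}

maybe_normalize <- function(sq, normalize_ambiguous, id) {
  if (normalize_ambiguous) {
    sq <- toupper(sq)
    sq <- gsub("[RYSWKMBDHV]", "N", sq)
  }
  normalize_dna(sq, what = sprintf("record %s", id))
}

pick_gene_ids <- function(cds) {
  ids <- rep(NA_character_, nrow(cds))
  for (col in c("locus_tag", "gene", "protein_id")) {
    if (col %in% names(cds)) ids[is.na(ids)] <- cds[[col]][is.na(ids)]
  }
  auto <- is.na(ids)
  ids[auto] <- sprintf("cds_%d", which(auto))
  ids
}

feature_id_of <- function(gr) {
  for (col in c("ID", "locus_tag", "Name", "gene")) {
    v <- S4Vectors::mcols(gr)[[col]]
    if (!is.null(v) && !is.na(v[1])) return(as.character(v[1]))
  }
  sprintf("cds_%d_%d", GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Extract intergenic regions
#'
#' Returns the maximal intervals of a replicon not covered by any CDS,
#' regardless of strand, including the stretches before the first and after
#' the last CDS. Motif hits are later filtered to these regions because
#' biologically meaningful SARP binding sites sit in promoters, not inside
#' coding sequence. A record with zero CDS yields one region spanning the
#' whole replicon.
#'
#' @param record a [genome_record()]
#' @param min_length drop regions shorter than this many bases
#' @return data frame with columns `record_id`, `start`, `end` (0-based
#'   half-open), `flank_left_gene`, `flank_right_gene`, `sequence`
#' @export
extract_intergenic <- function(record, min_length = 1L) {
  stopifnot(inherits(record, "genome_record"))
  L <- record$length
  cds <- record$features[record$features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) {
    gaps <- IRanges::IRanges(start = 1L, end = L)
  } else {
    ir <- IRanges::reduce(IRanges::IRanges(start = cds$start + 1L,
                                           end = cds$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
  }
  if (!length(gaps)) {
    return(data.frame(record_id = character(), start = integer(),
                      end = integer(), flank_left_gene = character(),
                      flank_right_gene = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  start0 <- IRanges::start(gaps) - 1L
  end0 <- IRanges::end(gaps)
  keep <- (end0 - start0) >= min_length
  start0 <- start0[keep]; end0 <- end0[keep]
  flank <- function(pos, side) {
    vapply(pos, function(p) {
      if (side == "left") {
        cand <- cds$gene_id[cds$end <= p]
        if (length(cand)) cand[which.max(cds$end[cds$end <= p])]
        else NA_character_
      } else {
        cand <- cds$gene_id[cds$start >= p]
        if (length(cand)) cand[which.min(cds$start[cds$start >= p])]
        else NA_character_
      }
    }, character(1))
  }
  data.frame(record_id = record$record_id, start = start0, end = end0,
             flank_left_gene = if (nrow(cds)) flank(start0, "left")
                               else NA_character_,
             flank_right_gene = if (nrow(cds)) flank(end0, "right")
                                else NA_character_,
             sequence = substring(record$sequence, start0 + 1L, end0),
             stringsAsFactors = FALSE)
}

#' Extract the promoter window upstream of a gene
#'
#' For a plus-strand gene at \[s, e) the window is
#' \[max(0, s - window_length), s); for a minus-strand gene it is
#' \[e, min(L, e + window_length)) with the sequence reverse-complemented,
#' so the returned sequence always reads 5' to 3' towards the gene's start
#' codon. With `clip_at_neighbor` the window stops at the nearest CDS
#' boundary so it never reaches into the upstream gene.
#'
#' The default window of 350 bases conservatively covers the 182-230 bp
#' upstream fragments in which SARP binding has been demonstrated
#' experimentally, while bounding the search space.
#'
#' @param record a [genome_record()]
#' @param gene_id gene to take the upstream region of
#' @param window_length maximum window size in bases
#' @param clip_at_neighbor stop the window at the nearest upstream CDS
#' @return list with `gene_id`, `start`, `end` (plus-strand 0-based
#'   half-open), `strand`, `window_length`, `sequence`
#' @export
promoter_window <- function(record, gene_id, window_length = 350L,
                            clip_at_neighbor = TRUE) {
  stopifnot(inherits(record, "genome_record"))
  f <- record$features
  i <- which(f$gene_id == gene_id)
  if (!length(i)) {
    stop(sprintf("gene '%s' not found in record %s", gene_id,
                 record$record_id), call. = FALSE)
  }
  i <- i[1]
  L <- record$length
  others <- f[-i, , drop = FALSE]
  if (f$strand[i] == "+") {
    s <- f$start[i]
    ws <- max(0L, s - as.integer(window_length))
    if (clip_at_neighbor && nrow(others)) {
      upstream_end <- others$end[others$end <= s]
      if (length(upstream_end)) ws <- max(ws, max(upstream_end))
    }
    we <- s
    sq <- substring(record$sequence, ws + 1L, we)
  } else {
    e <- f$end[i]
    we <- min(L, e + as.integer(window_length))
    if (clip_at_neighbor && nrow(others)) {
      downstream_start <- others$start[others$start >= e]
      if (length(downstream_start)) we <- min(we, min(downstream_start))
    }
    ws <- e
    sq <- revcomp(substring(record$sequence, ws + 1L, we))
  }
  list(gene_id = gene_id, start = ws, end = we, strand = f$strand[i],
       window_length = as.integer(window_length), sequence = sq)
}

#' Export intergenic regions as BED6
#'
#' BED is natively 0-based half-open so coordinates pass through unchanged;
#' the name field joins the flanking gene pair and strand is ".".
#'
#' @param regions data frame from [extract_intergenic()]
#' @param path output path
#' @return `path`, invisibly
#' @export
intergenic_to_bed <- function(regions, path) {
  name <- paste(ifelse(is.na(regions$flank_left_gene), ".",
                       regions$flank_left_gene),
                ifelse(is.na(regions$flank_right_gene), ".",
                       regions$flank_right_gene), sep = "|")
  bed <- data.frame(regions$record_id, regions$start, regions$end,
                    name, 0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
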