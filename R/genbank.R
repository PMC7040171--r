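# Minimal GenBank flat-file reader/writer.
#
# No installed R package parses GenBank flat files, so the package carries
# its own small parser covering what annotated bacterial genomes and
# antiSMASH region files need: LOCUS, FEATURES with single-interval or
# complement()/join() locations plus /qualifiers, and ORIGIN. join()
# compound locations are flattened to their span with a warning.

#' Parse a GenBank flat file into raw records
#'
#' Low-level parser used by [read_genome()] and [load_regions()]. Each
#' record is returned as a list with `record_id`, `length`, `sequence`
#' (may be `NA` if the file has no ORIGIN block), `source_taxon` and a
#' data frame `features` with columns `key`, `start` (0-based), `end`
#' (exclusive), `strand`, `compound` and one column per qualifier seen
#' (`locus_tag`, `gene`, `product`, ...).
#'
#' @param path path to a GenBank flat file
#' @return list of raw record lists
#' @export
parse_genbank <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read GenBank file: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines))) {
    stop(sprintf("not a GenBank flat file (no LOCUS line): %s", path),
         call. = FALSE)
  }
  # split into records on the '//' terminator
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) parse_genbank_record(lines[s:e]),
         starts, ends, SIMPLIFY = FALSE)
}

parse_genbank_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  record_id <- toks[2]
  declared_len <- suppressWarnings(as.integer(toks[3]))

  organism <- NA_character_
  org_line <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  if (length(org_line)) organism <- trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1]))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  feat_end <- if (length(orig_i)) orig_i[1] - 1L else length(lines)

  features <- if (length(feat_i)) {
    parse_genbank_features(lines[(feat_i[1] + 1L):feat_end])
  } else {
    empty_feature_table()
  }

  sequence <- NA_character_
  if (length(orig_i)) {
    seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  len <- if (!is.na(sequence)) nchar(sequence) else declared_len

  list(record_id = record_id, length = len, sequence = sequence,
       source_taxon = organism, features = features)
}

empty_feature_table <- function() {
  data.frame(key = character(), start = integer(), end = integer(),
             strand = character(), compound = logical(),
             stringsAsFactors = FALSE)
}

parse_genbank_features <- function(lines) {
  # feature keys start at column 6; qualifier/continuation lines at column 22
  is_key <- grepl("^\\s{5}\\S", lines)
  key_idx <- which(is_key)
  if (!length(key_idx)) return(empty_feature_table())
  blocks <- mapply(function(s, e) lines[s:e], key_idx,
                   c(utils::tail(key_idx, -1L) - 1L, length(lines)),
                   SIMPLIFY = FALSE)
  feats <- lapply(blocks, parse_feature_block)
  feats <- feats[!vapply(feats, is.null, logical(1))]
  if (!length(feats)) return(empty_feature_table())
  qual_names <- unique(unlist(lapply(feats, function(f) names(f$quals))))
  rows <- lapply(feats, function(f) {
    row <- data.frame(key = f$key, start = f$start, end = f$end,
                      strand = f$strand, compound = f$compound,
                      stringsAsFactors = FALSE)
    for (q in qual_names) {
      row[[q]] <- if (q %in% names(f$quals)) f$quals[[q]] else NA_character_
    }
    row
  })
  do.call(rbind, rows)
}

parse_feature_block <- function(block) {
  first <- block[1]
  key <- sub("^\\s+(\\S+).*$", "\\1", first)
  loc <- trimws(sub("^\\s+\\S+\\s*", "", first))
  # location may continue on following lines until a /qualifier starts
  i <- 2L
  while (i <= length(block) && !grepl("^\\s+/", block[i])) {
    loc <- paste0(loc, trimws(block[i]))
    i <- i + 1L
  }
  parsed <- parse_genbank_location(loc)
  if (is.null(parsed)) return(NULL)

  quals <- list()
  cur_name <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_name) && !(cur_name %in% names(quals))) {
      quals[[cur_name]] <<- gsub("\"", "", cur_val)
    }
  }
  while (i <= length(block)) {
    ln <- block[i]
    if (grepl("^\\s+/", ln)) {
      flush()
      q <- sub("^\\s+/", "", ln)
      eq <- regexpr("=", q, fixed = TRUE)
      if (eq > 0) {
        cur_name <- substr(q, 1L, eq - 1L)
        cur_val <- substr(q, eq + 1L, nchar(q))
      } else {
        cur_name <- q
        cur_val <- "true"
      }
    } else if (!is.null(cur_name)) {
      cur_val <- paste0(cur_val, trimws(ln))
    }
    i <- i + 1L
  }
  flush()

  list(key = key, start = parsed$start, end = parsed$end,
       strand = parsed$strand, compound = parsed$compound, quals = quals)
}

# returns 0-based half-open coordinates; join() flattened to span
parse_genbank_location <- function(loc) {
  strand <- "+"
  compound <- FALSE
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^(join|order)\\(", x)) {
    compound <- TRUE
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  }
  x <- gsub("[<>]", "", x)
  nums <- as.numeric(unlist(regmatches(x, gregexpr("[0-9]+", x))))
  if (!length(nums)) return(NULL)
  if (compound) {
    warning(sprintf("compound location '%s' flattened to its span", loc),
            call. = FALSE)
  }
  list(start = as.integer(min(nums)) - 1L, end = as.integer(max(nums)),
       strand = strand, compound = compound)
}

#' Write genome records as a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN blocks that round-trip through
#' [read_genome()]. Minus-strand features are written as
#' \code{complement(a..b)}; coordinates are converted to the 1-based
#' inclusive GenBank convention.
#'
#' @param records list of `genome_record` objects (see [genome_record()])
#' @param path output path
#' @param extra_features optional data frame of additional features with
#'   columns `record_id`, `key`, `start`, `end` (0-based half-open),
#'   `strand`, and optional qualifier columns (e.g. `product`)
#' @return `path`, invisibly
#' @export
write_genbank <- function(records, path, extra_features = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000",
                       rec$record_id, rec$length), con)
    writeLines(sprintf("DEFINITION  synthetic record %s.", rec$record_id), con)
    writeLines(sprintf("ACCESSION   %s", rec$record_id), con)
    if (!is.null(rec$source_taxon) && !is.na(rec$source_taxon)) {
      writeLines("SOURCE      synthetic construct", con)
      writeLines(sprintf("  ORGANISM  %s", rec$source_taxon), con)
    }
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rec$length), con)
    feats <- rec$features
    if (!is.null(feats) && nrow(feats)) {
      for (k in seq_len(nrow(feats))) {
        write_gbk_feature(con, "CDS", feats$start[k], feats$end[k],
                          feats$strand[k],
                          locus_tag = feats$gene_id[k],
                          product = feats$product[k])
      }
    }
    if (!is.null(extra_features) && nrow(extra_features)) {
      ef <- extra_features[extra_features$record_id == rec$record_id, ,
                           drop = FALSE]
      qual_cols <- setdiff(names(ef),
                           c("record_id", "key", "start", "end", "strand"))
      for (k in seq_len(nrow(ef))) {
        quals <- lapply(qual_cols, function(q) ef[[q]][k])
        names(quals) <- qual_cols
        do.call(write_gbk_feature,
                c(list(con, ef$key[k], ef$start[k], ef$end[k], ef$strand[k]),
                  quals))
      }
    }
    writeLines("ORIGIN", con)
    sq <- tolower(rec$sequence)
    pos <- seq(1L, nchar(sq), by = 60L)
    for (p in pos) {
      chunk <- substr(sq, p, min(p + 59L, nchar(sq)))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

write_gbk_feature <- function(con, key, start0, end0, strand, ...) {
  loc <- sprintf("%d..%d", start0 + 1L, end0)
  if (identical(strand, "-")) loc <- sprintf("complement(%s)", loc)
  writeLines(sprintf("     %-15s %s", key, loc), con)
  quals <- list(...)
  for (q in names(quals)) {
    v <- quals[[q]]
    if (is.null(v) || is.na(v)) next
    writeLines(sprintf("                     /%s=\"%s\"", q, v), con)
  }
}
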