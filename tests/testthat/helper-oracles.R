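# Independent oracles used by the unit and property suites. They stay
# deliberately naive: per-base loops and enumeration, no sharing of the
# package's scanning code paths.

# position-by-position identity of a site against IUPAC sets, counting
# only scored positions (naive double-loop oracle for score_site)
naive_identity <- function(site, consensus, spacer_positions = integer(0),
                           score_spacers = FALSE) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  sc <- strsplit(site, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  hits <- 0; denom <- 0
  for (i in seq_along(cc)) {
    spacer <- i %in% spacer_positions
    if (spacer && !score_spacers) next
    denom <- denom + 1
    ok <- if (spacer) sc[i] %in% c("A", "C", "G", "T")
          else sc[i] %in% sets[[cc[i]]]
    if (ok) hits <- hits + 1
  }
  hits / denom
}

# exhaustive window enumeration on both strands; 0-based plus-strand
# coordinates like scan_motifs
brute_scan <- function(sequence, consensus = "GTCAGSS", min_identity = 6 / 7) {
  span <- nchar(consensus)
  L <- nchar(sequence)
  rows <- list()
  strands <- list(`+` = sequence, `-` = sarpscout::revcomp(sequence))
  for (s in names(strands)) {
    sq <- strands[[s]]
    if (L < span) next
    for (j in 0:(L - span)) {
      site <- substr(sq, j + 1, j + span)
      id <- naive_identity(site, consensus)
      if (id >= min_identity - 1e-12) {
        start <- if (s == "+") j else L - j - span
        rows[[length(rows) + 1L]] <- data.frame(
          start = start, end = start + span, strand = s, identity = id,
          site_sequence = site, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      site_sequence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, -out$identity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base CDS coverage mask oracle for intergenic extraction
brute_intergenic_mask <- function(record) {
  covered <- rep(FALSE, record$length)
  f <- record$features
  for (i in seq_len(nrow(f))) {
    if (f$kind[i] != "CDS") next
    covered[(f$start[i] + 1):f$end[i]] <- TRUE
  }
  !covered
}

# Gotoh global alignment score with affine gaps and end-gap penalties,
# independent of Biostrings (oracle for the optimal alignment score)
gotoh_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (deletion)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (insertion)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[x[i - 1], y[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# two-gene toy genome used across seqio tests
toy_record <- function() {
  set.seed(11)
  genome_record(
    "toy1", random_dna(500, gc = 0.5),
    data.frame(gene_id = c("gA", "gB"), start = c(100L, 300L),
               end = c(200L, 400L), strand = c("+", "-"),
               stringsAsFactors = FALSE))
}
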