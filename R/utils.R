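#' @keywords internal
"_PACKAGE"

#' Round half away from zero to the nearest integer
#'
#' Percentage reporting throughout the package uses round-half-up (0.5 goes
#' to 1), not R's banker's rounding, so that printed census and similarity
#' percentages recompute exactly from their counts.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Reverse-complement a DNA string
#'
#' @param x character scalar over {A,C,G,T,N} (case-insensitive)
#' @return reverse complement, upper case
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# validate a DNA string; upper-cases, optionally rejects ambiguity codes
# other than N
normalize_dna <- function(x, allow_iupac = FALSE, what = "sequence") {
  x <- toupper(x)
  ok <- if (allow_iupac) "ACGTNRYSWKMBDHV" else "ACGTN"
  bad <- gsub(sprintf("[%s]", ok), "", x)
  if (nzchar(bad)) {
    stop(sprintf("%s contains invalid characters: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ",")),
         call. = FALSE)
  }
  x
}

# 0-based half-open -> 1-based inclusive (GenBank convention) and back
to1based <- function(start0) start0 + 1L
to0based <- function(start1) start1 - 1L
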