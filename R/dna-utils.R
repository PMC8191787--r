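#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the ACGT alphabet.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("AAAA")   # "TTTT"
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @keywords internal
.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s contains non-ACGT characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")))
  invisible(x)
}

## integer encoding A=0, C=1, G=2, T=3 (lexicographic base order)
#' @keywords internal
.dna_to_int <- function(seq) {
  v <- utf8ToInt(seq)
  out <- integer(length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

#' @keywords internal
.int_to_dna <- function(v) {
  paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
}

#' Hamming distance between two equal-length sequences
#'
#' Number of positions at which two strings differ.
#'
#' @param a,b character scalars of equal length.
#' @return integer mismatch count.
#' @examples
#' hamming("ACGT", "ACGT")  # 0
#' hamming("AAAA", "TTTT")  # 4
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming() requires equal-length sequences")
  sum(utf8ToInt(a) != utf8ToInt(b))
}
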