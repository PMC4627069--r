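#' @keywords internal
DNA_BASES4 <- c("A", "C", "G", "T")

#' Encode a DNA string as integers
#'
#' A/C/G/T map to 0..3; N (and any other IUPAC ambiguity) maps to 4.
#' @param x character scalar, a DNA string.
#' @return integer vector of codes in 0..4.
#' @keywords internal
encode_dna <- function(x) {
  v <- charToRaw(toupper(x))
  out <- integer(length(v))
  out[] <- 4L
  out[v == charToRaw("A")] <- 0L
  out[v == charToRaw("C")] <- 1L
  out[v == charToRaw("G")] <- 2L
  out[v == charToRaw("T")] <- 3L
  out
}

#' @keywords internal
decode_dna <- function(codes) {
  paste(c(DNA_BASES4, "N")[codes + 1L], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Handles A/C/G/T/N; other letters become N.
#' @param x character scalar.
#' @return character scalar.
#' @export
#' @examples
#' revcomp_dna("ATGC")  # "GCAT"
revcomp_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    gsub("[^ACGTNacgtn]", "N", x)
  )))
}

#' Reverse complement of a position probability matrix
#'
#' Rows are motif columns 5'->3'; columns are A,C,G,T probabilities.
#' @param ppm numeric matrix, width x 4.
#' @return numeric matrix of the same shape.
#' @export
revcomp_ppm <- function(ppm) {
  stopifnot(is.matrix(ppm), ncol(ppm) == 4L)
  out <- ppm[rev(seq_len(nrow(ppm))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES4
  rownames(out) <- NULL
  out
}

#' @keywords internal
consensus_of_ppm <- function(ppm) {
  paste(DNA_BASES4[max.col(ppm, ties.method = "first")], collapse = "")
}

#' @keywords internal
check_background <- function(background) {
  stopifnot(is.numeric(background), length(background) == 4L,
            all(background > 0), abs(sum(background) - 1) < 1e-6)
  background / sum(background)
}

# Sample one or more bases from a 4-vector of probabilities.
#' @keywords internal
sample_bases <- function(n, background) {
  sample(DNA_BASES4, n, replace = TRUE, prob = background)
}
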