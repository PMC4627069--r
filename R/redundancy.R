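# Redundancy reduction of sequence sets by pairwise global-alignment
# identity, as applied before motif discovery and at each profile-search
# iteration.

# Substitution matrix over A,C,G,T,N: N matches nothing (mismatch even
# against N).
#' @keywords internal
dna_submat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

#' Percent identity from a global alignment
#'
#' Aligns two sequences globally (Needleman-Wunsch with affine gaps;
#' defaults match +1, mismatch -1, gap open 5, gap extend 1 as costs) and
#' reports identity as matching columns divided by the alignment length
#' including gap columns (`denominator = "alignment"`), or by the shorter
#' sequence length (`denominator = "shorter"`). N matches nothing.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend alignment scores; gap costs
#'   are positive penalties, a run of L gaps costing
#'   `gap_open + L * gap_extend`.
#' @param denominator identity denominator dialect.
#' @return a list of class `identity_result` with `identity`,
#'   `aligned_length` and `matches`.
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")$identity  # 0.75
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 5, gap_extend = 1,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in pairwise_identity")
  a <- toupper(a); b <- toupper(b)
  nw <- nw_identity_cpp(encode_dna(a), encode_dna(b), match, mismatch,
                        gap_open, gap_extend)
  denom <- if (denominator == "alignment") nw$alen else
    min(nchar(a), nchar(b))
  structure(list(identity = nw$matches / denom,
                 aligned_length = nw$alen,
                 matches = nw$matches,
                 score = nw$score),
            class = "identity_result")
}

# Set of k-mers of a sequence (unique, as strings).
#' @keywords internal
kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Greedy redundancy filter at a pairwise-identity threshold
#'
#' Iterates records in input order and keeps a record iff its identity to
#' every already-kept record is below `threshold` (CD-HIT-style greedy
#' representative selection). An optional k-mer prefilter (k = 8) skips the
#' alignment when the shared-k-mer fraction, intersection over the smaller
#' k-mer set, is below 0.2 — far under any identity near the threshold.
#'
#' @param records a [dloop_set()] or named character vector.
#' @param threshold maximum allowed pairwise identity (default 0.90, i.e.
#'   retained sequences are less than 90 percent identical).
#' @param prefilter use the k-mer prefilter (default TRUE).
#' @param ... passed to [pairwise_identity()].
#' @return list with `kept` (same class as input, subset) and `dropped`
#'   (data.frame `dropped_id`, `kept_id`, `identity` naming, for every
#'   dropped record, the first kept record that excluded it).
#' @export
filter_redundancy <- function(records, threshold = 0.90, prefilter = TRUE,
                              ...) {
  stopifnot(threshold > 0, threshold <= 1)
  seqs <- dloop_seqs(records)
  if (!length(seqs)) stop("filter_redundancy: empty input")
  ids <- names(seqs)
  ksets <- if (prefilter) lapply(seqs, kmer_set) else NULL
  kept_idx <- integer(0)
  dropped <- list()
  for (i in seq_along(seqs)) {
    excluded_by <- NA_integer_
    excl_ident <- NA_real_
    for (j in kept_idx) {
      if (prefilter) {
        shared <- length(intersect(ksets[[i]], ksets[[j]])) /
          max(1L, min(length(ksets[[i]]), length(ksets[[j]])))
        if (shared < 0.2) next
      }
      idn <- pairwise_identity(seqs[[i]], seqs[[j]], ...)$identity
      if (idn >= threshold) {
        excluded_by <- j
        excl_ident <- idn
        break
      }
    }
    if (is.na(excluded_by)) {
      kept_idx <- c(kept_idx, i)
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(dropped_id = ids[i], kept_id = ids[excluded_by],
                   identity = excl_ident, stringsAsFactors = FALSE)
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(dropped_id = character(0), kept_id = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  kept <- if (inherits(records, "dloop_set"))
    records[records$id %in% ids[kept_idx], , drop = FALSE]
  else seqs[kept_idx]
  if (inherits(kept, "data.frame")) class(kept) <- c("dloop_set", "data.frame")
  list(kept = kept, dropped = dropped)
}

#' Write the dropped-pairs report of [filter_redundancy()] as TSV
#' @param dropped the `dropped` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dropped_tsv <- function(dropped, path) {
  write.table(dropped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
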