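# Iterative profile-based homology search: build a match/insert/delete
# profile from a multiple alignment, score sequences glocally (global in
# the profile, local in the sequence), admit hits above a bit threshold,
# realign, filter redundancy, rebuild, and iterate to a fixed point.

# ---------------------------------------------------------------------------
# Progressive (center-star) alignment
# ---------------------------------------------------------------------------

#' Center-star progressive multiple alignment
#'
#' Aligns every sequence globally to the first one (the center), in order
#' of decreasing identity to it, and merges the pairwise alignments into a
#' single multiple alignment ("once a gap, always a gap"). Intended for
#' realignment of short homologous regions inside the iterative profile
#' search; externally produced aligned FASTA can be used instead anywhere
#' an alignment is accepted.
#'
#' @param seqs named character vector of >= 1 sequences; the first is the
#'   center.
#' @param ... scoring parameters passed to [pairwise_identity()].
#' @return named character vector of equal-length gapped sequences.
#' @export
align_center_star <- function(seqs, ...) {
  seqs <- dloop_seqs(seqs)
  n <- length(seqs)
  if (n == 1L) return(seqs)
  center <- seqs[[1]]
  Lc <- nchar(center)
  others <- seqs[-1]
  idents <- vapply(others, function(s)
    pairwise_identity(center, s, ...)$identity, numeric(1))
  others <- others[order(-idents)]

  # per-sequence: aligned char at each center position + inserted runs at
  # each of the Lc+1 slots (slot k = between center chars k and k+1)
  rows <- list()
  ins_len <- integer(Lc + 1L)
  for (nm in names(others)) {
    pw <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(center), Biostrings::DNAString(others[[nm]]),
      type = "global", substitutionMatrix = dna_submat(),
      gapOpening = 5, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(pw)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(pw)), "")[[1]]
    aligned <- character(Lc)
    ins <- vector("list", Lc + 1L)
    pos <- 0L
    for (c_i in seq_along(pa)) {
      if (pa[c_i] != "-") {
        pos <- pos + 1L
        aligned[pos] <- pb[c_i]
      } else {
        ins[[pos + 1L]] <- c(ins[[pos + 1L]], pb[c_i])
      }
    }
    rows[[nm]] <- list(aligned = aligned, ins = ins)
    ins_len <- pmax(ins_len, lengths(ins))
  }

  pad <- function(chars, k) {
    c(chars, rep("-", k - length(chars)))
  }
  assemble <- function(aligned, ins) {
    out <- character(0)
    for (p in 0:Lc) {
      if (ins_len[p + 1L] > 0L)
        out <- c(out, pad(if (p + 1L <= length(ins)) ins[[p + 1L]] else
          character(0), ins_len[p + 1L]))
      if (p < Lc) out <- c(out, aligned[p + 1L])
    }
    paste(out, collapse = "")
  }
  center_row <- assemble(strsplit(center, "")[[1]],
                         vector("list", Lc + 1L))
  msa <- c(setNames(center_row, names(seqs)[1]),
           vapply(rows, function(r) assemble(r$aligned, r$ins),
                  character(1)))
  msa[names(seqs)[names(seqs) %in% names(msa)]]
}

#' Read an aligned FASTA file
#' @param path aligned FASTA (gap character `-`).
#' @return named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  xs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(xs))
  names(out) <- vapply(strsplit(names(xs), "\\s+"), `[`, character(1), 1L)
  if (length(unique(nchar(out))) > 1L)
    stop("aligned FASTA has inconsistent row widths: ", path)
  out
}

# ---------------------------------------------------------------------------
# Profile construction
# ---------------------------------------------------------------------------

#' Build a match/insert/delete profile from a multiple alignment
#'
#' Columns with at least 50 percent residue occupancy become match states.
#' Match emissions are smoothed column counts (pseudocount
#' `0.25 * background` per column); insert emissions are the background.
#' Transition probabilities come from the per-sequence state paths with
#' Laplace add-one smoothing; inserts before the first and after the last
#' match state are treated as (free) flanks, matching the glocal scoring
#' model.
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences (>= 2), or a path to an aligned FASTA file.
#' @param background 4-vector; estimated from the alignment when NULL.
#' @param occupancy_min minimum residue fraction for a match column.
#' @param beta pseudocount mass per emission column.
#' @return an object of class `profile_model`: `length`,
#'   `match_emissions` (length x 4), `insert_emissions`, `begin` (2-vector
#'   to M1/D1), `trans_m`, `trans_i`, `trans_d` (length x 3 rows of
#'   probabilities to the next match / same-position insert / next delete
#'   state; at the last state the first slot leads to End), `background`,
#'   `source_alignment_ids`.
#' @export
build_profile <- function(alignment, background = NULL,
                          occupancy_min = 0.5, beta = 0.25) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- read_alignment(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 2L)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have inconsistent widths: ",
         paste(unique(widths), collapse = ", "))
  if (is.null(names(alignment)))
    names(alignment) <- paste0("seq_", seq_along(alignment))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ncolu <- ncol(mat)
  nseq <- nrow(mat)
  occupancy <- colMeans(mat != "-")
  is_match <- occupancy >= occupancy_min
  Lp <- sum(is_match)
  if (Lp == 0L) stop("no alignment column reaches match occupancy")
  if (is.null(background)) {
    resid <- mat[mat != "-" & mat != "N"]
    if (!length(resid)) stop("alignment contains no residues")
    f <- table(factor(resid, levels = DNA_BASES4))
    background <- pmax(as.numeric(f) / sum(f), 1e-4)
    background <- background / sum(background)
  }
  background <- check_background(background)

  # emissions over match columns
  em <- matrix(0, Lp, 4, dimnames = list(NULL, DNA_BASES4))
  mcols <- which(is_match)
  for (j in seq_len(Lp)) {
    col <- mat[, mcols[j]]
    for (b in seq_len(4L)) em[j, b] <- sum(col == DNA_BASES4[b])
    em[j, ] <- em[j, ] + sum(col == "N") * background  # N spread as background
    em[j, ] <- em[j, ] + beta * background
    em[j, ] <- em[j, ] / sum(em[j, ])
  }

  # transition counts from per-sequence state paths; state index j is the
  # number of match columns passed. Flanking inserts (j == 0 or j == Lp
  # with no further match event) are dropped.
  cnt_b <- c(M = 0, D = 0)
  cnt_m <- matrix(0, Lp, 3, dimnames = list(NULL, c("M", "I", "D")))
  cnt_i <- matrix(0, Lp, 3, dimnames = list(NULL, c("M", "I", "D")))
  cnt_d <- matrix(0, Lp, 3, dimnames = list(NULL, c("M", "I", "D")))
  match_rank <- cumsum(is_match)
  for (s in seq_len(nseq)) {
    prev <- "B"; prev_j <- 0L
    events <- list()
    for (cx in seq_len(ncolu)) {
      if (is_match[cx]) {
        events[[length(events) + 1L]] <-
          list(state = if (mat[s, cx] == "-") "D" else "M",
               j = match_rank[cx])
      } else if (mat[s, cx] != "-") {
        j <- match_rank[cx]
        if (j >= 1L && j <= Lp - 1L)  # internal insert only
          events[[length(events) + 1L]] <- list(state = "I", j = j)
      }
    }
    for (ev in events) {
      if (prev == "B") cnt_b[ev$state] <- cnt_b[ev$state] + 1
      else if (prev == "M") cnt_m[prev_j, ev$state] <-
          cnt_m[prev_j, ev$state] + 1
      else if (prev == "I") cnt_i[prev_j, ev$state] <-
          cnt_i[prev_j, ev$state] + 1
      else cnt_d[prev_j, ev$state] <- cnt_d[prev_j, ev$state] + 1
      prev <- ev$state; prev_j <- ev$j
    }
    # final transition to End recorded in the "M" slot of the last state
    if (prev != "B") {
      if (prev == "M") cnt_m[prev_j, "M"] <- cnt_m[prev_j, "M"] + 1
      else if (prev == "I") cnt_i[prev_j, "M"] <- cnt_i[prev_j, "M"] + 1
      else cnt_d[prev_j, "M"] <- cnt_d[prev_j, "M"] + 1
    }
  }
  smooth <- function(cnt) {
    p <- cnt + 1  # Laplace add-one
    p / rowSums(p)
  }
  # last state: only End (slot M) and I_Lp (unused in glocal scoring) make
  # sense; renormalize the last row over {End}.
  tm <- smooth(cnt_m); ti <- smooth(cnt_i); td <- smooth(cnt_d)
  tm[Lp, ] <- c(1, 0, 0); ti[Lp, ] <- c(1, 0, 0); td[Lp, ] <- c(1, 0, 0)
  begin <- (cnt_b + 1) / sum(cnt_b + 1)
  structure(list(length = Lp, match_emissions = em,
                 insert_emissions = setNames(background, DNA_BASES4),
                 begin = begin, trans_m = tm, trans_i = ti, trans_d = td,
                 background = setNames(background, DNA_BASES4),
                 source_alignment_ids = names(alignment)),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model with", x$length, "match states from",
      length(x$source_alignment_ids), "aligned sequences\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Glocal Viterbi scoring
# ---------------------------------------------------------------------------

#' Score a sequence against a profile (glocal Viterbi)
#'
#' Best-path log2-odds score of an alignment global in the profile and
#' local in the sequence (free flanks), computed in log space. In
#' both-strand mode the reverse complement is scored too and the better
#' strand is reported; the hit interval is on the forward sequence.
#'
#' @param profile a `profile_model`.
#' @param seq DNA string.
#' @param strand_mode `"one_strand"` or `"both_strands"`.
#' @param seq_id id for the report.
#' @return a one-row data.frame (class `profile_hit`): `seq_id`, `start`,
#'   `end` (0-based half-open), `strand`, `bitscore`.
#' @export
score_sequence <- function(profile, seq,
                           strand_mode = c("one_strand", "both_strands"),
                           seq_id = "seq") {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(profile, "profile_model"), nchar(seq) >= 1L)
  l2m <- log2(profile$match_emissions /
                matrix(rep(profile$background, each = profile$length),
                       profile$length, 4))
  l2i <- log2(profile$insert_emissions / profile$background)
  logt <- function(p) ifelse(p > 0, log2(p), -1e30)
  tb <- logt(profile$begin)
  tm <- logt(profile$trans_m); ti <- logt(profile$trans_i)
  td <- logt(profile$trans_d)
  run <- function(s) profile_viterbi_cpp(encode_dna(s), l2m, l2i, tb,
                                         tm, ti, td)
  fwd <- run(seq)
  hit <- data.frame(seq_id = seq_id, start = fwd$start, end = fwd$end,
                    strand = "+", bitscore = fwd$score,
                    stringsAsFactors = FALSE)
  if (strand_mode == "both_strands") {
    L <- nchar(seq)
    rev <- run(revcomp_dna(seq))
    if (rev$score > fwd$score)
      hit <- data.frame(seq_id = seq_id, start = L - rev$end,
                        end = L - rev$start, strand = "-",
                        bitscore = rev$score, stringsAsFactors = FALSE)
  }
  class(hit) <- c("profile_hit", "data.frame")
  hit
}

#' Score every sequence of a set against a profile
#' @inheritParams score_sequence
#' @param records a [dloop_set()] or named character vector.
#' @return data.frame of hits, one row per sequence.
#' @export
score_all <- function(profile, records,
                      strand_mode = c("one_strand", "both_strands")) {
  strand_mode <- match.arg(strand_mode)
  seqs <- dloop_seqs(records)
  out <- do.call(rbind, lapply(names(seqs), function(id)
    score_sequence(profile, seqs[[id]], strand_mode, seq_id = id)))
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Iterative search
# ---------------------------------------------------------------------------

#' Iterative profile search to a membership fixed point
#'
#' Starting from seed sequences, each round (1) filters current members
#' for redundancy, (2) realigns them (center-star, or a supplied aligner),
#' (3) builds a profile, (4) scores the whole database, and (5) admits as
#' new members every database sequence with bitscore >= `include_bits`.
#' Iteration stops when the member id set repeats (a verified fixed point)
#' or after `max_rounds`.
#'
#' @param seeds named character vector or [dloop_set()] of seed sequences
#'   (ids may, but need not, occur in the database).
#' @param database named character vector or [dloop_set()] to search.
#' @param include_bits inclusion threshold in bits (default 10).
#' @param max_rounds maximum rounds (default 10).
#' @param strand_mode passed to [score_all()].
#' @param redundancy_threshold identity threshold used on members before
#'   realignment.
#' @param aligner function(named character) -> alignment; defaults to
#'   [align_center_star()].
#' @return list with `members` (character ids), `profile` (final
#'   `profile_model`), `hits` (final score table), `trace` (data.frame
#'   round/n_members), and `converged` flag.
#' @export
iterate_search <- function(seeds, database, include_bits = 10,
                           max_rounds = 10L,
                           strand_mode = c("one_strand", "both_strands"),
                           redundancy_threshold = 0.9,
                           aligner = align_center_star) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(max_rounds >= 1L)
  db <- dloop_seqs(database)
  seed_seqs <- dloop_seqs(seeds)
  pool <- c(db, seed_seqs[setdiff(names(seed_seqs), names(db))])
  members <- names(seed_seqs)
  seen <- list()
  trace <- data.frame(round = integer(0), n_members = integer(0))
  profile <- NULL
  hits <- NULL
  converged <- FALSE
  last_nonempty <- members
  for (round in seq_len(max_rounds)) {
    cur <- pool[members]
    kept <- if (length(cur) > 1L)
      names(filter_redundancy(cur, threshold = redundancy_threshold)$kept)
    else members
    aln <- if (length(kept) >= 2L) aligner(pool[kept]) else {
      # single member: profile from a duplicated row (uninformative
      # transitions, emissions = the sequence itself)
      setNames(rep(pool[kept], 2L), c(kept, paste0(kept, "_dup")))
    }
    profile <- build_profile(aln)
    hits <- score_all(profile, db, strand_mode = strand_mode)
    new_members <- hits$seq_id[hits$bitscore >= include_bits]
    # standalone seeds stay members while they still score
    ext <- setdiff(names(seed_seqs), names(db))
    if (length(ext)) {
      ext_hits <- score_all(profile, pool[ext], strand_mode = strand_mode)
      new_members <- c(new_members,
                       ext_hits$seq_id[ext_hits$bitscore >= include_bits])
    }
    new_members <- unique(new_members)
    trace <- rbind(trace,
                   data.frame(round = round,
                              n_members = length(new_members)))
    if (!length(new_members)) {
      warning("iterate_search: empty member set after round ", round,
              "; returning last non-empty set")
      members <- last_nonempty
      break
    }
    key <- paste(sort(new_members), collapse = "\r")
    if (key %in% unlist(seen)) {
      members <- new_members
      converged <- TRUE
      break
    }
    seen[[length(seen) + 1L]] <- key
    last_nonempty <- new_members
    members <- new_members
  }
  list(members = sort(members), profile = profile, hits = hits,
       trace = trace, converged = converged)
}

#' Serialize a profile as JSON
#' @param profile a `profile_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write profile hits as TSV
#' @param hits hit data.frame from [score_all()] (optionally with a
#'   `round` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
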