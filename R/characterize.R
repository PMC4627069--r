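# Turning discovered motifs into structural claims: conserved anchor
# triplets and spacer length, reverse-complement palindromy, merging of
# opposite-strand motifs, tandem copies, and variant-density overlay.
#
# Convention used throughout: motif columns are indexed 5'->3' on the
# motif's own strand (1-based within the PPM); occurrence intervals are
# 0-based half-open on the forward sequence.

#' Trim a motif to its informative core and find anchor triplets
#'
#' The core spans the first through last column with information content
#' >= `ic_cut`. Anchors are the maximal runs of at least `anchor_run`
#' consecutive columns with IC >= `anchor_ic` nearest the two core edges,
#' reported as consensus triplets (the `anchor_run` columns of the run
#' adjacent to the respective edge). The spacer is the columns strictly
#' between the two anchor triplets.
#'
#' @param motif a `motif_model` (with its `ic` vector).
#' @param ic_cut core-trimming IC cutoff in bits (default 0.5).
#' @param anchor_ic per-column IC required inside an anchor (default 1).
#' @param anchor_run minimum anchor run length (default 3).
#' @return an `anchor_report`: `core_start`, `core_end` (1-based motif
#'   columns, inclusive), `core_width`, `anchor1`, `anchor2` (consensus
#'   triplets or NA when fewer than two anchor runs exist), `spacer_len`.
#' @export
trim_core <- function(motif, ic_cut = 0.5, anchor_ic = 1, anchor_run = 3L) {
  stopifnot(inherits(motif, "motif_model"))
  ic <- motif$ic
  pass <- which(ic >= ic_cut)
  if (!length(pass)) {
    return(structure(list(core_start = NA_integer_, core_end = NA_integer_,
                          core_width = 0L, anchor1 = NA_character_,
                          anchor2 = NA_character_,
                          spacer_len = NA_integer_),
                     class = "anchor_report"))
  }
  core_start <- min(pass)
  core_end <- max(pass)
  # maximal runs of consecutive columns with ic >= anchor_ic
  hi <- ic >= anchor_ic
  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends)[r$values &
                                                   r$lengths >= anchor_run, ,
                                                 drop = FALSE]
  anchor1 <- anchor2 <- NA_character_
  spacer_len <- NA_integer_
  if (nrow(runs) >= 2L) {
    left <- runs[1L, ]
    right <- runs[nrow(runs), ]
    a1_cols <- left$start:(left$start + anchor_run - 1L)
    a2_cols <- (right$end - anchor_run + 1L):right$end
    anchor1 <- consensus_of_ppm(motif$ppm[a1_cols, , drop = FALSE])
    anchor2 <- consensus_of_ppm(motif$ppm[a2_cols, , drop = FALSE])
    spacer_len <- max(0L, min(a2_cols) - max(a1_cols) - 1L)
  }
  structure(list(core_start = core_start, core_end = core_end,
                 core_width = core_end - core_start + 1L,
                 anchor1 = anchor1, anchor2 = anchor2,
                 spacer_len = spacer_len),
            class = "anchor_report")
}

#' @export
print.anchor_report <- function(x, ...) {
  cat("anchor_report: core", x$core_start, "-", x$core_end,
      "(width", paste0(x$core_width, ")"),
      " anchors", x$anchor1, "/", x$anchor2,
      " spacer", x$spacer_len, "nt\n")
  invisible(x)
}

# Mean per-column similarity (1 - 0.5 * L1) between two PPMs at a column
# offset d: rows A[i] vs B[i + d] over the overlap.
#' @keywords internal
ppm_offset_similarity <- function(A, B, d) {
  i_from <- max(1L, 1L - d)
  i_to <- min(nrow(A), nrow(B) - d)
  if (i_to < i_from) return(NA_real_)
  idx <- i_from:i_to
  sims <- vapply(idx, function(i)
    1 - 0.5 * sum(abs(A[i, ] - B[i + d, ])), numeric(1))
  mean(sims)
}

# Best similarity between two PPMs over offsets and (optionally)
# reverse-complement orientation.
#' @keywords internal
ppm_best_similarity <- function(A, B, max_offset = 3L,
                                orientations = c("direct", "revcomp")) {
  best <- list(similarity = -Inf, offset = 0L, orientation = "direct")
  for (orient in orientations) {
    Bo <- if (orient == "revcomp") revcomp_ppm(B) else B
    for (d in -max_offset:max_offset) {
      s <- ppm_offset_similarity(A, Bo, d)
      if (!is.na(s) && s > best$similarity)
        best <- list(similarity = s, offset = d, orientation = orient)
    }
  }
  best
}

#' Palindromy score of a motif
#'
#' Similarity between the motif and its own reverse complement: the
#' maximum over column offsets in `[-max_offset, max_offset]` of the mean
#' per-column similarity `1 - 0.5 * L1` on the overlapping columns. The
#' score is symmetric: `palindromy(M)` and `palindromy(revcomp(M))` are
#' exactly equal.
#'
#' @param motif a `motif_model`.
#' @param threshold score at which `is_palindromic` is set (default 0.7).
#' @param max_offset offset scan range (default 3).
#' @return a `palindromy_report` with `score`, `offset`, `is_palindromic`.
#' @export
palindromy <- function(motif, threshold = 0.7, max_offset = 3L) {
  stopifnot(inherits(motif, "motif_model"))
  best <- ppm_best_similarity(motif$ppm, motif$ppm, max_offset,
                              orientations = "revcomp")
  structure(list(score = best$similarity, offset = best$offset,
                 is_palindromic = best$similarity >= threshold),
            class = "palindromy_report")
}

#' Merge related motifs across strands
#'
#' For every motif pair, the best similarity over column offsets
#' (|offset| <= `max_offset`) and orientations (direct and
#' reverse-complement) is computed as in [palindromy()]; single-linkage
#' clustering at `sim_threshold` then partitions the motifs. Motifs that
#' are reverse complements of each other — such as the same conserved
#' element discovered from opposite strands — always merge.
#'
#' @param motifs list of `motif_model`s (>= 1).
#' @param sim_threshold single-linkage similarity threshold (default 0.8).
#' @param max_offset offset scan range (default 3).
#' @return a `merge_report`: `clusters` (list of integer index vectors),
#'   `n_clusters`, and `pairs` (data.frame i, j, similarity, offset,
#'   orientation).
#' @export
strand_merge <- function(motifs, sim_threshold = 0.8, max_offset = 3L) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L,
            all(vapply(motifs, inherits, logical(1), "motif_model")))
  n <- length(motifs)
  pairs <- data.frame(i = integer(0), j = integer(0),
                      similarity = numeric(0), offset = integer(0),
                      orientation = character(0))
  adj <- diag(TRUE, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      best <- ppm_best_similarity(motifs[[i]]$ppm, motifs[[j]]$ppm,
                                  max_offset)
      pairs <- rbind(pairs, data.frame(
        i = i, j = j, similarity = best$similarity,
        offset = best$offset, orientation = best$orientation))
      if (best$similarity >= sim_threshold) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  # connected components (single linkage)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    frontier <- v
    while (length(frontier)) {
      comp[frontier] <- cid
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2L, any) &
                     is.na(comp))
      frontier <- nxt
    }
  }
  clusters <- split(seq_len(n), comp)
  names(clusters) <- NULL
  structure(list(clusters = clusters, n_clusters = length(clusters),
                 pairs = pairs),
            class = "merge_report")
}

#' Tandem arrangement of motif occurrences
#'
#' For each sequence and strand, sorts occurrences by start and measures
#' the gap `next.start - prev.end` between consecutive copies.
#' Overlapping pairs (negative gap) are excluded from the distances and
#' counted separately. Distances are invariant to shifting all
#' coordinates by a constant.
#'
#' @param occurrences occurrence data.frame (seq_id, start, end, strand).
#' @return a `tandem_report`: `distances` (all inter-copy gaps, nt),
#'   `modal_distance` (smallest mode; NA when no pairs), `n_overlapping`,
#'   `per_sequence` (data.frame seq_id, strand, n_copies).
#' @export
find_tandem <- function(occurrences) {
  stopifnot(is.data.frame(occurrences))
  distances <- integer(0)
  n_overlap <- 0L
  per_seq <- list()
  if (nrow(occurrences)) {
    groups <- split(occurrences,
                    list(occurrences$seq_id, occurrences$strand),
                    drop = TRUE)
    for (g in groups) {
      g <- g[order(g$start), , drop = FALSE]
      per_seq[[length(per_seq) + 1L]] <-
        data.frame(seq_id = g$seq_id[1], strand = g$strand[1],
                   n_copies = nrow(g), stringsAsFactors = FALSE)
      if (nrow(g) < 2L) next
      d <- g$start[-1L] - g$end[-nrow(g)]
      n_overlap <- n_overlap + sum(d < 0L)
      distances <- c(distances, d[d >= 0L])
    }
  }
  modal <- if (length(distances)) {
    tab <- table(distances)
    as.integer(names(tab)[which.max(tab)])  # smallest mode on ties
  } else NA_integer_
  per_seq <- if (length(per_seq)) do.call(rbind, per_seq) else
    data.frame(seq_id = character(0), strand = character(0),
               n_copies = integer(0))
  structure(list(distances = distances, modal_distance = modal,
                 n_overlapping = n_overlap, per_sequence = per_seq),
            class = "tandem_report")
}

#' Overlay per-position variant counts onto motif columns
#'
#' Assigns each variant position falling inside an occurrence to the
#' motif column it overlaps, strand-aware: column 1 is the motif's 5' end
#' on its own strand. Positions inside several occurrences are assigned
#' to the first (smallest start), so count mass is conserved:
#' assigned + unassigned == total. On circular genomes, positions beyond
#' `genome_length` are wrapped before assignment.
#'
#' @param occurrences occurrence data.frame on one coordinate system
#'   (0-based half-open `start`/`end`, `strand`).
#' @param variants data.frame with `position` (1-based) and `count`.
#' @param genome_length length of the coordinate system.
#' @param circular wrap out-of-range positions instead of rejecting them.
#' @param anchor_report optional [trim_core()] result used to classify
#'   motif columns as anchor / spacer / flank.
#' @return a `variant_overlay`: `column_counts`, `column_density`
#'   (counts / number of occurrences), `column_class`, `assigned`,
#'   `unassigned`, `total`, and — when classified — `anchor_mean_density`
#'   and `spacer_mean_density`.
#' @export
variant_overlay <- function(occurrences, variants, genome_length,
                            circular = FALSE, anchor_report = NULL) {
  stopifnot(is.data.frame(occurrences), is.data.frame(variants),
            all(c("position", "count") %in% names(variants)))
  pos <- variants$position
  if (circular) pos <- ((pos - 1L) %% genome_length) + 1L
  bad <- which(pos < 1L | pos > genome_length)
  if (length(bad))
    stop("variant position(s) outside [1, ", genome_length, "]: rows ",
         paste(head(bad, 10L), collapse = ", "))
  occ <- occurrences[order(occurrences$start), , drop = FALSE]
  width <- if (nrow(occ)) max(occ$end - occ$start) else 0L
  col_counts <- numeric(width)
  assigned <- 0
  unassigned <- 0
  for (r in seq_len(nrow(variants))) {
    q <- pos[r] - 1L  # 0-based
    hit <- which(occ$start <= q & q < occ$end)
    if (!length(hit)) {
      unassigned <- unassigned + variants$count[r]
      next
    }
    h <- hit[1L]
    col <- if (occ$strand[h] == "+") q - occ$start[h] + 1L
      else occ$end[h] - q
    col_counts[col] <- col_counts[col] + variants$count[r]
    assigned <- assigned + variants$count[r]
  }
  n_occ <- nrow(occ)
  density <- if (n_occ) col_counts / n_occ else col_counts
  classes <- rep("flank", width)
  out <- list(column_counts = col_counts, column_density = density,
              column_class = classes, n_occurrences = n_occ,
              assigned = assigned, unassigned = unassigned,
              total = sum(variants$count))
  if (!is.null(anchor_report) && !is.na(anchor_report$anchor1)) {
    # reconstruct anchor/spacer columns from the report geometry
    a1_end <- anchor_report$core_start + 2L
    a2_start <- anchor_report$core_end - 2L
    classes[anchor_report$core_start:a1_end] <- "anchor"
    classes[a2_start:anchor_report$core_end] <- "anchor"
    sp <- (a1_end + 1L):(a2_start - 1L)
    if (length(sp) && a1_end + 1L <= a2_start - 1L)
      classes[sp] <- "spacer"
    out$column_class <- classes
    out$anchor_mean_density <- mean(density[classes == "anchor"])
    out$spacer_mean_density <- mean(density[classes == "spacer"])
  }
  structure(out, class = "variant_overlay")
}

#' Scan sequences with a motif PWM
#'
#' Reports every window whose log2-odds score (PPM vs background) reaches
#' `min_bits`, on one or both strands — the occurrence source for tandem
#' analysis, where the ZOOPS model's one-site-per-sequence reporting is
#' not appropriate.
#'
#' @param motif a `motif_model`.
#' @param records a [dloop_set()] or named character vector.
#' @param strand_mode `"one_strand"` or `"both_strands"`.
#' @param min_bits reporting threshold in bits (default 8).
#' @return occurrence data.frame (seq_id, start, end, strand, score).
#' @export
scan_motif <- function(motif, records,
                       strand_mode = c("one_strand", "both_strands"),
                       min_bits = 8) {
  strand_mode <- match.arg(strand_mode)
  seqs <- dloop_seqs(records)
  w <- motif$width
  lo <- log2(motif$ppm / matrix(rep(motif$background, each = w), w, 4))
  lo <- cbind(lo, 0)  # N column scores 0
  lo_rc <- lo[rev(seq_len(w)), c(4, 3, 2, 1, 5), drop = FALSE]
  out <- list()
  for (id in names(seqs)) {
    x <- encode_dna(seqs[[id]]) + 1L
    L <- length(x)
    if (L < w) next
    m <- L - w + 1L
    sc <- numeric(m)
    for (k in seq_len(w)) sc <- sc + lo[k, x[k:(k + m - 1L)]]
    keep <- which(sc >= min_bits)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, start = keep - 1L, end = keep - 1L + w,
        strand = "+", score = sc[keep], stringsAsFactors = FALSE)
    if (strand_mode == "both_strands") {
      sc2 <- numeric(m)
      for (k in seq_len(w)) sc2 <- sc2 + lo_rc[k, x[k:(k + m - 1L)]]
      keep2 <- which(sc2 >= min_bits)
      if (length(keep2))
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id, start = keep2 - 1L, end = keep2 - 1L + w,
          strand = "-", score = sc2[keep2], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
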