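# Synthetic D-loop-like sequence sets with planted ground truth: the
# generator emulates the statistical structure the analysis assumes
# (skewed background, zero-or-one anchor-spacer-anchor site per sequence
# on either strand, optional tandem copies, near-duplicate clusters, and
# per-position variant counts depleted at anchors), so every pipeline
# stage can be scored against a truth manifest without any download.

#' Specification of a planted anchor-spacer-anchor element
#'
#' The default is the conserved D-loop element: ATG, a 9 nt variable
#' spacer, CAT — a 15 nt core. Anchor bases are substituted independently
#' at rate `eps`. The spacer is variable but not featureless: by default
#' (`spacer_consensus = "auto"`) spacer bases are mutated at rate
#' `spacer_eps` (default 0.25) from a fixed weak consensus, giving spacer columns an
#' information content well below the anchor level — the structure real
#' sequence logos of the element show. `spacer_consensus = NULL` draws
#' the spacer iid from the background instead; an element reduced to its
#' six anchor bases is close to the chance rate of anchor pairs in 900 nt
#' of skewed background, so a fully random spacer makes site-level
#' recovery intrinsically ambiguous.
#'
#' @param anchor1,anchor2 anchor triplets (any lengths are accepted).
#' @param spacer_len spacer length in nt; a vector is sampled uniformly
#'   per site (point mass by default).
#' @param eps per-base anchor substitution rate (default 0.05).
#' @param spacer_consensus `"auto"` (default), NULL for an iid background
#'   spacer, or an explicit consensus string whose length matches
#'   `spacer_len`.
#' @param spacer_eps per-base substitution rate from the spacer consensus.
#' @return a `motif_spec` list.
#' @export
motif_spec <- function(anchor1 = "ATG", spacer_len = 9L, anchor2 = "CAT",
                       eps = 0.05, spacer_consensus = "auto",
                       spacer_eps = 0.25) {
  if (identical(spacer_consensus, "auto")) {
    # fixed ATG/CAT-free pattern, truncated to each spacer length
    base <- strrep("TACTAATTAC", ceiling(max(spacer_len) / 10))
    spacer_consensus <- substr(rep(base, length(spacer_len)), 1L,
                               spacer_len)
  }
  if (!is.null(spacer_consensus))
    stopifnot(all(nchar(spacer_consensus) == spacer_len))
  structure(list(anchor1 = toupper(anchor1), spacer_len = spacer_len,
                 anchor2 = toupper(anchor2), eps = eps,
                 spacer_consensus = spacer_consensus,
                 spacer_eps = spacer_eps),
            class = "motif_spec")
}

#' Simulation configuration for synthetic D-loop sets
#'
#' Defaults are the study conditions of the package's validation suite:
#' 900 nt sequences over a G-poor background (A 0.31, C 0.25, G 0.13,
#' T 0.31) mimicking the L-strand composition of mammalian control
#' regions, site prevalence `gamma` 0.8, forward-strand planting.
#'
#' @param n_seqs number of sequences.
#' @param seq_len sequence length in nt (default 900).
#' @param background 4-vector (A, C, G, T).
#' @param motif a [motif_spec()].
#' @param gamma probability a sequence carries a (possibly tandem) site.
#' @param prob_minus probability a planted site goes on the minus strand.
#' @param tandem NULL, or `list(n_copies =, gaps =)`: number of copies per
#'   planted site (scalar or vector sampled per sequence) and the
#'   inter-copy gap lengths to sample from.
#' @param redundancy NULL, or `list(n_clusters =, cluster_size =,
#'   identity =)`: appends near-duplicate star clusters (one unmutated
#'   parent plus children mutated at per-base rate `1 - identity`).
#'   `n_seqs` counts all sequences including cluster members.
#' @param variants NULL, or `list(density =, depletion =)`: per-position
#'   expected variant counts on the first sequence's coordinate system,
#'   with the anchor-position rate divided by `depletion`.
#' @param seed integer seed; the only source of randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_seqs = 200L, seq_len = 900L,
                       background = c(A = 0.31, C = 0.25, G = 0.13,
                                      T = 0.31),
                       motif = motif_spec(), gamma = 0.8,
                       prob_minus = 0, tandem = NULL, redundancy = NULL,
                       variants = NULL, seed = 1L) {
  background <- check_background(background)
  stopifnot(gamma >= 0, gamma <= 1, prob_minus >= 0, prob_minus <= 1,
            n_seqs >= 1L)
  max_site <- nchar(motif$anchor1) + max(motif$spacer_len) +
    nchar(motif$anchor2)
  n_copies_max <- if (is.null(tandem)) 1L else max(tandem$n_copies)
  gap_max <- if (is.null(tandem)) 0L else max(tandem$gaps)
  block_max <- n_copies_max * max_site + (n_copies_max - 1L) * gap_max
  if (block_max > seq_len)
    stop("infeasible config: planted block (", block_max,
         " nt) longer than seq_len (", seq_len, ")")
  structure(list(n_seqs = as.integer(n_seqs),
                 seq_len = as.integer(seq_len), background = background,
                 motif = motif, gamma = gamma, prob_minus = prob_minus,
                 tandem = tandem, redundancy = redundancy,
                 variants = variants, seed = as.integer(seed)),
            class = "sim_config")
}

# One realization of the element (anchors mutated at eps, spacer drawn).
#' @keywords internal
sample_site <- function(ms, background) {
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    flip <- runif(length(ch)) < rate
    if (any(flip))
      ch[flip] <- vapply(ch[flip], function(b)
        sample(setdiff(DNA_BASES4, b), 1L), character(1))
    paste(ch, collapse = "")
  }
  pick <- if (length(ms$spacer_len) > 1L)
    sample(seq_along(ms$spacer_len), 1L) else 1L
  sl <- ms$spacer_len[pick]
  spacer <- if (is.null(ms$spacer_consensus))
    paste(sample_bases(sl, background), collapse = "")
  else mutate(ms$spacer_consensus[pick], ms$spacer_eps)
  paste0(mutate(ms$anchor1, ms$eps), spacer, mutate(ms$anchor2, ms$eps))
}

#' Generate a synthetic D-loop set with a truth manifest
#'
#' Sequences are drawn iid from the background; with probability `gamma`
#' a site (or a tandem block of sites) is planted at a uniform admissible
#' offset, reverse-complemented for minus-strand placements. Optional
#' near-duplicate clusters and a per-position variant table (on the first
#' sequence's coordinates, anchor-depleted) are produced with their
#' ground truth. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `records` (a [dloop_set()]) and `manifest` (class
#'   `truth_manifest`: `sites` data.frame with 0-based half-open
#'   intervals, strand, motif/copy ids; `clusters`; `variants` with
#'   per-position class anchor/spacer/outside).
#' @export
simulate_dloops <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ms <- config$motif
  bg <- config$background
  L <- config$seq_len
  red <- config$redundancy
  n_cluster_seqs <- if (is.null(red)) 0L else
    red$n_clusters * red$cluster_size
  n_indep <- config$n_seqs - n_cluster_seqs
  if (n_indep < 0L)
    stop("redundancy clusters exceed n_seqs")

  sites <- list()
  seqs <- character(0)
  ids <- character(0)
  clusters <- data.frame(id = character(0), cluster = integer(0),
                         role = character(0), stringsAsFactors = FALSE)

  plant_one <- function(id, force_site = FALSE) {
    s <- paste(sample_bases(L, bg), collapse = "")
    rows <- NULL
    if (force_site || runif(1) < config$gamma) {
      n_copies <- if (is.null(config$tandem)) 1L else {
        nc <- config$tandem$n_copies
        if (length(nc) > 1L) sample(nc, 1L) else nc
      }
      copies <- replicate(n_copies, sample_site(ms, bg))
      gaps <- if (n_copies > 1L) {
        g <- config$tandem$gaps
        vapply(seq_len(n_copies - 1L), function(i)
          if (length(g) > 1L) sample(g, 1L) else g, numeric(1))
      } else numeric(0)
      gap_seqs <- vapply(gaps, function(g)
        paste(sample_bases(g, bg), collapse = ""), character(1))
      block <- copies[1L]
      copy_starts <- 0L
      for (k in seq_len(n_copies - 1L)) {
        block <- paste0(block, gap_seqs[k], copies[k + 1L])
        copy_starts <- c(copy_starts,
                         copy_starts[k] + nchar(copies[k]) + gaps[k])
      }
      bl <- nchar(block)
      minus <- runif(1) < config$prob_minus
      off <- sample.int(L - bl + 1L, 1L) - 1L  # 0-based
      ins <- if (minus) revcomp_dna(block) else block
      s <- paste0(substr(s, 1L, off), ins, substr(s, off + bl + 1L, L))
      rows <- do.call(rbind, lapply(seq_len(n_copies), function(k) {
        cs <- copy_starts[k]
        cl <- nchar(copies[k])
        if (!minus)
          data.frame(seq_id = id, start = off + cs, end = off + cs + cl,
                     strand = "+", motif = "m1", copy = k,
                     site_len = cl, stringsAsFactors = FALSE)
        else
          data.frame(seq_id = id, start = off + bl - cs - cl,
                     end = off + bl - cs, strand = "-", motif = "m1",
                     copy = k, site_len = cl, stringsAsFactors = FALSE)
      }))
    }
    list(seq = s, sites = rows)
  }

  for (i in seq_len(n_indep)) {
    id <- paste0("seq_", i)
    force_site <- i == 1L && !is.null(config$variants)
    g <- plant_one(id, force_site = force_site)
    seqs <- c(seqs, g$seq)
    ids <- c(ids, id)
    if (!is.null(g$sites)) sites[[length(sites) + 1L]] <- g$sites
  }

  if (!is.null(red)) {
    rate <- 1 - red$identity
    for (cl in seq_len(red$n_clusters)) {
      pid <- paste0("clu", cl, "_1")
      g <- plant_one(pid)
      seqs <- c(seqs, g$seq)
      ids <- c(ids, pid)
      if (!is.null(g$sites)) sites[[length(sites) + 1L]] <- g$sites
      clusters <- rbind(clusters,
                        data.frame(id = pid, cluster = cl, role = "parent",
                                   stringsAsFactors = FALSE))
      parent_codes <- strsplit(g$seq, "")[[1]]
      for (m in seq_len(red$cluster_size - 1L)) {
        cid <- paste0("clu", cl, "_", m + 1L)
        ch <- parent_codes
        flip <- runif(L) < rate
        if (any(flip))
          ch[flip] <- vapply(ch[flip], function(b)
            sample(setdiff(DNA_BASES4, b), 1L), character(1))
        seqs <- c(seqs, paste(ch, collapse = ""))
        ids <- c(ids, cid)
        clusters <- rbind(clusters,
                          data.frame(id = cid, cluster = cl,
                                     role = "child",
                                     stringsAsFactors = FALSE))
        if (!is.null(g$sites)) {
          inh <- g$sites
          inh$seq_id <- cid
          sites[[length(sites) + 1L]] <- inh
        }
      }
    }
  }

  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(seq_id = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               motif = character(0), copy = integer(0),
               site_len = integer(0), stringsAsFactors = FALSE)
  rownames(sites) <- NULL

  variants <- data.frame(position = integer(0), count = integer(0),
                         class = character(0), stringsAsFactors = FALSE)
  if (!is.null(config$variants)) {
    vs <- config$variants
    ref_sites <- sites[sites$seq_id == ids[1L], , drop = FALSE]
    cls <- rep("outside", L)
    a1 <- nchar(ms$anchor1)
    a2 <- nchar(ms$anchor2)
    for (r in seq_len(nrow(ref_sites))) {
      span <- (ref_sites$start[r] + 1L):ref_sites$end[r]  # 1-based
      cls[span] <- "spacer"
      if (ref_sites$strand[r] == "+") {
        cls[span[1:a1]] <- "anchor"
        cls[span[(length(span) - a2 + 1L):length(span)]] <- "anchor"
      } else {
        cls[span[1:a2]] <- "anchor"
        cls[span[(length(span) - a1 + 1L):length(span)]] <- "anchor"
      }
    }
    rate <- ifelse(cls == "anchor", vs$density / vs$depletion, vs$density)
    counts <- rpois(L, rate)
    keep <- counts > 0L
    variants <- data.frame(position = which(keep), count = counts[keep],
                           class = cls[keep], stringsAsFactors = FALSE)
  }

  manifest <- structure(list(sites = sites, clusters = clusters,
                             variants = variants, seed = config$seed),
                        class = "truth_manifest")
  list(records = dloop_set(sequence = seqs, id = ids),
       manifest = manifest)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("truth_manifest:", nrow(x$sites), "planted site(s),",
      nrow(x$clusters), "cluster member(s),",
      nrow(x$variants), "variant position(s)\n")
  invisible(x)
}

#' Write a truth manifest as JSON
#' @param manifest a `truth_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a variant table as TSV (position, count)
#' @param variants the `variants` data.frame of a manifest.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(variants[, c("position", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score predicted occurrences against planted ground truth
#'
#' A prediction matches a planted site when it is on the same sequence
#' and strand and its start is within `slack` nt of the planted start.
#'
#' @param predicted occurrence data.frame (seq_id, start, strand).
#' @param manifest a `truth_manifest` (or its `sites` data.frame).
#' @param slack start-position tolerance in nt (default 2).
#' @return list with `recall`, `precision` (0 with `no_predictions` flag
#'   when the prediction set is empty), `n_matched_sites`,
#'   `n_matched_predictions`, `n_sites`, `n_predictions`.
#' @export
score_recovery <- function(predicted, manifest, slack = 2L) {
  sites <- if (inherits(manifest, "truth_manifest")) manifest$sites else
    manifest
  n_sites <- nrow(sites)
  n_pred <- nrow(predicted)
  if (n_pred == 0L) {
    return(list(recall = 0, precision = 0, no_predictions = TRUE,
                n_matched_sites = 0L, n_matched_predictions = 0L,
                n_sites = n_sites, n_predictions = 0L))
  }
  site_hit <- logical(n_sites)
  pred_hit <- logical(n_pred)
  for (p in seq_len(n_pred)) {
    ok <- which(sites$seq_id == predicted$seq_id[p] &
                  sites$strand == predicted$strand[p] &
                  abs(sites$start - predicted$start[p]) <= slack)
    if (length(ok)) {
      pred_hit[p] <- TRUE
      site_hit[ok] <- TRUE
    }
  }
  list(recall = if (n_sites) mean(site_hit) else 1,
       precision = mean(pred_hit), no_predictions = FALSE,
       n_matched_sites = sum(site_hit),
       n_matched_predictions = sum(pred_hit),
       n_sites = n_sites, n_predictions = n_pred)
}
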