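# Ungapped motif discovery by expectation-maximization under the ZOOPS
# model (zero or one site per sequence), single- or both-strand, with
# iterative erasure for multiple motifs.

#' Estimate a 0-order background model
#'
#' Maximum-likelihood A/C/G/T frequencies over all non-N positions, floored
#' at 1e-4 and renormalized so information content is always finite.
#'
#' @param records a [dloop_set()] or named character vector.
#' @param floor minimum frequency after flooring.
#' @return named numeric 4-vector (A, C, G, T) summing to 1.
#' @export
estimate_background <- function(records, floor = 1e-4) {
  seqs <- dloop_seqs(records)
  if (!length(seqs)) stop("estimate_background: empty input")
  codes <- unlist(lapply(seqs, encode_dna), use.names = FALSE)
  codes <- codes[codes < 4L]
  if (!length(codes)) stop("estimate_background: sequences contain only N")
  f <- tabulate(codes + 1L, nbins = 4L) / length(codes)
  f <- pmax(f, floor)
  setNames(f / sum(f), DNA_BASES4)
}

#' Per-column information content of a motif
#'
#' `ic[j] = sum_b ppm[j,b] * log2(ppm[j,b] / background[b])` with the
#' convention `0 * log(0) = 0` — the per-column Kullback-Leibler divergence
#' from the background, in bits, as drawn in sequence logos.
#'
#' @param ppm width x 4 position probability matrix (columns A,C,G,T).
#' @param background 4-vector of background probabilities (all > 0).
#' @return numeric vector of per-column bits.
#' @export
information_content <- function(ppm, background) {
  if (any(background <= 0)) stop("zero background frequency")
  background <- check_background(background)
  stopifnot(is.matrix(ppm), ncol(ppm) == 4L)
  apply(ppm, 1L, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  })
}

# Build the initial PPM for one EM start from an observed substring:
# the observed base gets probability 0.7, the rest is background-shaped.
#' @keywords internal
seed_ppm <- function(sub_codes, background, focus = 0.7) {
  w <- length(sub_codes)
  ppm <- matrix(rep((1 - focus) * background, each = w), w, 4)
  for (k in seq_len(w)) {
    b <- sub_codes[k]
    if (b < 4L) ppm[k, b + 1L] <- ppm[k, b + 1L] + focus
    else ppm[k, ] <- background
  }
  ppm / rowSums(ppm)
  }

#' Discover one motif by ZOOPS expectation-maximization
#'
#' Fits a fixed-width position probability matrix, a site prior `gamma`,
#' and per-sequence site posteriors under the zero-or-one-occurrence-per-
#' sequence model. In the E-step, the posterior of a site at offset `j`
#' (and strand `s` in both-strand mode) is proportional to
#' `(gamma / m_i) * prod_k ppm[k, x(j+k)] / background[x(j+k)]`, with
#' `m_i` the number of admissible slots, against a no-site mass of
#' `1 - gamma`; the M-step re-estimates the PPM from posterior-weighted
#' site counts plus `beta * background` pseudocounts and `gamma` from the
#' mean per-sequence site probability. In both-strand mode the
#' background is complement-symmetrized (A/T and C/G averaged) so the
#' model treats the strands identically. EM runs from `n_starts` starting
#' points seeded at substrings sampled deterministically from the data and
#' the best final log-likelihood wins. N (and erased) positions contribute
#' odds ratio 1. The penalized EM objective (log-likelihood plus the
#' pseudocount log-prior) is asserted non-decreasing on every run.
#'
#' @param records a [dloop_set()] or named character vector; every
#'   sequence must be at least `width` long.
#' @param width motif width in nt (>= 4).
#' @param strand_mode `"one_strand"` or `"both_strands"`.
#' @param seed integer; the only source of randomness.
#' @param n_starts number of seeded EM starts (default 20).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   change drops below `tol` (default 1e-6) or after `max_iter` (200).
#' @param beta total pseudocount mass per PPM column (default 0.25),
#'   distributed proportionally to the background.
#' @param background optional 4-vector; estimated from the data when NULL.
#' @param post_cutoff report an occurrence for a sequence when its best
#'   slot posterior reaches this value (default 0.5).
#' @return an object of class `motif_model`: `width`, `ppm`, `background`,
#'   `gamma`, `strand_mode`, `ic` (bits per column), `loglik`,
#'   `loglik_gain` (over the background-only model), `consensus`,
#'   `occurrences` (data.frame seq_id/start/end/strand/posterior, 0-based
#'   half-open on the forward sequence), and the per-iteration `trace`.
#' @export
zoops_em <- function(records, width,
                     strand_mode = c("one_strand", "both_strands"),
                     seed = 1L, n_starts = 20L, max_iter = 200L,
                     tol = 1e-6, beta = 0.25, background = NULL,
                     post_cutoff = 0.5) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(width >= 4L)
  seqs <- dloop_seqs(records)
  lens <- nchar(seqs)
  if (any(lens < width))
    stop("sequence(s) shorter than motif width ", width, ": ",
         paste(head(names(seqs)[lens < width], 3L), collapse = ", "))
  if (is.null(background)) background <- estimate_background(seqs)
  background <- check_background(background)
  enc <- lapply(seqs, encode_dna)
  fit_zoops(enc, ids = names(seqs), width = width,
            both = strand_mode == "both_strands", seed = seed,
            n_starts = n_starts, max_iter = max_iter, tol = tol,
            beta = beta, background = background,
            post_cutoff = post_cutoff,
            strand_mode = strand_mode)
}

# Core fit on pre-encoded sequences (shared with erase_and_repeat, which
# masks positions by code 4).
#' @keywords internal
fit_zoops <- function(enc, ids, width, both, seed, n_starts, max_iter,
                      tol, beta, background, post_cutoff, strand_mode) {
  set.seed(seed)
  n <- length(enc)
  bg <- as.numeric(background)
  # both-strand scanning requires a complement-symmetric background for
  # the model to be strand-symmetric (A/T and C/G averaged, as motif
  # tools do in their reverse-complement modes)
  if (both) bg <- (bg + rev(bg)) / 2
  log_bg <- log(bg)
  pseudo <- matrix(rep(beta * bg, each = width), width, 4)
  # Deterministic substring seeding with a prescreen: sample a pool of
  # distinct (sequence, offset) substrings, score each seed PPM with a
  # single E-step, and run full EM from the n_starts best — the classic
  # remedy for EM's sensitivity to its start when sites are sparse.
  n_cand <- max(5L * n_starts, 100L)
  cand_i <- sample.int(n, n_cand, replace = TRUE)
  cand_off <- vapply(cand_i, function(i)
    sample.int(length(enc[[i]]) - width + 1L, 1L), integer(1))
  keep <- !duplicated(cbind(cand_i, cand_off))
  cand_i <- cand_i[keep]; cand_off <- cand_off[keep]
  cand_score <- vapply(seq_along(cand_i), function(s) {
    sub <- enc[[cand_i[s]]][cand_off[s]:(cand_off[s] + width - 1L)]
    zoops_estep_cpp(enc, log(seed_ppm(sub, bg)), log_bg, bg, 0.5,
                    both)$loglik
  }, numeric(1))
  top <- order(-cand_score)[seq_len(min(n_starts, length(cand_i)))]
  starts <- lapply(top, function(s)
    enc[[cand_i[s]]][cand_off[s]:(cand_off[s] + width - 1L)])
  n_starts <- length(starts)

  # shifted copy of a PPM (vacated columns refilled with background)
  shift_ppm <- function(ppm, s) {
    w <- nrow(ppm)
    out <- matrix(rep(bg, each = w), w, 4)
    src <- seq_len(w) + s
    ok <- src >= 1L & src <= w
    out[ok, ] <- ppm[src[ok], , drop = FALSE]
    out
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    ppm <- seed_ppm(starts[[s]], bg)
    gamma <- 0.5
    prev_obj <- -Inf
    prev_ll <- -Inf
    trace <- numeric(0)
    est <- NULL
    n_shifts <- 0L
    for (it in seq_len(max_iter)) {
      est <- zoops_estep_cpp(enc, log(ppm), log_bg, bg, gamma, both)
      # penalized EM objective: data loglik + pseudocount (Dirichlet) prior
      obj <- est$loglik + sum(pseudo * log(pmax(ppm, 1e-300)))
      if (obj < prev_obj - 1e-8)
        stop("internal error: EM objective decreased (",
             prev_obj, " -> ", obj, ")")
      trace <- c(trace, est$loglik)
      converged <- is.finite(prev_ll) && abs(est$loglik - prev_ll) < tol
      prev_obj <- obj
      prev_ll <- est$loglik
      # M-step
      ppm_new <- est$counts + pseudo
      ppm <- ppm_new / rowSums(ppm_new)
      gamma <- min(max(est$gamma_mean, 1e-6), 1 - 1e-6)
      if (converged) {
        # phase-shift polish: EM cannot escape a column-shifted local
        # optimum by itself; adopt a shifted PPM when it scores better
        if (n_shifts < 3L) {
          # vacated columns carry no information until re-learned, so
          # each candidate gets one E/M refinement before comparison
          refine <- function(p0) {
            e1 <- zoops_estep_cpp(enc, log(p0), log_bg, bg, gamma, both)
            p1 <- e1$counts + pseudo
            p1 <- p1 / rowSums(p1)
            list(ppm = p1,
                 ll = zoops_estep_cpp(enc, log(p1), log_bg, bg, gamma,
                                      both)$loglik)
          }
          cands <- lapply(setdiff(-3:3, 0L), function(d)
            refine(shift_ppm(ppm, d)))
          lls <- vapply(cands, `[[`, numeric(1), "ll")
          if (max(lls) > est$loglik + tol) {
            ppm <- cands[[which.max(lls)]]$ppm
            n_shifts <- n_shifts + 1L
            prev_obj <- -Inf
            prev_ll <- -Inf
            next
          }
        }
        break
      }
    }
    if (is.null(best) || est$loglik > best$loglik) {
      best <- list(ppm = ppm, gamma = gamma, loglik = est$loglik,
                   est = est, trace = trace)
    }
  }

  colnames(best$ppm) <- DNA_BASES4
  # occurrences from the final E-step
  keep <- best$est$best_post >= post_cutoff
  occ <- data.frame(
    seq_id = ids[keep],
    start = best$est$best_off[keep],
    end = best$est$best_off[keep] + width,
    strand = c("+", "-")[best$est$best_strand[keep] + 1L],
    posterior = best$est$best_post[keep],
    stringsAsFactors = FALSE)
  occ <- occ[order(match(occ$seq_id, ids), occ$start), , drop = FALSE]
  rownames(occ) <- NULL
  # background-only log-likelihood for the gain
  ll0 <- sum(vapply(enc, function(x) sum(log_bg[x[x < 4L] + 1L]),
                    numeric(1)))
  ic <- information_content(best$ppm, bg)
  structure(list(width = width, ppm = best$ppm,
                 background = setNames(bg, DNA_BASES4),
                 gamma = best$gamma, strand_mode = strand_mode,
                 ic = ic, loglik = best$loglik,
                 loglik_gain = best$loglik - ll0,
                 consensus = consensus_of_ppm(best$ppm),
                 nsites = nrow(occ), occurrences = occ,
                 trace = best$trace),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model  width", x$width, " mode", x$strand_mode, "\n")
  cat("  consensus ", x$consensus, "\n")
  cat("  gamma", round(x$gamma, 3), " sites", x$nsites,
      " total IC", round(sum(x$ic), 1), "bits  loglik",
      round(x$loglik, 1), "\n")
  invisible(x)
}

#' Reverse complement of a motif model
#' @param motif a `motif_model`.
#' @return a `motif_model` with reverse-complemented PPM (occurrences and
#'   likelihoods are carried over unchanged; strands flip meaning).
#' @export
revcomp_motif <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  motif$ppm <- revcomp_ppm(motif$ppm)
  motif$ic <- rev(motif$ic)
  motif$consensus <- consensus_of_ppm(motif$ppm)
  if (nrow(motif$occurrences))
    motif$occurrences$strand <- ifelse(motif$occurrences$strand == "+",
                                       "-", "+")
  motif
}

#' Discover several motifs by iterative erasure
#'
#' Runs [zoops_em()], masks all positions covered by occurrences with
#' posterior >= `erase_cutoff` (they become N for subsequent likelihoods),
#' and repeats on the masked set, up to `n_motifs` times. Discovery stops
#' early when the best remaining motif's total information content falls
#' below `min_total_ic` bits.
#'
#' @inheritParams zoops_em
#' @param n_motifs maximum number of motifs to report.
#' @param erase_cutoff posterior above which an occurrence is erased.
#' @param min_total_ic early-stop threshold on total motif IC (bits).
#' @return an object of class `discovery_result`: `motifs` (list of
#'   `motif_model`, in discovery order — decreasing log-likelihood gain),
#'   `occurrences` (list parallel to `motifs`), and `erased_mask` (list of
#'   logical vectors per sequence).
#' @export
erase_and_repeat <- function(records, n_motifs, width,
                             strand_mode = c("one_strand", "both_strands"),
                             seed = 1L, n_starts = 20L, max_iter = 200L,
                             tol = 1e-6, beta = 0.25, background = NULL,
                             post_cutoff = 0.5, erase_cutoff = 0.5,
                             min_total_ic = 1) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(n_motifs >= 1L)
  seqs <- dloop_seqs(records)
  if (is.null(background)) background <- estimate_background(seqs)
  background <- check_background(background)
  enc <- lapply(seqs, encode_dna)
  ids <- names(seqs)
  mask <- lapply(enc, function(x) rep(FALSE, length(x)))
  names(mask) <- ids
  motifs <- list()
  occs <- list()
  for (m in seq_len(n_motifs)) {
    if (all(vapply(enc, function(x) all(x == 4L), logical(1)))) break
    fit <- fit_zoops(enc, ids = ids, width = width,
                     both = strand_mode == "both_strands",
                     seed = seed + m - 1L, n_starts = n_starts,
                     max_iter = max_iter, tol = tol, beta = beta,
                     background = background, post_cutoff = post_cutoff,
                     strand_mode = strand_mode)
    if (sum(fit$ic) < min_total_ic) break
    motifs[[length(motifs) + 1L]] <- fit
    occs[[length(occs) + 1L]] <- fit$occurrences
    er <- fit$occurrences[fit$occurrences$posterior >= erase_cutoff, ,
                          drop = FALSE]
    for (r in seq_len(nrow(er))) {
      i <- match(er$seq_id[r], ids)
      span <- (er$start[r] + 1L):er$end[r]
      enc[[i]][span] <- 4L
      mask[[i]][span] <- TRUE
    }
  }
  structure(list(motifs = motifs, occurrences = occs, erased_mask = mask),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("discovery_result with", length(x$motifs), "motif(s)\n")
  for (m in x$motifs)
    cat("  ", m$consensus, " IC", round(sum(m$ic), 1), "bits  sites",
        m$nsites, "\n")
  invisible(x)
}
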