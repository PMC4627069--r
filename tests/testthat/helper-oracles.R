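# Independent oracles (brute-force enumeration) and fixture builders.
# These deliberately share no code with the implementation paths they
# check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, bases = BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  flip <- runif(length(ch)) < rate
  ch[flip] <- vapply(ch[flip], function(b)
    sample(setdiff(BASES, b), 1L), character(1))
  paste(ch, collapse = "")
}

# ---------------------------------------------------------------------------
# Brute-force global alignment with affine gaps (gap run of length L costs
# open + L * ext). Returns the optimal score and the set of identity values
# achieved by optimal alignments (matches / alignment length).
# ---------------------------------------------------------------------------
oracle_global_align <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 5, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  acc <- list()
  rec <- function(i, j, prev, score, matches, alen) {
    if (i > length(A) && j > length(B)) {
      acc[[length(acc) + 1L]] <<- c(score, matches, alen)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      hit <- A[i] == B[j] && A[i] != "N"
      rec(i + 1L, j + 1L, "M", score + if (hit) match else mismatch,
          matches + hit, alen + 1L)
    }
    if (i <= length(A))
      rec(i + 1L, j, "X",
          score - (if (prev == "X") gap_ext else gap_open + gap_ext),
          matches, alen + 1L)
    if (j <= length(B))
      rec(i, j + 1L, "Y",
          score - (if (prev == "Y") gap_ext else gap_open + gap_ext),
          matches, alen + 1L)
  }
  rec(1L, 1L, "S", 0, 0L, 0L)
  m <- do.call(rbind, acc)
  best <- max(m[, 1])
  sel <- m[, 1] > best - 1e-9
  list(score = best, identities = unique(m[sel, 2] / m[sel, 3]))
}

# ---------------------------------------------------------------------------
# ZOOPS E-step by exhaustive configuration enumeration (probability space,
# no logs): every (no-site | offset x strand) configuration per sequence.
# ---------------------------------------------------------------------------
oracle_zoops <- function(seqs, ppm, bg, gamma, both) {
  w <- nrow(ppm)
  code <- function(s) match(strsplit(s, "")[[1]], BASES)  # NA for N
  rc_code <- function(x) rev(5L - x)
  out_post <- numeric(length(seqs))
  counts <- matrix(0, w, 4)
  loglik <- 0
  for (si in seq_along(seqs)) {
    x <- code(seqs[[si]])
    L <- length(x)
    m1 <- L - w + 1L
    m <- if (both) 2L * m1 else m1
    p_bg_full <- prod(bg[x[!is.na(x)]])
    win_prob <- function(codes) {
      p <- 1
      for (k in seq_len(w)) {
        b <- codes[k]
        p <- p * if (is.na(b)) 1 else ppm[k, b] / bg[b]
      }
      p
    }
    slots <- list()
    weights <- numeric(0)
    for (j in seq_len(m1)) {
      slots[[length(slots) + 1L]] <- list(off = j, strand = 1L,
                                          codes = x[j:(j + w - 1L)])
    }
    if (both) for (j in seq_len(m1)) {
      slots[[length(slots) + 1L]] <- list(off = j, strand = 2L,
                                          codes = rc_code(x[j:(j + w - 1L)]))
    }
    odds <- vapply(slots, function(s) win_prob(s$codes), numeric(1))
    site_mass <- (gamma / m) * odds
    total <- (1 - gamma) + sum(site_mass)
    loglik <- loglik + log(total) + log(p_bg_full)
    z <- site_mass / total
    out_post[si] <- sum(z)
    for (k in seq_along(slots)) {
      cds <- slots[[k]]$codes
      for (col in seq_len(w)) {
        b <- cds[col]
        if (!is.na(b)) counts[col, b] <- counts[col, b] + z[k]
      }
    }
  }
  list(site_post = out_post, counts = counts, loglik = loglik)
}

# ---------------------------------------------------------------------------
# Glocal profile score by exhaustive path enumeration (log2 space), same
# state model as build_profile/score_sequence: begin -> {M1, D1}, inserts
# between internal match states only, end from the last state's first
# transition slot, free sequence flanks.
# ---------------------------------------------------------------------------
oracle_profile_score <- function(profile, seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], BASES)
  n <- length(x)
  Lp <- profile$length
  l2m <- log2(profile$match_emissions /
                matrix(rep(profile$background, each = Lp), Lp, 4))
  l2i <- log2(profile$insert_emissions / profile$background)
  lt <- function(p) ifelse(p > 0, log2(p), -Inf)
  tb <- lt(profile$begin)
  tm <- lt(profile$trans_m); ti <- lt(profile$trans_i)
  td <- lt(profile$trans_d)
  em <- function(j, i) if (is.na(x[i])) 0 else l2m[j, x[i]]
  ei <- function(i) if (is.na(x[i])) 0 else l2i[x[i]]
  best <- -Inf
  # rec: best completion after arriving in (state, j) with next unread
  # residue index i (suffix beyond the hit is free)
  rec <- function(state, j, i) {
    trow <- switch(state, M = tm[j, ], I = ti[j, ], D = td[j, ])
    if (j == Lp) {
      if (state == "I") return(-Inf)
      return(trow[1])  # -> End
    }
    out <- trow[1] + if (i <= n) em(j + 1L, i) + rec("M", j + 1L, i + 1L)
      else -Inf
    if (j >= 1L && j <= Lp - 1L && i <= n)
      out <- max(out, trow[2] + ei(i) + rec("I", j, i + 1L))
    out <- max(out, trow[3] + rec("D", j + 1L, i))
    out
  }
  for (start in seq_len(n))  # first consumed residue (free prefix)
    best <- max(best, tb[1] + em(1L, start) + rec("M", 1L, start + 1L))
  for (start in seq_len(n + 1L))  # D1 entry at any point
    best <- max(best, tb[2] + rec("D", 1L, start))
  best
}

# ---------------------------------------------------------------------------
# Fixtures
# ---------------------------------------------------------------------------

# Wrap a motif_model around a bare PPM for characterization tests.
make_motif <- function(ppm, background = rep(0.25, 4),
                       strand_mode = "one_strand") {
  colnames(ppm) <- BASES
  structure(list(width = nrow(ppm), ppm = ppm,
                 background = setNames(background, BASES),
                 gamma = NA_real_, strand_mode = strand_mode,
                 ic = information_content(ppm, background),
                 loglik = NA_real_, loglik_gain = NA_real_,
                 consensus = paste(BASES[max.col(ppm)], collapse = ""),
                 nsites = 0L, occurrences = data.frame(),
                 trace = numeric(0)),
            class = "motif_model")
}

# PPM whose consensus is `consensus`, with probability `p` on the
# consensus base and the rest spread evenly.
consensus_ppm <- function(consensus, p = 0.91) {
  ch <- strsplit(consensus, "")[[1]]
  ppm <- matrix((1 - p) / 3, length(ch), 4, dimnames = list(NULL, BASES))
  for (k in seq_along(ch)) ppm[k, ch[k]] <- p
  ppm
}

# Small two-record GenBank flat file (one circular genome with an
# origin-wrapping D-loop, one linear genome with a control-region
# misc_feature), written programmatically.
write_test_genbank <- function(path, L = 2000L, dloop_a = 1801L,
                               dloop_b = 120L, seed = 42L) {
  set.seed(seed)
  wrap60 <- function(s) {
    n <- nchar(s)
    starts <- seq(1L, n, 60L)
    vapply(seq_along(starts), function(i)
      sprintf("%9d %s", starts[i],
              tolower(substr(s, starts[i], min(n, starts[i] + 59L)))),
      character(1))
  }
  s1 <- random_dna(L)
  s2 <- random_dna(500L)
  lines <- c(
    sprintf("LOCUS       TESTCIRC            %5d bp    DNA     circular VRT 01-JAN-2000", L),
    "DEFINITION  Synthetic circular mitochondrial test genome.",
    "ACCESSION   TESTCIRC",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    "                     /organism=\"Testus circularis\"",
    "                     /organelle=\"mitochondrion\"",
    sprintf("     D-loop          join(%d..%d,1..%d)", dloop_a, L, dloop_b),
    "ORIGIN",
    wrap60(s1),
    "//",
    "LOCUS       TESTLIN               500 bp    DNA     linear VRT 01-JAN-2000",
    "ACCESSION   TESTLIN",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "                     /organism=\"Testus linearis\"",
    "     misc_feature    101..160",
    "                     /note=\"control region\"",
    "ORIGIN",
    wrap60(s2),
    "//")
  writeLines(lines, path)
  list(seq_circ = s1, seq_lin = s2)
}
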