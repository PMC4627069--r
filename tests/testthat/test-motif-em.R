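# ZOOPS expectation-maximization: background model, information content,
# E-step correctness against exhaustive enumeration, recovery of planted
# sites, erasure, and strand symmetry.

test_that("background estimation matches direct counting", {
  expect_equal(unname(estimate_background(c(x = "ACGTACGT"))),
               rep(0.25, 4))
  bg <- estimate_background(c(x = "AAAA"))
  expect_equal(sum(bg), 1)
  expect_gt(bg[["A"]], 0.99)
  expect_true(all(bg > 0))
  set.seed(201)
  s <- random_dna(4000, prob = c(0.4, 0.3, 0.2, 0.1))
  bg2 <- estimate_background(c(x = s))
  counts <- table(factor(strsplit(s, "")[[1]], levels = BASES))
  expect_equal(unname(bg2), as.numeric(counts / sum(counts)),
               tolerance = 1e-3)
  expect_error(estimate_background(c(x = "NNNN")), "only N")
})

test_that("information content matches closed-form cases", {
  unif <- rep(0.25, 4)
  expect_equal(information_content(matrix(0.25, 1, 4), unif), 0)
  expect_equal(information_content(matrix(c(1, 0, 0, 0), 1), unif), 2)
  expect_equal(information_content(matrix(c(0.5, 0.5, 0, 0), 1), unif), 1)
  expect_error(information_content(matrix(0.25, 1, 4), c(0, 0.5, 0.25, 0.25)),
               "zero background")
})

test_that("E-step equals exhaustive configuration enumeration", {
  set.seed(202)
  for (both in c(FALSE, TRUE)) {
    for (r in 1:6) {
      seqs <- replicate(3, random_dna(sample(5:8, 1)))
      if (r == 6) substr(seqs[1], 2, 2) <- "N"  # ambiguity handling
      ppm <- matrix(runif(12), 3, 4)
      ppm <- ppm / rowSums(ppm)
      bg <- c(0.3, 0.25, 0.2, 0.25)
      gamma <- runif(1, 0.2, 0.9)
      enc <- lapply(seqs, dloopmotif:::encode_dna)
      got <- dloopmotif:::zoops_estep_cpp(enc, log(ppm), log(bg), bg,
                                          gamma, both)
      want <- oracle_zoops(seqs, ppm, bg, gamma, both)
      expect_equal(got$site_post, want$site_post, tolerance = 1e-10)
      expect_equal(got$counts, want$counts, tolerance = 1e-10)
      expect_equal(got$loglik, want$loglik, tolerance = 1e-8)
    }
  }
})

test_that("planted sites are recovered with high recall and precision", {
  sim <- simulate_dloops(sim_config(n_seqs = 100, seq_len = 400,
                                    gamma = 0.8, seed = 31))
  m <- zoops_em(sim$records, width = 18, seed = 1, n_starts = 10)
  # the 18 nt window may start up to 3 nt left of the 15 nt element
  sc <- score_recovery(m$occurrences, sim$manifest, slack = 3)
  expect_gte(sc$recall, 0.85)
  expect_gte(sc$precision, 0.85)
  rep <- trim_core(m)
  expect_equal(rep$core_width, 15L)
  expect_equal(rep$anchor1, "ATG")
  expect_equal(rep$anchor2, "CAT")
  expect_equal(rep$spacer_len, 9L)
  # EM diagnostics: finite non-decreasing-to-final trace, normalized PPM
  expect_true(all(is.finite(m$trace)))
  expect_gte(m$trace[length(m$trace)], m$trace[1])
  expect_equal(rowSums(m$ppm), rep(1, 18), tolerance = 1e-9)
  expect_gt(m$loglik_gain, 0)
})

test_that("degenerate data drives the site prior to one", {
  # every sequence carries the identical site at offset 0; flanks are
  # background-flat (iid uniform, different per sequence)
  site <- "ACGTACGTAC"
  set.seed(203)
  seqs <- setNames(vapply(1:12, function(i)
    paste0(site, random_dna(20)), character(1)), paste0("s", 1:12))
  m <- zoops_em(seqs, width = 10, seed = 1, n_starts = 4,
                background = rep(0.25, 4))
  expect_gte(m$gamma, 0.99)
  expect_true(all(m$occurrences$start == 0L))
  expect_true(all(m$occurrences$posterior > 0.99))
})

test_that("width larger than the shortest sequence is an error", {
  expect_error(zoops_em(c(a = "ACGTACGT", b = "ACG"), width = 6), "shorter")
})

test_that("the both-strand model is symmetric under reverse complement", {
  # exact model symmetry: any (PPM, gamma) evaluated on a data set and
  # its reverse-complemented PPM evaluated on the mirrored data give the
  # same likelihood and site posteriors
  sim <- simulate_dloops(sim_config(n_seqs = 40, seq_len = 200,
                                    gamma = 0.8, prob_minus = 0.5,
                                    seed = 32))
  seqs <- setNames(sim$records$sequence, sim$records$id)
  enc_f <- lapply(seqs, dloopmotif:::encode_dna)
  enc_r <- lapply(seqs, function(s) dloopmotif:::encode_dna(revcomp_dna(s)))
  # strand symmetry requires a complement-symmetric background, which is
  # what both-strand discovery uses internally
  bg <- estimate_background(seqs)
  bg <- unname((bg + rev(bg)) / 2)
  set.seed(33)
  ppm <- matrix(runif(18 * 4, 0.05, 1), 18, 4)
  ppm <- ppm / rowSums(ppm)
  a <- dloopmotif:::zoops_estep_cpp(enc_f, log(ppm), log(bg), bg,
                                    0.7, TRUE)
  b <- dloopmotif:::zoops_estep_cpp(enc_r, log(revcomp_ppm(ppm)),
                                    log(bg), bg, 0.7, TRUE)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-9)
  expect_equal(a$site_post, b$site_post, tolerance = 1e-9)
})

test_that("discovery on mirrored data returns the mirrored motif", {
  sim <- simulate_dloops(sim_config(n_seqs = 80, seq_len = 300,
                                    gamma = 0.8, prob_minus = 0.5,
                                    seed = 21))
  seqs <- setNames(sim$records$sequence, sim$records$id)
  rc <- vapply(seqs, revcomp_dna, character(1))
  m1 <- zoops_em(seqs, width = 18, strand_mode = "both_strands",
                 seed = 4, n_starts = 10)
  m2 <- zoops_em(rc, width = 18, strand_mode = "both_strands",
                 seed = 4, n_starts = 10)
  # both runs reach the same optimum up to reverse complement; the
  # log-likelihoods then agree to summation-order noise
  expect_lt(abs(m1$loglik - m2$loglik), 1e-3)
  # in both-strand mode a motif and its reverse complement are the same
  # model, so the mirrored run may come back in either orientation
  best <- dloopmotif:::ppm_best_similarity(m1$ppm, m2$ppm)
  expect_gt(best$similarity, 0.95)
})

test_that("site prior shrinks on background-only data as n grows", {
  gamma_at <- function(n, seeds) {
    vapply(seeds, function(sd) {
      set.seed(sd)
      seqs <- setNames(replicate(n, random_dna(150)), paste0("s", 1:n))
      zoops_em(seqs, width = 8, seed = sd, n_starts = 4, max_iter = 60,
               background = rep(0.25, 4))$gamma
    }, numeric(1))
  }
  g_small <- gamma_at(30, 1:3)
  g_large <- gamma_at(120, 1:3)
  expect_lt(mean(g_large), mean(g_small))
})

test_that("erasure finds two distinct planted motifs, then masks them", {
  simA <- simulate_dloops(sim_config(n_seqs = 60, seq_len = 300,
                                     gamma = 0.9, seed = 33))
  simB <- simulate_dloops(sim_config(
    n_seqs = 60, seq_len = 300, gamma = 0.9, seed = 34,
    motif = motif_spec("GAC", 7L, "CTG")))
  simB$records$id <- paste0("b_", simB$records$id)
  simB$manifest$sites$seq_id <- paste0("b_", simB$manifest$sites$seq_id)
  recs <- rbind(simA$records, simB$records)
  class(recs) <- c("dloop_set", "data.frame")
  disc <- erase_and_repeat(recs, n_motifs = 2, width = 18, seed = 3,
                           n_starts = 10)
  expect_length(disc$motifs, 2L)
  # each planted family is recovered by one of the two motifs
  pairs <- expand.grid(motif = 1:2, manifest = 1:2)
  rec_mat <- matrix(0, 2, 2)
  for (k in seq_len(nrow(pairs))) {
    man <- list(simA$manifest, simB$manifest)[[pairs$manifest[k]]]
    rec_mat[pairs$motif[k], pairs$manifest[k]] <-
      score_recovery(disc$motifs[[pairs$motif[k]]]$occurrences, man,
                     slack = 3)$recall
  }
  expect_gt(max(rec_mat[, 1]), 0.8)
  expect_gt(max(rec_mat[, 2]), 0.8)
  expect_true(which.max(rec_mat[, 1]) != which.max(rec_mat[, 2]))
  # erased positions are recorded
  expect_gt(sum(unlist(disc$erased_mask)), 0)
})

test_that("n_motifs = 1 reproduces a single zoops_em run", {
  sim <- simulate_dloops(sim_config(n_seqs = 30, seq_len = 200,
                                    gamma = 0.8, seed = 35))
  one <- zoops_em(sim$records, width = 12, seed = 4, n_starts = 5)
  d <- erase_and_repeat(sim$records, n_motifs = 1, width = 12, seed = 4,
                        n_starts = 5)
  expect_length(d$motifs, 1L)
  expect_equal(d$motifs[[1]]$ppm, one$ppm)
  expect_equal(d$motifs[[1]]$loglik, one$loglik)
})

test_that("fully masked data stops discovery immediately", {
  seqs <- setNames(rep(strrep("N", 60), 4), paste0("s", 1:4))
  d <- erase_and_repeat(seqs, n_motifs = 3, width = 10,
                        background = rep(0.25, 4))
  expect_length(d$motifs, 0L)
})

test_that("motif files round-trip through the exchange format", {
  sim <- simulate_dloops(sim_config(n_seqs = 25, seq_len = 150,
                                    gamma = 0.9, seed = 36))
  m <- zoops_em(sim$records, width = 15, seed = 5, n_starts = 5)
  f <- withr::local_tempfile(fileext = ".meme")
  write_motifs(m, f, names = "coreTAS_like")
  txt <- readLines(f)
  expect_true(any(grepl("^MEME version", txt)))
  expect_true(any(grepl("^Background letter frequencies", txt)))
  expect_true(any(grepl("w= 15", txt)))
  back <- read_motifs(f)
  expect_named(back, "coreTAS_like")
  # the format carries 6 decimals, so agreement is absolute
  expect_lt(max(abs(back[[1]]$ppm - m$ppm)), 1e-6)
  expect_lt(max(abs(back[[1]]$background - m$background)), 1e-6)
  # occurrences round-trip through BED6
  b <- withr::local_tempfile(fileext = ".bed")
  write_occurrences_bed(m$occurrences, b)
  occ <- read_occurrences_bed(b)
  expect_equal(occ$seq_id, m$occurrences$seq_id)
  expect_equal(occ$start, m$occurrences$start)
  expect_equal(occ$strand, m$occurrences$strand)
  expect_equal(occ$posterior, round(1000 * m$occurrences$posterior) / 1000)
})
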