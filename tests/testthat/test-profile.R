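# Profile construction, glocal Viterbi scoring against a path-enumeration
# oracle, and the iterative profile search.

test_that("profiles from clean alignments have the expected shape", {
  aln <- setNames(rep("ACGTACGTAC", 4), paste0("s", 1:4))
  p <- build_profile(aln, background = rep(0.25, 4))
  expect_equal(p$length, 10L)
  expect_s3_class(p, "profile_model")
  # M->M dominates every internal transition (4 observations + add-one
  # smoothing over three successors: 5/7)
  expect_true(all(p$trans_m[1:9, 1] > 0.7))
  expect_true(all(p$trans_m[1:9, 1] > p$trans_m[1:9, 2]))
  expect_true(all(p$trans_m[1:9, 1] > p$trans_m[1:9, 3]))
  expect_gt(p$match_emissions[1, "A"], 0.9)
  # rows normalized
  expect_equal(rowSums(p$match_emissions), rep(1, 10), tolerance = 1e-9)
  expect_equal(rowSums(p$trans_m), rep(1, 10), tolerance = 1e-9)
  expect_equal(rowSums(p$trans_i), rep(1, 10), tolerance = 1e-9)
  expect_equal(rowSums(p$trans_d), rep(1, 10), tolerance = 1e-9)
  expect_equal(sum(p$begin), 1, tolerance = 1e-9)
})

test_that("low-occupancy columns become inserts, not match states", {
  aln <- c(a = "AC-GT", b = "A--GT", c = "A--GT", d = "A--GT")
  p <- build_profile(aln, background = rep(0.25, 4))
  # column 2 has 25% occupancy and column 3 is empty: match states are
  # the A, G and T columns only
  expect_equal(p$length, 3L)
})

test_that("match emissions equal the count-based oracle", {
  aln <- c(a = "ACGT", b = "ACGA", c = "ACTT", d = "GCGT")
  p <- build_profile(aln, background = rep(0.25, 4), beta = 0.25)
  counts1 <- c(A = 3, C = 0, G = 1, T = 0) + 0.25 * 0.25
  expect_equal(unname(p$match_emissions[1, ]),
               unname(counts1 / sum(counts1)), tolerance = 1e-12)
  counts4 <- c(A = 1, C = 0, G = 0, T = 3) + 0.25 * 0.25
  expect_equal(unname(p$match_emissions[4, ]),
               unname(counts4 / sum(counts4)), tolerance = 1e-12)
  expect_error(build_profile(c(a = "ACGT", b = "ACG")), "widths")
})

test_that("a profile scores its own source sequence above random ones", {
  set.seed(301)
  s <- random_dna(40)
  p <- build_profile(setNames(c(s, s), c("x", "x2")),
                     background = rep(0.25, 4))
  self <- score_sequence(p, s)$bitscore
  others <- vapply(1:30, function(i)
    score_sequence(p, random_dna(40))$bitscore, numeric(1))
  expect_true(all(self > others))
})

test_that("Viterbi equals exhaustive path enumeration on small cases", {
  set.seed(302)
  n_checked <- 0L
  for (r in 1:40) {
    nseq <- sample(2:4, 1)
    ncol_aln <- sample(2:4, 1)
    rows <- vapply(seq_len(nseq), function(i) {
      ch <- sample(c(BASES, "-"), ncol_aln, replace = TRUE,
                   prob = c(rep(0.22, 4), 0.12))
      paste(ch, collapse = "")
    }, character(1))
    names(rows) <- paste0("r", seq_len(nseq))
    p <- tryCatch(build_profile(rows, background = rep(0.25, 4)),
                  error = function(e) NULL)
    if (is.null(p) || p$length > 4L) next
    target <- random_dna(sample(1:6, 1))
    got <- score_sequence(p, target)$bitscore
    want <- oracle_profile_score(p, target)
    expect_equal(got, want, tolerance = 1e-9,
                 info = paste(paste(rows, collapse = "/"), target))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 20L)
})

test_that("both-strand scoring is symmetric under reverse complement", {
  set.seed(303)
  s <- random_dna(30)
  aln <- setNames(c(s, mutate_dna(s, 0.1)), c("a", "b"))
  p <- build_profile(aln, background = rep(0.25, 4))
  target <- paste0(random_dna(10), s, random_dna(10))
  fwd <- score_sequence(p, target, strand_mode = "both_strands")
  rev <- score_sequence(p, revcomp_dna(target),
                        strand_mode = "both_strands")
  expect_equal(fwd$bitscore, rev$bitscore, tolerance = 1e-9)
  expect_true(fwd$strand != rev$strand)
  # intervals mirror each other
  L <- nchar(target)
  expect_equal(rev$start, L - fwd$end)
  expect_equal(rev$end, L - fwd$start)
})

test_that("center-star alignment reproduces simple indel structure", {
  seqs <- c(center = "ACGTACGT", ins = "ACGGTACGT", del = "ACGACGT")
  aln <- align_center_star(seqs)
  expect_length(unique(nchar(aln)), 1L)
  expect_equal(gsub("-", "", aln[["center"]]), "ACGTACGT")
  expect_equal(gsub("-", "", aln[["ins"]]), "ACGGTACGT")
  expect_equal(gsub("-", "", aln[["del"]]), "ACGACGT")
})

test_that("iterative search recovers a planted family and converges", {
  set.seed(304)
  parent <- random_dna(80)
  fam <- setNames(vapply(1:30, function(i) mutate_dna(parent, 0.1),
                         character(1)), paste0("fam_", 1:30))
  unrel <- setNames(vapply(1:70, function(i) random_dna(80),
                           character(1)), paste0("unr_", 1:70))
  db <- c(fam, unrel)
  res <- iterate_search(fam[1], db, include_bits = 10)
  expect_true(res$converged)
  expect_gte(sum(grepl("^fam_", res$members)) / 30, 0.9)
  expect_equal(sum(grepl("^unr_", res$members)), 0L)
  # true fixed point: one more round from the converged set reproduces it
  again <- iterate_search(db[res$members], db, include_bits = 10,
                          max_rounds = 1)
  expect_setequal(again$members, res$members)
  # membership is monotone in -include_bits
  loose <- iterate_search(fam[1], db, include_bits = 5)
  strict <- iterate_search(fam[1], db, include_bits = 20)
  expect_true(all(strict$members %in% res$members))
  expect_true(all(res$members %in% loose$members))
})

test_that("a seed without homologs is its own fixed point", {
  set.seed(305)
  db <- setNames(vapply(1:20, function(i) random_dna(60), character(1)),
                 paste0("d", 1:20))
  seed <- c(lonely = random_dna(60))
  res <- iterate_search(seed, db, include_bits = 10, max_rounds = 5)
  expect_equal(res$members, "lonely")
  expect_true(res$converged)
})

test_that("max_rounds = 1 performs exactly one scoring pass", {
  set.seed(306)
  db <- setNames(vapply(1:10, function(i) random_dna(50), character(1)),
                 paste0("d", 1:10))
  res <- iterate_search(db[1], db, include_bits = 10, max_rounds = 1)
  expect_equal(nrow(res$trace), 1L)
})

test_that("profiles and hits serialize to JSON / TSV", {
  aln <- c(a = "ACGTAC", b = "ACGTAC", c = "ACTTAC")
  p <- build_profile(aln, background = rep(0.25, 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(p, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$length, 6L)
  expect_equal(back$source_alignment_ids, c("a", "b", "c"))
  hits <- score_all(p, c(x = "ACGTAC", y = "TTTTTT"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, tf)
  rt <- read.table(tf, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  expect_equal(rt$seq_id, c("x", "y"))
  expect_gt(rt$bitscore[1], rt$bitscore[2])
})
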