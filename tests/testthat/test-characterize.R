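# Anchor/spacer extraction, palindromy, strand merging, tandem copies and
# the variant-density overlay.

# PPM shaped like the conserved element: strong anchor triplets around a
# weaker spacer, padded by background flanks inside a wider window.
element_ppm <- function(spacer_len = 9, anchor_p = 0.95, spacer_p = 0.4,
                        flank = c(2, 1)) {
  bg_row <- matrix(0.25, 1, 4, dimnames = list(NULL, BASES))
  rows <- do.call(rbind, c(
    replicate(flank[1], bg_row, simplify = FALSE),
    list(consensus_ppm("ATG", anchor_p)),
    replicate(spacer_len, {
      r <- matrix((1 - spacer_p) / 3, 1, 4, dimnames = list(NULL, BASES))
      r[1, sample(BASES, 1)] <- spacer_p
      r
    }, simplify = FALSE),
    list(consensus_ppm("CAT", anchor_p)),
    replicate(flank[2], bg_row, simplify = FALSE)))
  rows
}

test_that("anchor triplets and spacer are read off the IC profile", {
  set.seed(401)
  m <- make_motif(element_ppm(9))
  rep <- trim_core(m)
  expect_equal(rep$core_width, 15L)
  expect_equal(rep$anchor1, "ATG")
  expect_equal(rep$anchor2, "CAT")
  expect_equal(rep$spacer_len, 9L)
  # 10 nt spacer variant
  m10 <- make_motif(element_ppm(10))
  expect_equal(trim_core(m10)$spacer_len, 10L)
  expect_equal(trim_core(m10)$core_width, 16L)
})

test_that("uninformative motifs yield empty anchor reports", {
  m <- make_motif(matrix(0.25, 12, 4))
  rep <- trim_core(m)
  expect_equal(rep$core_width, 0L)
  expect_true(is.na(rep$anchor1))
})

test_that("core width is the full motif at zero cutoff and shrinks with it", {
  set.seed(402)
  m <- make_motif(element_ppm(9))
  expect_equal(trim_core(m, ic_cut = 0)$core_width, m$width)
  cuts <- c(0, 0.25, 0.5, 1, 1.5)
  widths <- vapply(cuts, function(ct) trim_core(m, ic_cut = ct)$core_width,
                   integer(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("palindromy scores are exact for symmetric constructions", {
  # a PPM equal to its own reverse complement scores 1
  half <- consensus_ppm("ATGCC", 0.9)
  pal <- rbind(half, revcomp_ppm(half))
  expect_equal(palindromy(make_motif(pal))$score, 1.0)
  expect_true(palindromy(make_motif(pal))$is_palindromic)
  # homopolymer A vs its revcomp (homopolymer T) is dissimilar
  hA <- make_motif(consensus_ppm(strrep("A", 10), 0.95))
  expect_lt(palindromy(hA)$score, 0.4)
  expect_false(palindromy(hA)$is_palindromic)
})

test_that("palindromy is symmetric under reverse complement", {
  set.seed(403)
  for (r in 1:10) {
    ppm <- matrix(runif(4 * 12), 12, 4)
    ppm <- ppm / rowSums(ppm)
    m <- make_motif(ppm)
    expect_equal(palindromy(m)$score, palindromy(revcomp_motif(m))$score,
                 tolerance = 1e-12)
  }
})

test_that("opposite-strand versions of one element merge into one cluster", {
  set.seed(404)
  A <- element_ppm(9)
  m1 <- make_motif(A)
  m2 <- revcomp_motif(make_motif(A))
  mg <- strand_merge(list(m1, m2))
  expect_equal(mg$n_clusters, 1L)
  expect_equal(mg$pairs$orientation, "revcomp")
  # the partition is invariant to reverse-complementing any input
  mg2 <- strand_merge(list(revcomp_motif(m1), m2))
  expect_equal(mg2$n_clusters, 1L)
})

test_that("unrelated high-information motifs stay separate", {
  set.seed(405)
  n_sep <- 0L
  for (r in 1:20) {
    c1 <- paste(sample(BASES, 15, TRUE), collapse = "")
    c2 <- paste(sample(BASES, 15, TRUE), collapse = "")
    mg <- strand_merge(list(make_motif(consensus_ppm(c1, 0.9)),
                            make_motif(consensus_ppm(c2, 0.9))))
    n_sep <- n_sep + (mg$n_clusters == 2L)
  }
  expect_gte(n_sep, 19L)
})

test_that("tandem distances follow the non-overlap rule", {
  occ <- data.frame(
    seq_id = c("s1", "s1", "s2", "s3", "s3", "s3", "s4", "s4"),
    start = c(100L, 117L, 50L, 10L, 27L, 44L, 5L, 15L),
    end = c(115L, 132L, 65L, 25L, 42L, 59L, 20L, 18L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  rep <- find_tandem(occ)
  # s1 contributes 117-115 = 2; s3 contributes 2 and 2; s4 overlaps
  expect_equal(sort(rep$distances), c(2L, 2L, 2L))
  expect_equal(rep$modal_distance, 2L)
  expect_equal(rep$n_overlapping, 1L)
  # single occurrences contribute nothing
  expect_equal(find_tandem(occ[3, ])$modal_distance, NA_integer_)
  # shifting all coordinates leaves distances unchanged
  shifted <- occ
  shifted$start <- shifted$start + 1000L
  shifted$end <- shifted$end + 1000L
  expect_equal(find_tandem(shifted)$distances, rep$distances)
  # opposite strands are never paired
  mixed <- occ[1:2, ]
  mixed$strand <- c("+", "-")
  expect_length(find_tandem(mixed)$distances, 0L)
})

test_that("generated tandem copies show the configured 2-3 nt gaps", {
  sim <- simulate_dloops(sim_config(
    n_seqs = 40, seq_len = 400, gamma = 1, seed = 41,
    tandem = list(n_copies = 2L, gaps = 2:3)))
  rep <- find_tandem(sim$manifest$sites)
  expect_true(all(rep$distances %in% 2:3))
  expect_true(rep$modal_distance %in% 2:3)
})

test_that("variant counts map onto strand-aware motif columns", {
  occ <- data.frame(seq_id = "ref",
                    start = c(100L, 200L), end = c(115L, 215L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  variants <- data.frame(position = c(101L, 115L, 201L, 215L, 500L),
                         count = c(2L, 1L, 3L, 4L, 7L))
  ov <- variant_overlay(occ, variants, genome_length = 1000L)
  # plus strand: position 101 (0-based 100) is column 1
  expect_equal(ov$column_counts[1], 2 + 4)  # col 1: pos 101 (+), pos 215 (-)
  expect_equal(ov$column_counts[15], 1 + 3) # col 15: pos 115 (+), pos 201 (-)
  expect_equal(ov$unassigned, 7)
  expect_equal(ov$assigned + ov$unassigned, sum(variants$count))
  # wrapped coordinates on circular genomes
  ov2 <- variant_overlay(occ, data.frame(position = 1101L, count = 5L),
                         genome_length = 1000L, circular = TRUE)
  expect_equal(ov2$column_counts[1], 5)
  expect_error(variant_overlay(occ, data.frame(position = 1101L, count = 1L),
                               genome_length = 1000L), "outside")
})

test_that("anchor-depleted variants show lower anchor-column density", {
  sim <- simulate_dloops(sim_config(
    n_seqs = 10, seq_len = 900, gamma = 1, seed = 42,
    variants = list(density = 0.5, depletion = 10)))
  man <- sim$manifest
  expect_gt(nrow(man$variants), 0)
  ref_sites <- man$sites[man$sites$seq_id == "seq_1", ]
  expect_equal(nrow(ref_sites), 1L)
  # overlay computed from the occurrence list and the raw variant table
  ov <- variant_overlay(ref_sites, man$variants, genome_length = 900L,
                        anchor_report = structure(
                          list(core_start = 1L, core_end = 15L,
                               core_width = 15L, anchor1 = "ATG",
                               anchor2 = "CAT", spacer_len = 9L),
                          class = "anchor_report"))
  expect_equal(ov$assigned + ov$unassigned, sum(man$variants$count))
  expect_lt(ov$anchor_mean_density, ov$spacer_mean_density)
})
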