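# End-to-end orchestration: extract -> filter -> discover (one strand)
# -> discover (both strands) -> characterize, with intermediate files and
# one JSON summary. A thin command-line wrapper around these functions
# ships in inst/cli/dloopmotif.R.

# Deterministic per-stage sub-seed from one global seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full D-loop motif pipeline
#'
#' Filters the input for redundancy, discovers motifs on one strand and on
#' both strands, and characterizes the results (core trimming, anchors and
#' spacer, palindromy, strand merging, tandem copies). All intermediate
#' files (filtered FASTA, dropped-pairs TSV, motif-exchange files, BED6
#' occurrences, JSON reports) are written under `out_dir`, plus a single
#' `summary.json`.
#'
#' @param input a [dloop_set()], a FASTA path, or a GenBank flat file
#'   (detected by content) from which D-loops are extracted.
#' @param out_dir output directory (created if needed).
#' @param width motif window width in nt (default 18).
#' @param n_motifs motifs to report in one-strand discovery (default 2).
#' @param threshold redundancy identity threshold (default 0.90).
#' @param seed global seed; each stochastic stage derives its own
#'   sub-seed from it deterministically.
#' @param n_starts EM starts per motif (default 20).
#' @param tandem_min_bits PWM-scan threshold for the tandem analysis.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(input, out_dir, width = 18L, n_motifs = 2L,
                         threshold = 0.90, seed = 1L, n_starts = 20L,
                         tandem_min_bits = 8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- load_input(input)
  if (!nrow(records)) stop("pipeline: no input sequences")

  flt <- filter_redundancy(records, threshold = threshold)
  write_dloop_fasta(flt$kept, file.path(out_dir, "filtered.fasta"))
  write_dropped_tsv(flt$dropped, file.path(out_dir, "dropped.tsv"))

  disc1 <- erase_and_repeat(flt$kept, n_motifs = n_motifs, width = width,
                            strand_mode = "one_strand",
                            seed = stage_seed(seed, "discover_one"),
                            n_starts = n_starts)
  if (length(disc1$motifs)) {
    write_motifs(disc1, file.path(out_dir, "motifs_one_strand.meme"))
    for (k in seq_along(disc1$motifs))
      write_occurrences_bed(disc1$motifs[[k]]$occurrences,
                            file.path(out_dir,
                                      sprintf("occ_one_strand_m%d.bed", k)),
                            name = paste0("motif_", k))
    write_discovery_json(disc1, file.path(out_dir,
                                          "discovery_one_strand.json"))
  }

  disc2 <- zoops_em(flt$kept, width = width,
                    strand_mode = "both_strands",
                    seed = stage_seed(seed, "discover_both"),
                    n_starts = n_starts)
  write_motifs(disc2, file.path(out_dir, "motifs_both_strands.meme"))
  write_occurrences_bed(disc2$occurrences,
                        file.path(out_dir, "occ_both_strands.bed"))

  motif_summaries <- lapply(disc1$motifs, function(m) {
    ar <- trim_core(m)
    pr <- palindromy(m)
    list(consensus = m$consensus, total_ic_bits = sum(m$ic),
         nsites = m$nsites, gamma = m$gamma,
         core_width = ar$core_width, anchor1 = ar$anchor1,
         anchor2 = ar$anchor2, spacer_len = ar$spacer_len,
         palindromy_score = pr$score, is_palindromic = pr$is_palindromic)
  })
  merge_rep <- strand_merge(c(disc1$motifs, list(disc2)))
  tandem_rep <- if (length(disc1$motifs)) {
    occ <- scan_motif(disc1$motifs[[1L]], flt$kept,
                      strand_mode = "both_strands",
                      min_bits = tandem_min_bits)
    find_tandem(occ)
  } else find_tandem(data.frame())

  summary <- list(
    n_input = nrow(records), n_kept = nrow(flt$kept),
    n_dropped = nrow(flt$dropped),
    one_strand_motifs = motif_summaries,
    both_strands = list(consensus = disc2$consensus,
                        total_ic_bits = sum(disc2$ic),
                        nsites = disc2$nsites,
                        palindromy_score = palindromy(disc2)$score),
    merge = list(n_clusters = merge_rep$n_clusters,
                 clusters = merge_rep$clusters),
    tandem = list(modal_distance = tandem_rep$modal_distance,
                  n_distances = length(tandem_rep$distances),
                  n_overlapping = tandem_rep$n_overlapping))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# Accept a dloop_set, FASTA path or GenBank path.
#' @keywords internal
load_input <- function(input) {
  if (inherits(input, "dloop_set")) return(input)
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    first <- readLines(input, n = 1L, warn = FALSE)
    if (startsWith(first, "LOCUS")) return(extract_dloops(input))
    return(read_dloop_fasta(input))
  }
  if (is.character(input)) return(dloop_set(input))
  stop("unsupported pipeline input")
}
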