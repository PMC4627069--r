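# Text interchange: minimal motif-exchange format, BED6 occurrences,
# logo-ready letter heights, JSON discovery report.

#' Write motifs in minimal motif-exchange text format
#'
#' Standard minimal format: version header, alphabet, strands line,
#' background letter frequencies, then one letter-probability matrix per
#' motif with its `nsites`.
#'
#' @param x a `discovery_result`, a `motif_model`, or a list of
#'   `motif_model`s.
#' @param path output path.
#' @param names optional motif names (default `motif_1`, `motif_2`, ...).
#' @return `path`, invisibly.
#' @export
write_motifs <- function(x, path, names = NULL) {
  motifs <- if (inherits(x, "discovery_result")) x$motifs
    else if (inherits(x, "motif_model")) list(x) else x
  stopifnot(length(motifs) >= 1L,
            all(vapply(motifs, inherits, logical(1), "motif_model")))
  if (is.null(names)) names <- paste0("motif_", seq_along(motifs))
  bg <- motifs[[1]]$background
  strands <- if (motifs[[1]]$strand_mode == "both_strands") "+ -" else "+"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               paste("strands:", strands), "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    writeLines(sprintf("MOTIF %s", names[k]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      m$width, max(1L, m$nsites)), con)
    writeLines(apply(m$ppm, 1L, function(p)
      sprintf(" %.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from minimal motif-exchange text format
#'
#' @param path file written by [write_motifs()] or any minimal-format
#'   motif file over the ACGT alphabet.
#' @return list of `motif_model` objects (with IC recomputed against the
#'   file's background; likelihood fields are NA).
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop("cannot read motif file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines)))
    stop("not a minimal motif-exchange file (missing version header): ", path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toks[c(TRUE, FALSE)]
    bg <- vals[DNA_BASES4]
  }
  strands_at <- grep("^strands:", lines, value = TRUE)
  mode <- if (length(strands_at) && grepl("-", strands_at[1]))
    "both_strands" else "one_strand"
  motif_at <- grep("^MOTIF", lines)
  motifs <- list()
  for (at in motif_at) {
    name <- strsplit(trimws(lines[at]), "\\s+")[[1]][2]
    hdr_at <- at + grep("^letter-probability matrix:",
                        lines[(at + 1L):length(lines)])[1]
    hdr <- lines[hdr_at]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
    nsites <- suppressWarnings(
      as.integer(sub(".*nsites= *([0-9]+).*", "\\1", hdr)))
    rows <- lines[(hdr_at + 1L):(hdr_at + w)]
    ppm <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    colnames(ppm) <- DNA_BASES4
    motifs[[name]] <- structure(
      list(width = w, ppm = ppm, background = bg, gamma = NA_real_,
           strand_mode = mode, ic = information_content(ppm, bg),
           loglik = NA_real_, loglik_gain = NA_real_,
           consensus = consensus_of_ppm(ppm),
           nsites = if (is.na(nsites)) 0L else nsites,
           occurrences = data.frame(), trace = numeric(0)),
      class = "motif_model")
  }
  motifs
}

#' Write motif occurrences as BED6
#'
#' Columns: seq_id, start, end (0-based half-open), name (motif id),
#' score = round(1000 * posterior), strand.
#' @param occurrences occurrence data.frame (seq_id, start, end, strand,
#'   posterior).
#' @param path output path.
#' @param name motif name for column 4.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occurrences, path, name = "motif_1") {
  bed <- data.frame(occurrences$seq_id, occurrences$start, occurrences$end,
                    name, round(1000 * occurrences$posterior),
                    occurrences$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED6 motif occurrences
#' @param path BED6 file from [write_occurrences_bed()].
#' @return occurrence data.frame (seq_id, start, end, strand, posterior).
#' @export
read_occurrences_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(seq_id = bed[[1]], start = bed[[2]], end = bed[[3]],
             strand = bed[[6]], posterior = bed[[5]] / 1000,
             stringsAsFactors = FALSE)
}

#' Export logo-ready per-column letter heights
#'
#' Two dialects are provided: `"ic"` scales each column's letter
#' probabilities by the column information content in bits (entropy-style
#' logos), `"odds"` exports per-letter log2 odds against the background
#' clipped at 0 (background-relative heights).
#'
#' @param motif a `motif_model`.
#' @param path output TSV path (column, A, C, G, T).
#' @param heights `"ic"` or `"odds"`.
#' @return the height matrix, invisibly.
#' @export
write_logo_tsv <- function(motif, path, heights = c("ic", "odds")) {
  heights <- match.arg(heights)
  h <- if (heights == "ic") motif$ppm * motif$ic
    else pmax(log2(sweep(motif$ppm, 2L, motif$background, "/")), 0)
  out <- data.frame(column = seq_len(motif$width), h)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(h)
}

#' Write a JSON discovery report
#'
#' Per motif: consensus, gamma, nsites, loglik trace, and IC vector.
#' @param result a `discovery_result` or `motif_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_discovery_json <- function(result, path) {
  motifs <- if (inherits(result, "motif_model")) list(result) else
    result$motifs
  rep <- lapply(motifs, function(m)
    list(width = m$width, consensus = m$consensus, gamma = m$gamma,
         nsites = m$nsites, total_ic_bits = sum(m$ic), ic = m$ic,
         loglik = m$loglik, loglik_gain = m$loglik_gain,
         loglik_trace = m$trace))
  names(rep) <- paste0("motif_", seq_along(rep))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
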