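# Input/output for annotated mitochondrial genomes and D-loop sequence sets.
#
# Internal coordinates are 0-based half-open everywhere in this package;
# GenBank 1-based inclusive intervals are converted exactly once, here at
# parse/extraction time, and interval strings shown to the user keep the
# GenBank convention.

#' Construct a D-loop sequence set
#'
#' A `dloop_set` is a data.frame with columns `id`, `species`, `sequence`,
#' `source_intervals` (GenBank-style 1-based interval string, may be ""),
#' and `wraps_origin`. All motif-discovery functions accept one.
#'
#' @param sequence character vector of DNA sequences.
#' @param id character vector of unique identifiers (defaults to names of
#'   `sequence` or `seq_1`, `seq_2`, ...).
#' @param species character vector (optional).
#' @param source_intervals character vector (optional).
#' @param wraps_origin logical vector (optional).
#' @return an object of class `dloop_set`.
#' @export
dloop_set <- function(sequence, id = NULL, species = NA_character_,
                      source_intervals = "", wraps_origin = FALSE) {
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (is.null(id)) {
    id <- if (!is.null(names(sequence))) names(sequence) else
      paste0("seq_", seq_len(n))
  }
  stopifnot(length(id) == n, !anyDuplicated(id))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    n_amb <- sum(vapply(sequence[bad], function(s)
      nchar(gsub("[ACGTN]", "", s)), integer(1)))
    message("mapped ", n_amb, " ambiguity code(s) to N in ",
            sum(bad), " record(s)")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  out <- data.frame(id = as.character(id),
                    species = rep_len(as.character(species), n),
                    sequence = sequence,
                    source_intervals = rep_len(as.character(source_intervals), n),
                    wraps_origin = rep_len(as.logical(wraps_origin), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("dloop_set", "data.frame")
  out
}

#' @export
print.dloop_set <- function(x, ...) {
  cat("dloop_set with", nrow(x), "sequence(s); lengths",
      if (nrow(x)) paste0(min(nchar(x$sequence)), "-", max(nchar(x$sequence)))
      else "-", "nt\n")
  invisible(x)
}

# Coerce a dloop_set or named character vector to named character sequences.
#' @keywords internal
dloop_seqs <- function(x) {
  if (inherits(x, "dloop_set")) return(setNames(x$sequence, x$id))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
    return(toupper(x))
  }
  stop("expected a dloop_set or a named character vector of sequences")
}

# ---------------------------------------------------------------------------
# GenBank flat-file parsing (minimal: LOCUS topology, FEATURES, ORIGIN)
# ---------------------------------------------------------------------------

#' Read annotated genomes from a GenBank flat file
#'
#' Parses LOCUS (accession, topology), the feature table (keys, locations
#' including `join(...)` and `complement(...)`, qualifiers) and the ORIGIN
#' sequence block. Records lacking an explicit topology are treated as
#' circular, the default for mitochondrial genomes.
#'
#' @param path path to a GenBank flat file with one or more records.
#' @return a list of `genome_record` objects, in file order. Each has
#'   fields `id`, `species`, `sequence`, `length`, `is_circular`, and
#'   `features` (a list of `list(key, intervals, qualifiers)`, intervals as
#'   a 2-column matrix of 1-based inclusive start/end).
#' @export
read_genomes <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (!length(locus_idx)) stop("not a GenBank flat file (no LOCUS line): ", path)
  end_idx <- grep("^//\\s*$", lines)
  if (length(end_idx) < length(locus_idx))
    stop("truncated GenBank file: record without terminating '//' in ", path)
  records <- list()
  for (k in seq_along(locus_idx)) {
    from <- locus_idx[k]
    to <- end_idx[which(end_idx > from)[1]]
    rec <- parse_genbank_record(lines[from:to])
    if (is.null(rec)) next
    records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) stop("no usable records in GenBank file: ", path)
  records
}

#' @keywords internal
parse_genbank_record <- function(rl) {
  locus <- rl[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else "unknown"
  is_circular <- if (grepl("\\blinear\\b", locus, ignore.case = TRUE)) FALSE
    else TRUE  # explicit 'circular' or unstated: mitochondrial default
  # accession line overrides LOCUS name when present
  acc <- grep("^ACCESSION", rl, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "\\s+")[[1]]
    if (length(a) >= 2) id <- a[2]
  }
  feat_start <- grep("^FEATURES", rl)
  origin_start <- grep("^ORIGIN", rl)
  features <- list()
  species <- NA_character_
  if (length(feat_start)) {
    fend <- if (length(origin_start)) origin_start[1] - 1L else length(rl)
    features <- parse_feature_table(rl[(feat_start[1] + 1L):fend])
    src <- Filter(function(f) identical(tolower(f$key), "source"), features)
    if (length(src) && !is.null(src[[1]]$qualifiers[["organism"]]))
      species <- src[[1]]$qualifiers[["organism"]]
  }
  sequence <- ""
  if (length(origin_start)) {
    seq_lines <- rl[(origin_start[1] + 1L):(length(rl) - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (!nzchar(sequence)) {
    warning("record ", id, " has zero-length sequence; skipped")
    return(NULL)
  }
  structure(list(id = id, species = species, sequence = sequence,
                 length = nchar(sequence), is_circular = is_circular,
                 features = features),
            class = "genome_record")
}

#' @keywords internal
parse_feature_table <- function(fl) {
  fl <- fl[nzchar(trimws(fl))]
  features <- list()
  cur <- NULL
  cur_qual <- NULL  # name of qualifier being continued
  for (ln in fl) {
    if (grepl("^ {5}\\S", ln)) {              # new feature
      if (!is.null(cur)) features[[length(features) + 1L]] <- finish_feature(cur)
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = parts[1],
                  location = paste(parts[-1], collapse = ""),
                  qualifiers = list())
      cur_qual <- NULL
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {             # qualifier
        m <- regmatches(txt, regexec("^/([^=]+)(=(.*))?$", txt))[[1]]
        qname <- m[2]
        qval <- if (length(m) >= 4 && nzchar(m[3])) gsub('^"|"$', "", m[4]) else ""
        cur$qualifiers[[qname]] <- qval
        cur_qual <- qname
      } else if (!is.null(cur_qual)) {        # qualifier continuation
        cur$qualifiers[[cur_qual]] <-
          paste(cur$qualifiers[[cur_qual]], gsub('"$', "", txt))
      } else {                                # location continuation
        cur$location <- paste0(cur$location, txt)
      }
    }
  }
  if (!is.null(cur)) features[[length(features) + 1L]] <- finish_feature(cur)
  features
}

#' @keywords internal
finish_feature <- function(f) {
  list(key = f$key,
       intervals = parse_location(f$location),
       location = f$location,
       qualifiers = f$qualifiers)
}

# Parse a GenBank location string into a 2-column matrix of 1-based
# inclusive intervals, in the stated join order. Strand is deferred.
#' @keywords internal
parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  loc <- gsub("complement\\(", "(", loc)
  loc <- gsub("join\\(", "(", loc)
  loc <- gsub("order\\(", "(", loc)
  loc <- gsub("[()<>]", "", loc)
  parts <- strsplit(loc, ",")[[1]]
  out <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2)))
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# ---------------------------------------------------------------------------
# D-loop extraction
# ---------------------------------------------------------------------------

#' Extract the D-loop / control region from an annotated genome
#'
#' Finds the first feature whose key matches one of `feature_keys`
#' (case-insensitive). A key of the form `"key:text"` matches features of
#' that key carrying any qualifier whose value contains `text`
#' (case-insensitive), e.g. `"misc_feature:control region"`. A location
#' joining a terminal interval to an initial interval of a circular genome
#' is linearized in the stated join order and flagged `wraps_origin`. The
#' forward (L-strand) orientation of the source record is always taken;
#' strand handling belongs to motif discovery.
#'
#' @param genome a `genome_record` from [read_genomes()].
#' @param feature_keys character vector of accepted feature keys.
#' @return a one-row [dloop_set()], or `NULL` (with a warning) when the
#'   genome has no matching annotation.
#' @export
extract_dloop <- function(genome,
                          feature_keys = c("D-loop",
                                           "misc_feature:control region")) {
  stopifnot(inherits(genome, "genome_record"))
  hit <- NULL
  n_match <- 0L
  for (f in genome$features) {
    for (fk in feature_keys) {
      spec <- strsplit(fk, ":", fixed = TRUE)[[1]]
      key_ok <- identical(tolower(f$key), tolower(spec[1]))
      qual_ok <- if (length(spec) > 1L) {
        any(vapply(f$qualifiers, function(q)
          grepl(tolower(spec[2]), tolower(q), fixed = TRUE), logical(1)))
      } else TRUE
      if (key_ok && qual_ok) {
        n_match <- n_match + 1L
        if (is.null(hit)) hit <- f
        break
      }
    }
  }
  if (is.null(hit)) {
    warning("no D-loop/control-region annotation in record ", genome$id)
    return(NULL)
  }
  if (n_match > 1L)
    warning("record ", genome$id, ": ", n_match,
            " matching features; using the first")
  iv <- hit$intervals
  L <- genome$length
  if (any(iv < 1L) || any(iv > L))
    stop("record ", genome$id, ": feature interval outside [1, ", L, "]")
  wraps <- FALSE
  if (nrow(iv) > 1L) {
    for (k in seq_len(nrow(iv) - 1L)) {
      if (iv[k, "end"] == L && iv[k + 1L, "start"] == 1L) wraps <- TRUE
    }
  }
  if (wraps && !genome$is_circular)
    stop("record ", genome$id,
         ": origin-wrapping feature location on a linear genome")
  seq_parts <- vapply(seq_len(nrow(iv)), function(k)
    substr(genome$sequence, iv[k, "start"], iv[k, "end"]), character(1))
  loc_str <- paste(sprintf("%d..%d", iv[, "start"], iv[, "end"]),
                   collapse = ",")
  dloop_set(sequence = paste(seq_parts, collapse = ""),
            id = genome$id, species = genome$species,
            source_intervals = loc_str, wraps_origin = wraps)
}

#' Extract D-loops from every record of a GenBank file
#'
#' @param path GenBank flat file.
#' @param feature_keys see [extract_dloop()].
#' @return a [dloop_set()] (possibly with fewer rows than the file has
#'   records, when annotations are missing).
#' @export
extract_dloops <- function(path,
                           feature_keys = c("D-loop",
                                            "misc_feature:control region")) {
  genomes <- read_genomes(path)
  sets <- Filter(Negate(is.null),
                 lapply(genomes, extract_dloop, feature_keys = feature_keys))
  if (!length(sets)) return(dloop_set(character(0), id = character(0)))
  out <- do.call(rbind, lapply(sets, as.data.frame))
  class(out) <- c("dloop_set", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# FASTA round trip
# ---------------------------------------------------------------------------

#' Write a D-loop set as FASTA
#'
#' Headers carry id, species, source interval string and wrap flag; lines
#' are wrapped at 60 columns.
#' @param records a [dloop_set()] (non-empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dloop_fasta <- function(records, path) {
  stopifnot(inherits(records, "dloop_set"), nrow(records) > 0L)
  xs <- Biostrings::DNAStringSet(records$sequence)
  names(xs) <- sprintf("%s species=%s loc=%s wraps=%d",
                       records$id,
                       gsub(" ", "_", ifelse(is.na(records$species), "NA",
                                             records$species)),
                       ifelse(nzchar(records$source_intervals),
                              records$source_intervals, "."),
                       as.integer(records$wraps_origin))
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a D-loop set
#'
#' Sequences are uppercased; headers written by [write_dloop_fasta()] have
#' their metadata fields recovered, any other header keeps its first token
#' as the id.
#' @param path FASTA file.
#' @return a [dloop_set()]; empty (with a warning) for an empty file.
#' @export
read_dloop_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(dloop_set(character(0), id = character(0)))
  }
  xs <- Biostrings::readDNAStringSet(path)
  headers <- names(xs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  field <- function(h, key) {
    m <- regmatches(h, regexec(paste0(key, "=(\\S+)"), h))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  species <- vapply(headers, field, character(1), "species", USE.NAMES = FALSE)
  species <- ifelse(species == "NA", NA_character_, gsub("_", " ", species))
  loc <- vapply(headers, field, character(1), "loc", USE.NAMES = FALSE)
  loc <- ifelse(is.na(loc) | loc == ".", "", loc)
  wraps <- vapply(headers, field, character(1), "wraps", USE.NAMES = FALSE)
  wraps <- !is.na(wraps) & wraps == "1"
  dloop_set(sequence = as.character(xs), id = ids, species = species,
            source_intervals = loc, wraps_origin = wraps)
}
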