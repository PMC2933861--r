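# File formats: FASTA in, bedGraph/TSV/BED/JSON out. All coordinates are
# written 0-based half-open except AGP, which is converted at the boundary.

#' Read genome sequences from FASTA
#'
#' Reads a (possibly gzipped) multi-record FASTA. Record ids are the header
#' up to the first whitespace; duplicates are an error. Sequences are
#' uppercased (soft-masking is ignored) and restricted to A/C/G/T/N — any
#' other character is an error naming the record and offset.
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @return A named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(readDNAStringSet(path),
                  error = function(e)
                    stop("failed to read FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L)
      stop(sprintf(
        "record '%s': invalid character '%s' at offset %d",
        ids[i], substr(seqs[[i]], bad, bad), as.integer(bad)
      ), call. = FALSE)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector (or `synthetic_genome`).
#' @param path Output path (`.gz` suffix compresses).
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequences, path, width = 70L) {
  if (inherits(sequences, "synthetic_genome")) sequences <- sequences$sequences
  set <- DNAStringSet(sequences)
  writeXStringSet(set, path, width = width,
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a window profile as bedGraph
#'
#' One `chrom start end value` line per window with a value; missing
#' windows are omitted. Values are printed with 6 significant digits.
#'
#' @param profile A `window_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "window_profile"))
  keep <- !is.na(profile$value)
  lines <- sprintf("%s\t%d\t%d\t%.6g", profile$seqid[keep],
                   profile$start[keep], profile$end[keep],
                   profile$value[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Write a window profile as TSV
#'
#' Headered table with every window, including missing ones (`NA` value):
#' `sequence_id`, `start`, `end`, `metric`, `value`, `informative_length`.
#'
#' @inheritParams write_bedgraph
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "window_profile"))
  df <- data.frame(
    sequence_id = profile$seqid, start = profile$start, end = profile$end,
    metric = attr(profile, "metric"), value = profile$value,
    informative_length = profile$informative
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph profile back
#'
#' Inverse of [write_bedgraph()] up to omitted missing windows; used mainly
#' for round-trip checks and for feeding externally computed profiles into
#' the junction tools.
#'
#' @param path bedGraph path.
#' @param metric Metric label to attach.
#' @param window_size,step Window geometry of the stored profile.
#' @return A `window_profile`.
#' @export
read_bedgraph <- function(path, metric = "binding_energy",
                          window_size = 50000L, step = window_size) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("seqid", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  new_window_profile(df$seqid, df$start, df$end, df$value,
                     informative = rep(NA_integer_, nrow(df)),
                     metric = metric, window_size = window_size, step = step)
}

#' Write a signature vector as JSON
#'
#' @param signature A `signature_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_json <- function(signature, path) {
  stopifnot(inherits(signature, "signature_vector"))
  jsonlite::write_json(
    list(rho = as.list(signature$rho),
         defined = as.list(signature$defined),
         symmetrized = signature$symmetrized,
         n_dinuc = signature$n_dinuc),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a signature vector from JSON
#'
#' @param path Path written by [write_signature_json()].
#' @return A `signature_vector`.
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rho <- unlist(x$rho)[DINUCS]
  defined <- as.logical(unlist(x$defined)[DINUCS])
  rho[!defined] <- NA_real_
  new_signature_vector(rho, defined, isTRUE(x$symmetrized),
                       x$n_dinuc %||% NA_real_)
}

#' Write monomer hits as BED6
#'
#' Score column is `round(identity * 1000)`.
#'
#' @param hits A `monomer_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$seqid, hits$start,
                   hits$end, sprintf("hit_%d", seq_len(nrow(hits))),
                   as.integer(round(hits$identity * 1000)), hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write repeat arrays as BED6
#'
#' Score column is the hit count; strand is `+` (arrays may mix strands —
#' see the `strand_mix` column of [cluster_arrays()] output).
#'
#' @param arrays A `repeat_arrays` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrays_bed <- function(arrays, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+", arrays$seqid, arrays$start,
                   arrays$end, sprintf("array_%d", seq_len(nrow(arrays))),
                   arrays$hit_count)
  writeLines(lines, path)
  invisible(path)
}
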