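# Satellite monomer search and tandem-array detection.
#
# Centromeric satellites are short (here ~91 bp) monomers repeated
# head-to-tail in large arrays. The search is deliberately simple: ungapped
# full-length alignment of the monomer at every offset on both strands,
# keeping matches at >= 90% identity, then single-linkage chaining of hits
# whose starts lie within 10 monomer lengths of each other. At this identity
# over ~91 bp, indel-free matching recovers satellite arrays without a
# gapped aligner; gapped search is out of scope.

#' Find ungapped monomer matches in a genome
#'
#' Scans every offset of every sequence on both strands for full-length,
#' ungapped alignments of the monomer with identity
#' `matches / monomer_length >= min_identity` (Ns in the subject count as
#' mismatches). Overlapping hits on the same strand are reduced to local
#' identity maxima, so a hit set over a clean tandem array has one hit per
#' monomer copy.
#'
#' @param genome Sequences (named character vector, list, or
#'   `DNAStringSet`).
#' @param monomer The monomer sequence (character or `DNAString`), N-free,
#'   at least 20 bases.
#' @param min_identity Minimum identity in (0, 1\] (default 0.90).
#' @return A data frame of class `monomer_hits` with columns `seqid`,
#'   `start` (0-based), `end` (half-open), `strand`, `identity`, sorted by
#'   position, with the monomer length attached as an attribute.
#' @export
find_monomer_hits <- function(genome, monomer, min_identity = 0.90) {
  stopifnot(min_identity > 0, min_identity <= 1)
  seqs <- as_seq_set(genome, "genome record")
  monomer <- as.character(as_dna(monomer, "monomer"))
  L <- nchar(monomer)
  if (L < 20L) stop("monomer must be at least 20 bases", call. = FALSE)
  if (grepl("N", monomer, fixed = TRUE))
    stop("monomer contains N; an unambiguous query is required",
         call. = FALSE)
  max_mm <- as.integer(floor(L * (1 - min_identity) + 1e-9))
  pats <- list(`+` = seq_to_int(monomer),
               `-` = seq_to_int(revcomp_chr(monomer)))
  out <- list()
  for (id in names(seqs)) {
    subject <- seq_to_int(seqs[[id]])
    for (strand in c("+", "-")) {
      h <- cpp_hamming_hits(subject, pats[[strand]], max_mm)
      if (length(h$start) == 0L) next
      identity <- (L - h$mismatches) / L
      keep <- .reduce_overlapping_hits(h$start, identity, L)
      out[[length(out) + 1L]] <- data.frame(
        seqid = id, start = h$start[keep], end = h$start[keep] + L,
        strand = strand, identity = identity[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(out) == 0L) {
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               strand = character(0), identity = numeric(0))
  } else {
    do.call(rbind, out)
  }
  hits <- hits[order(hits$seqid, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, monomer_length = L,
            class = c("monomer_hits", "data.frame"))
}

## Non-maximum suppression within one (sequence, strand): greedy by identity
## (ties to the leftmost hit), rejecting any hit overlapping an already
## accepted one. Hits exactly one monomer length apart do not overlap, so
## clean tandem copies all survive.
.reduce_overlapping_hits <- function(starts, identity, L) {
  ord <- order(-identity, starts)
  keep <- logical(length(starts))
  accepted <- numeric(0)
  for (i in ord) {
    if (length(accepted) == 0L || all(abs(accepted - starts[i]) >= L)) {
      keep[i] <- TRUE
      accepted <- c(accepted, starts[i])
    }
  }
  keep
}

#' Chain monomer hits into tandem arrays
#'
#' Single-linkage clustering by the gap rule: consecutive hits (sorted by
#' start, strands pooled) join the same array when their starts differ by at
#' most `max_gap_factor * monomer_length` (910 bp for a 91-mer at the
#' default factor of 10). Clusters of a single hit are discarded; an array's
#' interval runs from its first hit start to its last hit end.
#'
#' @param hits A `monomer_hits` data frame (or any data frame with `seqid`,
#'   `start`, `end`, `strand`, `identity`).
#' @param monomer_length Monomer length in bases; taken from `hits` when
#'   available.
#' @param max_gap_factor Gap threshold as a multiple of the monomer length
#'   (default 10).
#' @return A data frame of class `repeat_arrays`: `seqid`, `start`, `end`,
#'   `hit_count`, `mean_identity`, `strand_mix` (fraction of reverse-strand
#'   hits).
#' @export
cluster_arrays <- function(hits, monomer_length = attr(hits, "monomer_length"),
                           max_gap_factor = 10) {
  stopifnot(max_gap_factor >= 1)
  if (is.null(monomer_length))
    stop("monomer_length is required when hits carry no attribute",
         call. = FALSE)
  threshold <- max_gap_factor * monomer_length
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), hit_count = integer(0),
                      mean_identity = numeric(0), strand_mix = numeric(0))
  if (nrow(hits) == 0L)
    return(structure(empty, class = c("repeat_arrays", "data.frame")))
  out <- list()
  for (id in unique(hits$seqid)) {
    h <- hits[hits$seqid == id, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(h$start) > threshold))
    for (g in unique(grp)) {
      rows <- h[grp == g, , drop = FALSE]
      if (nrow(rows) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        seqid = id, start = min(rows$start), end = max(rows$end),
        hit_count = nrow(rows), mean_identity = mean(rows$identity),
        strand_mix = mean(rows$strand == "-"), stringsAsFactors = FALSE
      )
    }
  }
  arrays <- if (length(out) == 0L) empty else do.call(rbind, out)
  arrays <- arrays[order(arrays$seqid, arrays$start), , drop = FALSE]
  rownames(arrays) <- NULL
  structure(arrays, class = c("repeat_arrays", "data.frame"))
}

#' Symmetrized signature of a repeat array
#'
#' Extracts the array interval from the genome and computes its rho*
#' signature, for contrasting the array's dinucleotide composition (e.g. CG
#' enrichment, CC/GG depletion of centromeric satellites) against a
#' genome-wide baseline via [delta_star()].
#'
#' @param genome Sequences (named as in [find_monomer_hits()]).
#' @param array A one-row data frame or list with `seqid`, `start`, `end`
#'   (0-based half-open), e.g. a row of [cluster_arrays()] output.
#' @return A `signature_vector`.
#' @export
array_signature <- function(genome, array) {
  seqs <- as_seq_set(genome, "genome record")
  seqid <- as.character(array$seqid[1L] %||% array[["seqid"]])
  start <- as.integer(array$start[1L])
  end <- as.integer(array$end[1L])
  if (!seqid %in% names(seqs))
    stop("array sequence id '", seqid, "' not in genome", call. = FALSE)
  len <- nchar(seqs[[seqid]])
  if (start < 0L || end > len || start >= end)
    stop("array interval [", start, ", ", end, ") outside sequence '",
         seqid, "' of length ", len, call. = FALSE)
  rho_star(count_dinucleotides(substr(seqs[[seqid]], start + 1L, end)))
}

#' Scan for tandem periodicity
#'
#' For each candidate period p, scores the fraction of positions i (over
#' non-N pairs) with `base(i) == base(i + p)`. An exactly p-periodic
#' sequence scores 1 at p (and at its multiples); random sequence scores
#' near 0.25. Periods are ranked by score with one dominant-length
#' adjustment: every multiple of a true monomer length scores equally well
#' up to sampling noise (copies are equidistant from the shared consensus),
#' so the smallest divisor of the top-scoring period whose score lies
#' within three standard errors of the top score is promoted to rank 1.
#' Multiples of that dominant period are annotated as its harmonics.
#'
#' @param sequence A sequence of length at least `2 * max_period`.
#' @param max_period Largest period to test (default 200).
#' @return A data frame with `period`, `score`, `n_pairs` (comparisons
#'   made), and `harmonic_of` (`NA` except for multiples of the dominant
#'   period), dominant period first, then decreasing score.
#' @export
detect_tandem_periods <- function(sequence, max_period = 200L) {
  x <- seq_to_int(as.character(as_dna(sequence)))
  n <- length(x)
  max_period <- as.integer(max_period)
  if (n < 2L * max_period)
    stop("sequence too short: need at least 2 * max_period = ",
         2L * max_period, " bases", call. = FALSE)
  x[x == 0L] <- NA_integer_
  stats <- vapply(seq_len(max_period), function(p) {
    a <- x[seq_len(n - p)]
    b <- x[seq.int(p + 1L, n)]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(c(NA_real_, 0))
    c(sum(a[ok] == b[ok]) / sum(ok), sum(ok))
  }, numeric(2))
  score <- stats[1L, ]
  n_pairs <- stats[2L, ]
  argmax <- which.max(score)          # smallest period on exact ties
  dominant <- argmax
  divs <- which(argmax %% seq_len(argmax - 1L) == 0L)
  for (d in divs) {                   # ascending
    if (is.na(score[d]) || n_pairs[d] == 0L) next
    se <- sqrt(score[d] * (1 - score[d]) / n_pairs[d])
    if (score[d] >= score[argmax] - 3 * se) {
      dominant <- d
      break
    }
  }
  out <- data.frame(period = seq_len(max_period), score = score,
                    n_pairs = as.integer(n_pairs))
  out <- out[order(out$period != dominant, -out$score, out$period), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$harmonic_of <- ifelse(out$period != dominant &
                              out$period %% dominant == 0L,
                            dominant, NA_integer_)
  out
}
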