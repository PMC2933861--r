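# Dinucleotide relative-abundance signatures.
#
# For a sequence with nucleotide frequencies f_X and dinucleotide frequencies
# f_XY (overlapping 2-mers), the signature of dinucleotide XY is the odds
# ratio rho_XY = f_XY / (f_X f_Y). Because genomic DNA is double stranded the
# symmetrized form rho*_XY pools every count with its reverse complement
# before forming frequencies, so rho*_XY == rho*_revcomp(XY) by construction.
# The coarse-grained distance between two signature vectors f and g is
# delta*(f, g) = (1/16) * sum_XY |rho*_XY(f) - rho*_XY(g)|.

#' Count mononucleotides and dinucleotides in a sequence
#'
#' Counts follow the N-exclusion rule used throughout the package: bases
#' other than A/C/G/T contribute to neither the mononucleotide nor the
#' dinucleotide counts, and a dinucleotide is counted only when its two bases
#' are physically adjacent and both informative. In particular no pair is
#' formed across a run of Ns, so assembly gaps never create artifactual
#' dinucleotides. Dinucleotides are counted with overlap (positions i, i+1
#' for every i).
#'
#' @param sequence A character string, `DNAString`, or length-1
#'   `DNAStringSet` over the alphabet A/C/G/T/N (case-insensitive). Any other
#'   character is an error naming the offending position.
#' @return An object of class `dinuc_counts`: a list with `mono` (named
#'   length-4 integer), `dinuc` (named length-16 integer),
#'   `informative_length` (number of non-N bases), and `total_length`.
#' @examples
#' count_dinucleotides("ACGT")$dinuc[c("AC", "CG", "GT")]
#' count_dinucleotides("AANTT")$dinuc[c("AA", "TT", "AT")]  # no pair across N
#' @export
count_dinucleotides <- function(sequence) {
  dna <- as_dna(sequence)
  if (length(dna) == 0L) {
    return(new_dinuc_counts(
      setNames(integer(4L), DNA_BASES), setNames(integer(16L), DINUCS),
      informative = 0L, total = 0L
    ))
  }
  mono_all <- alphabetFrequency(dna, baseOnly = TRUE)
  mono <- mono_all[DNA_BASES]
  dinuc <- oligonucleotideFrequency(dna, width = 2L)[DINUCS]
  new_dinuc_counts(mono, dinuc, informative = sum(mono), total = length(dna))
}

new_dinuc_counts <- function(mono, dinuc, informative, total) {
  structure(
    list(
      mono = setNames(as.integer(mono), DNA_BASES),
      dinuc = setNames(as.integer(dinuc), DINUCS),
      informative_length = as.integer(informative),
      total_length = as.integer(total)
    ),
    class = "dinuc_counts"
  )
}

#' Merge dinucleotide counts from disjoint sequences
#'
#' Pools counts additively, as when accumulating a genome-wide baseline over
#' chromosomes. No dinucleotide is formed across the join (each argument was
#' counted independently), matching how multi-record inputs are handled.
#'
#' @param ... `dinuc_counts` objects.
#' @return A single pooled `dinuc_counts` object.
#' @export
merge_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "dinuc_counts"))
    xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, logical(1), "dinuc_counts")))
  new_dinuc_counts(
    mono = Reduce(`+`, lapply(xs, `[[`, "mono")),
    dinuc = Reduce(`+`, lapply(xs, `[[`, "dinuc")),
    informative = sum(vapply(xs, `[[`, integer(1), "informative_length")),
    total = sum(vapply(xs, `[[`, integer(1), "total_length"))
  )
}

#' @export
print.dinuc_counts <- function(x, ...) {
  cat(sprintf(
    "<dinuc_counts> %d informative / %d total bases, %d dinucleotides\n",
    x$informative_length, x$total_length, sum(x$dinuc)
  ))
  invisible(x)
}

## Core of the rho computation, shared by the scalar path (vectors) and the
## windowed path (one row per window). `mono` is n x 4, `dinuc` n x 16.
## Returns rho and definedness matrices; undefined entries (a component base
## frequency of zero) are NA, never 0 or Inf.
.rho_core_matrix <- function(mono, dinuc, symmetrize = TRUE) {
  if (symmetrize) {
    mono <- mono + mono[, COMP_IDX, drop = FALSE]
    dinuc <- dinuc + dinuc[, RC_IDX, drop = FALSE]
  }
  ntot <- rowSums(mono)
  dtot <- rowSums(dinuc)
  fX <- mono / ntot
  fXY <- dinuc / dtot
  den <- fX[, X_IDX, drop = FALSE] * fX[, Y_IDX, drop = FALSE]
  defined <- den > 0 & dtot > 0
  rho <- fXY / den
  rho[!defined] <- NA_real_
  colnames(rho) <- DINUCS
  colnames(defined) <- DINUCS
  list(rho = rho, defined = defined, n_dinuc = dtot)
}

new_signature_vector <- function(rho, defined, symmetrized, n_dinuc) {
  structure(
    list(
      rho = setNames(as.numeric(rho), DINUCS),
      defined = setNames(as.logical(defined), DINUCS),
      symmetrized = isTRUE(symmetrized),
      n_dinuc = as.numeric(n_dinuc)
    ),
    class = "signature_vector"
  )
}

#' Dinucleotide relative abundances (rho, rho*)
#'
#' Computes the 16 odds ratios `f_XY / (f_X f_Y)` from a `dinuc_counts`
#' object. With `symmetrize = TRUE` (the default, and the form used
#' everywhere else in the package) counts are first pooled with those of the
#' reverse complement — mononucleotides A with T and C with G, dinucleotides
#' XY with revcomp(XY) — so that the result is strand-independent:
#' `rho[XY] == rho[revcomp(XY)]` exactly.
#'
#' Entries whose component base frequencies are zero are undefined and
#' returned as `NA` with `defined = FALSE`; they are never reported as 0 or
#' infinity.
#'
#' @param counts A `dinuc_counts` object with `informative_length >= 2` and
#'   at least one counted dinucleotide.
#' @param symmetrize Pool counts with the reverse complement first (default
#'   `TRUE`).
#' @return An object of class `signature_vector`: list with `rho` (named
#'   numeric 16-vector), `defined` (named logical), `symmetrized`, and
#'   `n_dinuc` (dinucleotides counted, after any pooling).
#' @examples
#' sig <- rho_star(count_dinucleotides(strrep("A", 1000)))
#' sig$rho[c("AA", "TT")]  # both exactly 2 on a homopolymer
#' @export
rho_star <- function(counts, symmetrize = TRUE) {
  stopifnot(inherits(counts, "dinuc_counts"))
  if (counts$informative_length < 2L)
    stop("degenerate input: fewer than 2 informative bases", call. = FALSE)
  if (sum(counts$dinuc) == 0L)
    stop("degenerate input: no adjacent informative base pairs to count",
         call. = FALSE)
  res <- .rho_core_matrix(
    matrix(counts$mono, nrow = 1L), matrix(counts$dinuc, nrow = 1L),
    symmetrize = symmetrize
  )
  new_signature_vector(res$rho[1L, ], res$defined[1L, ], symmetrize,
                       res$n_dinuc[1L])
}

#' @export
print.signature_vector <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<signature_vector> %s, %d/16 defined, %g dinucleotides\n",
    if (x$symmetrized) "symmetrized (rho*)" else "unsymmetrized (rho)",
    sum(x$defined), x$n_dinuc
  ))
  print(round(matrix(x$rho, 4L, 4L,
                     dimnames = list(DNA_BASES, DNA_BASES)), digits))
  invisible(x)
}

#' Over-/under-representation thresholds for rho* entries
#'
#' Random-sequence calibration thresholds for single rho* components: for
#' random DNA a value above `upper` or below `lower` occurs with probability
#' below `tail_probability`, so values outside the band flag over- or
#' under-represented dinucleotides.
#'
#' @return A list with `upper` (1.23), `lower` (0.78), and
#'   `tail_probability` (0.001).
#' @export
signature_thresholds <- function() {
  list(upper = 1.23, lower = 0.78, tail_probability = 0.001)
}

#' Coarse-grained signature difference delta*
#'
#' `delta_star(f, g)` is the average absolute difference of two signature
#' vectors: `(1/16) * sum_XY |rho_XY(f) - rho_XY(g)|`. It is 1/16 of an L1
#' distance, hence non-negative, symmetric, and satisfies the triangle
#' inequality.
#'
#' Both vectors must have been symmetrized the same way. By default an entry
#' undefined in either vector is an error; with `skip_undefined = TRUE` the
#' mean is taken over the entries defined in both vectors instead
#' (skip-and-renormalize).
#'
#' @param f,g `signature_vector` objects with matching `symmetrized` flags.
#' @param skip_undefined Average over mutually defined entries instead of
#'   erroring on undefined ones (default `FALSE`).
#' @return A non-negative number.
#' @examples
#' a <- rho_star(count_dinucleotides(strrep("ACGT", 250)))
#' delta_star(a, a)  # identical vectors -> 0
#' @export
delta_star <- function(f, g, skip_undefined = FALSE) {
  stopifnot(inherits(f, "signature_vector"), inherits(g, "signature_vector"))
  if (!identical(f$symmetrized, g$symmetrized))
    stop("configuration error: signature vectors have mismatched ",
         "symmetrization flags", call. = FALSE)
  both <- f$defined & g$defined
  if (!all(both)) {
    if (!skip_undefined)
      stop("undefined rho entries (", paste(DINUCS[!both], collapse = ", "),
           "); use skip_undefined = TRUE to average over defined entries",
           call. = FALSE)
    if (!any(both))
      stop("no entry is defined in both signature vectors", call. = FALSE)
  }
  mean(abs(f$rho[both] - g$rho[both]))
}

#' Genome-wide signature from one or more records
#'
#' Pools mononucleotide and dinucleotide counts over all records (no
#' dinucleotide spans a record boundary) and computes the symmetrized
#' signature, giving the genome-wide baseline vector that windowed delta*
#' profiles are compared against.
#'
#' @param records Sequences: named character vector, list, or `DNAStringSet`.
#' @param symmetrize Pool with reverse-complement counts (default `TRUE`).
#' @return A `signature_vector`.
#' @export
genome_signature <- function(records, symmetrize = TRUE) {
  seqs <- as_seq_set(records, "record")
  counts <- merge_counts(lapply(seqs, count_dinucleotides))
  rho_star(counts, symmetrize = symmetrize)
}

#' Windowed delta* profile against a baseline signature
#'
#' Slides non-overlapping (or stepped) windows along a sequence, computes the
#' symmetrized signature of each window, and records its delta* distance from
#' `baseline` (typically [genome_signature()] of the whole assembly). Windows
#' with fewer informative bases than half the window size, or with any
#' undefined rho* entry, yield `NA` rather than a value; the terminal partial
#' window is retained and flagged `short`.
#'
#' @param record A single sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`); a name, if present, becomes the profile's sequence id.
#' @param baseline A fully defined, symmetrized `signature_vector`.
#' @param window_size Window width in bases (default 50000, minimum 1000).
#' @param step Distance between window starts (default `window_size`, i.e.
#'   non-overlapping).
#' @param seqid Sequence id for the profile (defaults to the record's name).
#' @return A `window_profile` data frame (columns `seqid`, `start`, `end`,
#'   `value`, `informative`, `short`) with metric `"delta_star"`.
#' @export
delta_profile <- function(record, baseline, window_size = 50000L,
                          step = window_size, seqid = NULL) {
  stopifnot(inherits(baseline, "signature_vector"))
  if (!baseline$symmetrized)
    stop("baseline must be a symmetrized signature (rho*); windowed delta* ",
         "profiles are strand-symmetric by construction", call. = FALSE)
  if (!all(baseline$defined))
    stop("baseline signature has undefined entries (",
         paste(DINUCS[!baseline$defined], collapse = ", "),
         "); cannot scan against it", call. = FALSE)
  wc <- .window_counts(record, window_size, step, seqid = seqid)
  res <- .rho_core_matrix(wc$mono, wc$dinuc, symmetrize = TRUE)
  dev <- abs(res$rho - matrix(baseline$rho, nrow(res$rho), 16L, byrow = TRUE))
  value <- rowMeans(dev)          # NA whenever any entry is undefined
  value[wc$informative < window_size / 2] <- NA_real_
  new_window_profile(wc$seqid, wc$start, wc$end, value, wc$informative,
                     metric = "delta_star", window_size = window_size,
                     step = step)
}
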