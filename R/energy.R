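# Nearest-neighbor (NN) DNA duplex free energies and windowed binding-energy
# profiles. The default parameter set is the consensus table of ten unique
# dinucleotide-pair free energies of binding at 37 degrees C (kcal/mol),
# expanded to all 16 dinucleotides by reverse-complement sharing: a duplex
# step and its reverse complement are the same physical stack, so
# dg[XY] == dg[revcomp(XY)] always.

.DEFAULT_DG <- c(
  "AA/TT" = -1.00, "AC/GT" = -1.44, "AG/CT" = -1.28, "AT" = -0.88,
  "CA/TG" = -1.45, "CC/GG" = -1.84, "CG" = -2.17, "GA/TC" = -1.30,
  "GC" = -2.24, "TA" = -0.58
)

.expand_pairs <- function(pairs) {
  dg <- setNames(rep(NA_real_, 16L), DINUCS)
  for (i in seq_along(pairs)) {
    label <- names(pairs)[i]
    members <- strsplit(label, "/", fixed = TRUE)[[1L]]
    members <- toupper(trimws(members))
    if (!all(members %in% DINUCS))
      stop("bad pair label '", label, "' in energy table", call. = FALSE)
    rc <- RC_DINUC[members[1L]]
    expected <- unique(c(members[1L], rc))
    if (!setequal(unique(members), expected))
      stop("pair label '", label, "' does not name a reverse-complement ",
           "pair", call. = FALSE)
    for (m in expected) {
      if (!is.na(dg[m]) && dg[m] != pairs[i])
        stop("conflicting values for dinucleotide ", m, call. = FALSE)
      dg[m] <- pairs[i]
    }
  }
  if (anyNA(dg))
    stop("energy table incomplete; missing ",
         paste(DINUCS[is.na(dg)], collapse = ", "), call. = FALSE)
  dg
}

new_energy_table <- function(pairs) {
  structure(list(dg = .expand_pairs(pairs), source_pairs = pairs),
            class = "energy_table")
}

#' Default nearest-neighbor free-energy table
#'
#' The packaged consensus NN free energies of binding at 37 degrees C, in
#' kcal/mol: ten unique reverse-complement pair parameters expanded to all 16
#' dinucleotides. All values are negative (binding is favorable); GC is the
#' most stable step (-2.24) and TA the least (-0.58).
#'
#' @return An `energy_table`: list with `dg` (named numeric 16-vector) and
#'   `source_pairs` (the 10 unique pair parameters).
#' @examples
#' tab <- default_energy_table()
#' tab$dg[c("AA", "TT", "GC", "CA", "TG")]
#' @export
default_energy_table <- function() new_energy_table(.DEFAULT_DG)

#' Read a nearest-neighbor energy table from TSV
#'
#' Expects two tab-separated columns: a pair label (`"AA/TT"`, or a single
#' self-complementary dinucleotide such as `"AT"`) and the free energy in
#' kcal/mol. All ten unique pairs must be present; reverse-complement
#' expansion and consistency are enforced. Lets alternative NN parameter sets
#' be swapped in for the packaged default.
#'
#' @param path Path to the TSV file. A header line (`pair`, `dg`) is
#'   optional.
#' @return An `energy_table`.
#' @export
read_energy_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", strip.white = TRUE)
  if (ncol(df) < 2L) stop("energy table needs two columns", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L])))) df <- df[-1L, ]
  vals <- as.numeric(df[[2L]])
  if (anyNA(vals)) stop("non-numeric free energy values", call. = FALSE)
  new_energy_table(setNames(vals, df[[1L]]))
}

#' @export
print.energy_table <- function(x, ...) {
  cat("<energy_table> NN free energy of binding at 37C (kcal/mol)\n")
  print(x$source_pairs)
  invisible(x)
}

#' Mean nearest-neighbor binding energy of a sequence
#'
#' Sums the NN free energies of all counted (overlapping, non-N-adjacent)
#' dinucleotides and divides by their number. The N-exclusion rule matches
#' [count_dinucleotides()]: a dinucleotide with an N, or spanning an N run,
#' contributes nothing to either the sum or the denominator.
#'
#' Because the free energies are negative, the value is reported as a
#' positive magnitude by default (the conventional plotting scale);
#' `report_magnitude = FALSE` restores the signed mean.
#'
#' @param sequence A sequence over A/C/G/T/N.
#' @param table An `energy_table` (default [default_energy_table()]).
#' @param report_magnitude Flip the sign to a positive magnitude (default
#'   `TRUE`).
#' @return The mean energy in kcal/mol per dinucleotide, or `NA` when no
#'   dinucleotide could be counted.
#' @examples
#' window_energy(strrep("A", 1000), report_magnitude = FALSE)  # -1.00
#' window_energy(strrep("C", 1000), report_magnitude = FALSE)  # -1.84
#' @export
window_energy <- function(sequence, table = default_energy_table(),
                          report_magnitude = TRUE) {
  stopifnot(inherits(table, "energy_table"))
  counts <- count_dinucleotides(sequence)
  d <- sum(counts$dinuc)
  if (d == 0L) return(NA_real_)
  e <- sum(counts$dinuc * table$dg) / d
  if (report_magnitude) -e else e
}

#' Windowed binding-energy profile
#'
#' Mean NN binding energy per window along a sequence. The windowing contract
#' matches [delta_profile()]: windows with fewer informative bases than half
#' the window size (or with no countable dinucleotide) are `NA`, and the
#' terminal partial window is retained and flagged.
#'
#' @inheritParams delta_profile
#' @inheritParams window_energy
#' @return A `window_profile` with metric `"binding_energy"`.
#' @export
energy_profile <- function(record, window_size = 50000L, step = window_size,
                           table = default_energy_table(),
                           report_magnitude = TRUE, seqid = NULL) {
  stopifnot(inherits(table, "energy_table"))
  wc <- .window_counts(record, window_size, step, seqid = seqid)
  d <- rowSums(wc$dinuc)
  value <- as.numeric(wc$dinuc %*% table$dg) / d   # NaN where d == 0
  value[d == 0L | wc$informative < window_size / 2] <- NA_real_
  if (report_magnitude) value <- -value
  new_window_profile(wc$seqid, wc$start, wc$end, value, wc$informative,
                     metric = "binding_energy", window_size = window_size,
                     step = step)
}

#' Windowed GC-content profile
#'
#' Per-window (C+G) fraction, with Ns excluded from both numerator and
#' denominator; a window with no informative base is `NA`.
#'
#' @inheritParams delta_profile
#' @return A `window_profile` with metric `"gc_fraction"`.
#' @examples
#' gc_profile(strrep("GGCCATAT", 250))$value  # 0.5
#' @export
gc_profile <- function(record, window_size = 50000L, step = window_size,
                       seqid = NULL) {
  wc <- .window_counts(record, window_size, step, seqid = seqid,
                       min_window = 1L)
  value <- (wc$mono[, "C"] + wc$mono[, "G"]) / wc$informative
  value[wc$informative == 0L] <- NA_real_
  new_window_profile(wc$seqid, wc$start, wc$end, value, wc$informative,
                     metric = "gc_fraction", window_size = window_size,
                     step = step)
}
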