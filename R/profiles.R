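# Windowed profiles over half-open, 0-based genomic intervals.
#
# A window_profile is a data frame with one row per window (seqid, start,
# end, value, informative, short) plus attributes recording the metric
# ("delta_star", "binding_energy", or "gc_fraction"), window size, and step.
# Windows are sorted and, at the default step == window_size, tile the
# sequence without overlap; only the terminal window may be shorter.

new_window_profile <- function(seqid, start, end, value, informative,
                               metric, window_size, step) {
  stopifnot(length(start) == length(end), length(value) == length(start))
  df <- data.frame(
    seqid = if (length(seqid) == 1L) rep(seqid, length(start)) else seqid,
    start = as.integer(start),
    end = as.integer(end),
    value = as.numeric(value),
    informative = as.integer(informative),
    short = (end - start) < window_size,
    stringsAsFactors = FALSE
  )
  structure(df,
            metric = metric,
            window_size = as.integer(window_size),
            step = as.integer(step),
            class = c("window_profile", "data.frame"))
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf(
    "<window_profile> %s on %s: %d windows of %d bp (step %d), %d missing\n",
    attr(x, "metric"), x$seqid[1L] %||% "?", nrow(x), attr(x, "window_size"),
    attr(x, "step"), sum(is.na(x$value))
  ))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more windows)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Metric of a window profile
#' @param profile A `window_profile`.
#' @return One of `"delta_star"`, `"binding_energy"`, `"gc_fraction"`.
#' @export
profile_metric <- function(profile) attr(profile, "metric")

## Shared windowed counting: returns per-window mono (n x 4) and dinuc
## (n x 16) count matrices, informative base counts, and the window grid.
## Dinucleotides never span a window boundary (windows are counted
## independently), consistent with scanning each window as its own sequence.
.window_counts <- function(record, window_size, step, seqid = NULL,
                           min_window = 1000L) {
  if (is.null(seqid)) {
    nm <- names(record)
    seqid <- if (!is.null(nm) && nzchar(nm[1L])) nm[1L] else "seq1"
  }
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (window_size < min_window)
    stop("window_size must be at least ", min_window, " bases", call. = FALSE)
  if (step < 1L) stop("step must be positive", call. = FALSE)
  dna <- as_dna(if (is.character(record)) record[[1L]] else record)
  len <- length(dna)
  if (len < 1L) stop("cannot window an empty sequence", call. = FALSE)
  starts <- seq.int(0L, len - 1L, by = step)
  ends <- pmin(starts + window_size, len)
  v <- Views(dna, start = starts + 1L, end = ends)
  mono <- alphabetFrequency(v, baseOnly = TRUE)[, DNA_BASES, drop = FALSE]
  dinuc <- oligonucleotideFrequency(v, width = 2L)[, DINUCS, drop = FALSE]
  list(seqid = seqid, start = starts, end = ends,
       mono = mono, dinuc = dinuc, informative = rowSums(mono))
}

#' Pearson correlation between two window profiles
#'
#' Correlates two profiles computed on the same window grid (same sequence
#' id, starts, and ends), e.g. a binding-energy profile against a GC-content
#' profile. Windows missing in either profile are dropped pairwise; at least
#' 3 surviving pairs are required.
#'
#' @param p,q `window_profile` objects on identical grids.
#' @return The Pearson correlation coefficient, in \[-1, 1\].
#' @export
profile_correlation <- function(p, q) {
  stopifnot(inherits(p, "window_profile"), inherits(q, "window_profile"))
  if (!identical(p$seqid, q$seqid) || !identical(p$start, q$start) ||
      !identical(p$end, q$end))
    stop("profiles are not on the same window grid", call. = FALSE)
  ok <- !is.na(p$value) & !is.na(q$value)
  if (sum(ok) < 3L)
    stop("insufficient data: fewer than 3 windows with values in both ",
         "profiles", call. = FALSE)
  x <- p$value[ok]
  y <- q$value[ok]
  if (sd(x) == 0 || sd(y) == 0)
    stop("insufficient data: a profile is constant over the shared windows",
         call. = FALSE)
  cor(x, y)
}
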