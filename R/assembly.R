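# Scaffold-layout overlay and junction quality control.
#
# The guiding observation: large-scale composition gradients (binding
# energy, GC, delta*) run smoothly across correctly assembled pseudomolecule
# regions, so an abrupt break located precisely at a scaffold boundary is
# unlikely to be a property of the DNA and more likely a placement or
# orientation error. Junction scores quantify the break; flip evaluation
# asks whether reversing a scaffold's window order (exact for
# strand-symmetric metrics) reduces it.

new_assembly_layout <- function(df) {
  need <- c("object", "start", "end", "type", "component", "orientation",
            "gap_length")
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$object, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("assembly_layout", "data.frame"))
}

#' @export
print.assembly_layout <- function(x, ...) {
  cat(sprintf("<assembly_layout> %d objects, %d scaffold placements, %d gaps\n",
              length(unique(x$object)), sum(x$type == "sequence"),
              sum(x$type == "gap")))
  print.data.frame(head(as.data.frame(x), 8L))
  invisible(x)
}

.layout_scaffolds <- function(layout, object) {
  sc <- layout[layout$type == "sequence" & layout$object == object, ,
               drop = FALSE]
  if (nrow(sc) == 0L)
    stop("layout has no scaffold placements for object '", object, "'",
         call. = FALSE)
  sc[order(sc$start), , drop = FALSE]
}

#' Read a scaffold layout from AGP or BED
#'
#' AGP v2.0 (1-based inclusive, tab- or space-separated, `#` comments) and
#' BED6 (0-based half-open) are both normalized to internal 0-based half-open
#' coordinates. AGP gap components (types N/U) are preserved; all other
#' component types are treated as sequence placements. AGP objects must tile
#' contiguously without overlap; BED intervals must not overlap.
#'
#' @param path Path to a `.agp` or `.bed` file (detected by extension, with
#'   a content sniff as fallback).
#' @param seq_lengths Optional named vector of object lengths; placements
#'   extending past them are an error.
#' @return An `assembly_layout` data frame with columns `object`, `start`,
#'   `end`, `type` (`"sequence"`/`"gap"`), `component`, `orientation`,
#'   `gap_length`.
#' @export
read_layout <- function(path, seq_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  layout <- if (ext == "agp") {
    .read_agp(path)
  } else if (ext %in% c("bed", "bed6")) {
    .read_bed_layout(path)
  } else {
    first <- readLines(path, n = 50L)
    first <- first[!grepl("^#", first) & nzchar(first)][1L]
    fields <- strsplit(first, "[ \t]+")[[1L]]
    if (length(fields) >= 8L && fields[5L] %in%
        c("W", "N", "U", "A", "D", "F", "G", "O", "P"))
      .read_agp(path) else .read_bed_layout(path)
  }
  if (!is.null(seq_lengths)) {
    for (ob in unique(layout$object)) {
      if (!ob %in% names(seq_lengths)) next
      if (max(layout$end[layout$object == ob]) > seq_lengths[[ob]])
        stop("layout for object '", ob, "' extends past its sequence length ",
             seq_lengths[[ob]], call. = FALSE)
    }
  }
  layout
}

.read_agp <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty AGP file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop("malformed AGP line(s): ", paste(keep[nf < 8L], collapse = ", "),
         call. = FALSE)
  get <- function(i) vapply(fields, `[`, character(1), i)
  object <- get(1L)
  beg <- as.integer(get(2L))
  end <- as.integer(get(3L))
  part <- as.integer(get(4L))
  type <- get(5L)
  is_gap <- type %in% c("N", "U")
  gap_length <- rep(NA_integer_, length(object))
  gap_length[is_gap] <- as.integer(get(6L)[is_gap])
  df <- data.frame(
    object = object,
    start = beg - 1L,                        # to 0-based half-open
    end = end,
    type = ifelse(is_gap, "gap", "sequence"),
    component = ifelse(is_gap, NA_character_, get(6L)),
    orientation = NA_character_,
    gap_length = gap_length,
    line = keep,
    stringsAsFactors = FALSE
  )
  ori <- rep(NA_character_, nrow(df))
  ok9 <- !is_gap & nf >= 9L
  ori[ok9] <- vapply(fields[ok9], `[`, character(1), 9L)
  ori[!is_gap & (is.na(ori) | !ori %in% c("+", "-"))] <- "+"
  df$orientation <- ori
  ## validation: contiguous non-overlapping tiling per object, parts in order
  bad <- integer(0)
  for (ob in unique(df$object)) {
    sel <- df$object == ob
    rows <- df[sel, , drop = FALSE]
    rows <- rows[order(part[sel]), , drop = FALSE]
    if (rows$start[1L] != 0L) bad <- c(bad, rows$line[1L])
    if (nrow(rows) > 1L) {
      gapped <- rows$start[-1L] != rows$end[-nrow(rows)]
      bad <- c(bad, rows$line[-1L][gapped])
    }
    bad <- c(bad, rows$line[rows$end <= rows$start])
  }
  if (length(bad) > 0L)
    stop("AGP components do not tile object(s) contiguously; offending ",
         "line(s): ", paste(sort(unique(bad)), collapse = ", "),
         call. = FALSE)
  df$line <- NULL
  new_assembly_layout(df)
}

.read_bed_layout <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("empty BED file: ", path, call. = FALSE)
  nm <- gr$name
  if (is.null(nm) || anyNA(nm))
    stop("BED layout requires a name column (scaffold id)", call. = FALSE)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  df <- data.frame(
    object = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    type = "sequence",
    component = nm,
    orientation = strand,
    gap_length = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (ob in unique(df$object)) {
    rows <- df[df$object == ob, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1L] < rows$end[-nrow(rows)]))
      stop("overlapping BED intervals on object '", ob, "'", call. = FALSE)
  }
  new_assembly_layout(df)
}

#' Write a layout as AGP v2.0
#'
#' Converts the internal 0-based half-open representation back to AGP's
#' 1-based inclusive coordinates. Optionally applies accepted orientation
#' flips before writing.
#'
#' @param layout An `assembly_layout`.
#' @param path Output path.
#' @param flip Character vector of scaffold ids whose recorded orientation
#'   should be reversed in the emitted file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path, flip = character(0)) {
  stopifnot(inherits(layout, "assembly_layout"))
  lines <- character(nrow(layout))
  part <- 0L
  prev_object <- ""
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    if (row$object != prev_object) { part <- 0L; prev_object <- row$object }
    part <- part + 1L
    if (row$type == "gap") {
      lines[i] <- paste(row$object, row$start + 1L, row$end, part, "N",
                        row$gap_length, "scaffold", "yes", "paired-ends",
                        sep = "\t")
    } else {
      ori <- row$orientation
      if (row$component %in% flip) ori <- if (ori == "-") "+" else "-"
      lines[i] <- paste(row$object, row$start + 1L, row$end, part, "W",
                        row$component, 1L, row$end - row$start, ori,
                        sep = "\t")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## Discontinuity at one junction: |mean of the k non-missing windows nearest
## the junction on the left - same on the right|. Window index vectors are in
## ascending genomic order and restricted to the flanking scaffolds, so
## windows overlapping the junction (or a gap between the scaffolds) never
## contribute. NA when either side has fewer than k non-missing windows.
.junction_disc <- function(values, idx_left, idx_right, k) {
  vl <- values[idx_left]
  vl <- vl[!is.na(vl)]
  vr <- values[idx_right]
  vr <- vr[!is.na(vr)]
  if (length(vl) < k || length(vr) < k) return(NA_real_)
  abs(mean(tail(vl, k)) - mean(head(vr, k)))
}

.windows_within <- function(profile, start, end) {
  which(profile$start >= start & profile$end <= end)
}

#' Composition discontinuities at scaffold junctions
#'
#' For every junction between consecutive scaffolds on the profiled object,
#' computes the absolute difference between the mean profile value of the
#' `k` windows nearest the junction on each side. Only windows fully
#' contained in the flanking scaffold are used, so windows straddling the
#' junction (or an intervening gap) are excluded; gaps between scaffolds do
#' not create junctions of their own.
#'
#' @param profile A `window_profile` computed on the object sequence.
#' @param layout An `assembly_layout` containing the profile's sequence id
#'   as an object.
#' @param k Number of flanking windows per side (default 3).
#' @return A data frame of class `junction_scores`: `object`,
#'   `junction_pos`, `left_scaffold`, `right_scaffold`, `discontinuity`
#'   (`NA` when a side has fewer than `k` usable windows), `k`, `n_left`,
#'   `n_right`.
#' @export
junction_discontinuities <- function(profile, layout, k = 3L) {
  stopifnot(inherits(profile, "window_profile"),
            inherits(layout, "assembly_layout"), k >= 1L)
  object <- profile$seqid[1L]
  if (!object %in% layout$object)
    stop("profile sequence id '", object, "' does not match any layout ",
         "object (", paste(unique(layout$object), collapse = ", "), ")",
         call. = FALSE)
  sc <- .layout_scaffolds(layout, object)
  n <- nrow(sc)
  if (n < 2L) {
    out <- data.frame(object = character(0), junction_pos = integer(0),
                      left_scaffold = character(0),
                      right_scaffold = character(0),
                      discontinuity = numeric(0), k = integer(0),
                      n_left = integer(0), n_right = integer(0))
    return(structure(out, class = c("junction_scores", "data.frame")))
  }
  idx <- lapply(seq_len(n),
                function(i) .windows_within(profile, sc$start[i], sc$end[i]))
  vals <- profile$value
  out <- data.frame(
    object = object,
    junction_pos = sc$end[-n],
    left_scaffold = sc$component[-n],
    right_scaffold = sc$component[-1L],
    discontinuity = vapply(seq_len(n - 1L), function(i)
      .junction_disc(vals, idx[[i]], idx[[i + 1L]], k), numeric(1)),
    k = as.integer(k),
    n_left = vapply(idx[-n], function(i) sum(!is.na(vals[i])), integer(1)),
    n_right = vapply(idx[-1L], function(i) sum(!is.na(vals[i])), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("junction_scores", "data.frame"))
}

#' Default flip-suggestion threshold for a profile
#'
#' A robust noise scale: 4 times the median absolute successive-window
#' difference of the profile. An orientation flip is only suggested when the
#' junction-score improvement exceeds this. The multiplier places the
#' threshold at roughly three noise standard deviations of the improvement
#' statistic for an unflipped scaffold (see the methods vignette for the
#' derivation), keeping false suggestions rare while leaving genuine
#' gradient breaks — typically many times the single-window noise — well
#' above it.
#'
#' @param profile A `window_profile`.
#' @return A non-negative number on the profile's value scale.
#' @export
flip_threshold <- function(profile) {
  d <- abs(diff(profile$value))
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(Inf)
  4 * median(d)
}

#' Evaluate reversing one scaffold's orientation
#'
#' Scores a scaffold by the sum of its (up to two) adjacent junction
#' discontinuities, then re-scores after reversing the order of the
#' scaffold's windows — which is exactly what a sequence-level reverse
#' complement does to any strand-symmetric profile (binding energy, GC, or
#' symmetrized delta*), so the sequence is never re-read. The flip is
#' suggested when the improvement (current minus flipped score) exceeds the
#' threshold.
#'
#' Scaffolds with fewer than `k` fully contained windows return an
#' insufficient-resolution result; those with fewer than `2k` are evaluated
#' but flagged low-confidence and never suggested. Windows straddling the
#' scaffold's ends belong to neither side and are excluded from both
#' evaluations.
#'
#' @inheritParams junction_discontinuities
#' @param scaffold_id Component id of the scaffold to evaluate.
#' @param threshold Improvement needed to suggest the flip; default
#'   [flip_threshold()] of the profile.
#' @return A one-row data frame of class `flip_suggestion`: `scaffold_id`,
#'   `n_windows`, `score_current`, `score_flipped`, `improvement`,
#'   `threshold`, `suggested`, `low_confidence`, `flag`.
#' @export
evaluate_flip <- function(profile, layout, scaffold_id, k = 3L,
                          threshold = NULL) {
  stopifnot(inherits(profile, "window_profile"),
            inherits(layout, "assembly_layout"), k >= 1L)
  metric <- attr(profile, "metric")
  if (!metric %in% c("binding_energy", "gc_fraction", "delta_star"))
    stop("flip evaluation requires a strand-symmetric metric; got '",
         metric, "'", call. = FALSE)
  object <- profile$seqid[1L]
  sc <- .layout_scaffolds(layout, object)
  i <- match(scaffold_id, sc$component)
  if (is.na(i))
    stop("scaffold '", scaffold_id, "' not found in layout for object '",
         object, "'", call. = FALSE)
  if (is.null(threshold)) threshold <- flip_threshold(profile)
  idx <- lapply(seq_len(nrow(sc)),
                function(j) .windows_within(profile, sc$start[j], sc$end[j]))
  own <- idx[[i]]
  mk <- function(score_current = NA_real_, score_flipped = NA_real_,
                 flag = "ok", suggested = FALSE, low_confidence = FALSE) {
    structure(data.frame(
      scaffold_id = scaffold_id, n_windows = length(own),
      score_current = score_current, score_flipped = score_flipped,
      improvement = score_current - score_flipped, threshold = threshold,
      suggested = suggested, low_confidence = low_confidence, flag = flag,
      metric = metric, stringsAsFactors = FALSE
    ), class = c("flip_suggestion", "data.frame"))
  }
  if (length(own) < k) return(mk(flag = "insufficient_windows"))
  low_conf <- length(own) < 2L * k
  score <- function(values) {
    parts <- c(
      if (i > 1L) .junction_disc(values, idx[[i - 1L]], own, k),
      if (i < nrow(sc)) .junction_disc(values, own, idx[[i + 1L]], k)
    )
    parts <- parts[!is.na(parts)]
    if (length(parts) == 0L) NA_real_ else sum(parts)
  }
  vals <- profile$value
  cur <- score(vals)
  flipped_vals <- vals
  flipped_vals[own] <- rev(vals[own])
  flp <- score(flipped_vals)
  if (is.na(cur) || is.na(flp))
    return(mk(cur, flp, flag = "missing_junction_windows",
              low_confidence = low_conf))
  suggested <- (cur - flp) > threshold && !low_conf
  mk(cur, flp, flag = "ok", suggested = suggested, low_confidence = low_conf)
}

#' Evaluate flips for every scaffold on an object
#'
#' Convenience wrapper running [evaluate_flip()] over all scaffold
#' placements of the profiled object with a shared threshold.
#'
#' @inheritParams evaluate_flip
#' @return A data frame with one `flip_suggestion` row per scaffold.
#' @export
suggest_flips <- function(profile, layout, k = 3L, threshold = NULL) {
  object <- profile$seqid[1L]
  sc <- .layout_scaffolds(layout, object)
  if (is.null(threshold)) threshold <- flip_threshold(profile)
  rows <- lapply(sc$component, function(id)
    evaluate_flip(profile, layout, id, k = k, threshold = threshold))
  out <- do.call(rbind, rows)
  structure(out, class = c("flip_suggestion", "data.frame"))
}

#' Per-region summary statistics of a profile
#'
#' Splits the profiled sequence at the given boundary positions and reports
#' the mean, sample standard deviation (n-1), and window count of the
#' profile in each region. Windows are assigned to the region containing
#' their midpoint; missing windows are excluded. Typical use: contrasting
#' euchromatic arms against the pericentromere.
#'
#' @param profile A `window_profile`.
#' @param boundaries Sorted base positions strictly inside the sequence.
#' @return A data frame with `region`, `start`, `end`, `n`, `mean`, `sd`
#'   (an empty region is reported with `n = 0`).
#' @export
region_stats <- function(profile, boundaries) {
  stopifnot(inherits(profile, "window_profile"))
  len <- max(profile$end)
  boundaries <- sort(as.numeric(boundaries))
  if (any(boundaries <= 0 | boundaries >= len))
    stop("boundaries must lie strictly inside (0, ", len, ")", call. = FALSE)
  breaks <- c(0, boundaries, len)
  mid <- (profile$start + profile$end) / 2
  region <- findInterval(mid, breaks, rightmost.closed = TRUE)
  out <- data.frame(
    region = seq_len(length(breaks) - 1L),
    start = breaks[-length(breaks)],
    end = breaks[-1L]
  )
  out$n <- vapply(out$region, function(r)
    sum(region == r & !is.na(profile$value)), integer(1))
  out$mean <- vapply(out$region, function(r) {
    v <- profile$value[region == r]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  out$sd <- vapply(out$region, function(r) {
    v <- profile$value[region == r]
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else sd(v)
  }, numeric(1))
  out
}
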