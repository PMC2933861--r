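# Synthetic chromosomes with the compositional architecture of a
# repeat-dense plant genome, plus scaffold shredding with known flips.
#
# The default chromosome emulates the soybean-like situation the package is
# built for: euchromatic arms (GC 0.32) flank a pericentromere whose
# repeat-free backbone (GC 0.33) is increasingly occupied by GC-rich
# LTR-like elements (GC 0.39) toward the middle, giving a composite
# pericentromeric GC near 0.37 and — crucially — smooth binding-energy /
# GC gradients on the pericentromere flanks. A CG-enriched ~91 bp satellite
# monomer is tandem-arrayed at the chromosome midpoint, producing a
# localized delta* peak distinct from the broad energy peak. All regions
# share a CpG-depleted background dinucleotide bias (rho*_CG 0.54,
# rho*_CC/GG 1.21) so the satellite's contrast (rho*_CG 2.85, rho*_CC/GG
# 0.567) yields a delta* excursion of roughly
# (|2.85-0.54| + 2*|0.567-1.21|)/16 ~ 0.22 over array windows.

#' Specification for a synthetic chromosome
#'
#' Defaults follow the compositional facts the generator is meant to
#' emulate; see the package vignette for the reasoning behind each number.
#' Lengths are in bases.
#'
#' @param arm_length Length of each euchromatic arm (default 5 Mb).
#' @param arm_gc GC fraction of the arms (default 0.32).
#' @param peri_length Pericentromere length (default 5 Mb).
#' @param peri_background_gc GC of the repeat-free pericentromeric backbone
#'   (default 0.33).
#' @param background_bias Dinucleotide odds-ratio bias shared by all
#'   backgrounds (default CpG-depleted: CG 0.54, CC/GG 1.21).
#' @param ltr_gc GC of LTR-like elements (default 0.39).
#' @param ltr_length Element length (default 1000; solo-LTR scale).
#' @param ltr_peak_coverage Element coverage at the pericentromere core
#'   (default 0.9).
#' @param ltr_ramp_fraction Fraction of the pericentromere, at each end,
#'   over which coverage ramps linearly from 0 to the peak (default 0.26).
#' @param satellite_length Total satellite array length (default 200 kb),
#'   placed at the pericentromere midpoint; 0 disables the array.
#' @param monomer_length,monomer_gc,monomer_bias Satellite monomer length
#'   (default 91), GC (default 0.42), and dinucleotide bias targets
#'   (default CG 2.85, CC/GG 0.567).
#' @param satellite_divergence Per-base substitution rate applied to the
#'   arrayed copies (default 0.05).
#' @param name Sequence id of the emitted chromosome (default `"chrS"`).
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(arm_length = 5e6, arm_gc = 0.32,
                        peri_length = 5e6, peri_background_gc = 0.33,
                        background_bias = c(CG = 0.54, CC = 1.21, GG = 1.21),
                        ltr_gc = 0.39, ltr_length = 1000L,
                        ltr_peak_coverage = 0.9, ltr_ramp_fraction = 0.26,
                        satellite_length = 200000L, monomer_length = 91L,
                        monomer_gc = 0.42,
                        monomer_bias = c(CG = 2.85, CC = 0.567, GG = 0.567),
                        satellite_divergence = 0.05, name = "chrS") {
  spec <- list(
    arm_length = as.integer(arm_length), arm_gc = arm_gc,
    peri_length = as.integer(peri_length),
    peri_background_gc = peri_background_gc,
    background_bias = background_bias, ltr_gc = ltr_gc,
    ltr_length = as.integer(ltr_length),
    ltr_peak_coverage = ltr_peak_coverage,
    ltr_ramp_fraction = ltr_ramp_fraction,
    satellite_length = as.integer(satellite_length),
    monomer_length = as.integer(monomer_length), monomer_gc = monomer_gc,
    monomer_bias = monomer_bias,
    satellite_divergence = satellite_divergence, name = name
  )
  with(spec, {
    stopifnot(arm_length > 0, peri_length > 0, ltr_length > 0,
              monomer_length > 0, satellite_length >= 0)
    for (g in c(arm_gc, peri_background_gc, ltr_gc, monomer_gc))
      if (g <= 0 || g >= 1) stop("GC targets must lie in (0, 1)",
                                 call. = FALSE)
    if (ltr_peak_coverage < 0 || ltr_peak_coverage > 1)
      stop("ltr_peak_coverage must lie in [0, 1]", call. = FALSE)
    if (ltr_ramp_fraction < 0 || ltr_ramp_fraction > 0.5)
      stop("ltr_ramp_fraction must lie in [0, 0.5]", call. = FALSE)
    if (satellite_length > peri_length)
      stop("satellite array does not fit in the pericentromere",
           call. = FALSE)
    if (satellite_divergence < 0 || satellite_divergence >= 1)
      stop("satellite_divergence must lie in [0, 1)", call. = FALSE)
  })
  structure(spec, class = "genome_spec")
}

## LTR-like element coverage at a relative position x in [0, 1) of the
## pericentromere: linear ramps at both ends, flat core.
.ltr_coverage <- function(x, ramp, peak) {
  ifelse(x < ramp, peak * x / ramp,
         ifelse(x > 1 - ramp, peak * (1 - x) / ramp, peak))
}

#' Generate a CG-enriched satellite monomer
#'
#' Samples monomers from a Markov chain built for the requested GC and
#' dinucleotide bias until one shows the wanted composition directionally
#' (rho*_CG clearly above 1, rho*_CC/GG clearly below 1) with a realized GC
#' within 0.05 of the target — a short monomer realizes its targets noisily,
#' so candidates are screened; the GC constraint keeps the arrayed
#' satellite from dragging regional GC off its own target. Deterministic
#' given the RNG state or `seed`.
#'
#' @inheritParams genome_spec
#' @param length Monomer length (default 91).
#' @param gc Monomer GC target (default 0.42).
#' @param bias Dinucleotide odds-ratio targets (default CG 2.85, CC/GG
#'   0.567).
#' @param seed Optional seed.
#' @param max_tries Candidates to screen before giving up (default 200).
#' @return A character string of `length` bases.
#' @export
satellite_monomer <- function(length = 91L, gc = 0.42,
                              bias = c(CG = 2.85, CC = 0.567, GG = 0.567),
                              seed = NULL, max_tries = 200L) {
  chain <- markov_from_targets(gc, bias)
  with_seed_opt(seed, {
    for (i in seq_len(max_tries)) {
      cand <- int_to_seq(.sample_chain(length, chain))
      counts <- count_dinucleotides(cand)
      gc_real <- sum(counts$mono[c("C", "G")]) / counts$informative_length
      if (abs(gc_real - gc) > 0.05) next
      sig <- tryCatch(rho_star(counts), error = function(e) NULL)
      if (is.null(sig)) next
      ok <- all(sig$defined[c("CG", "CC", "GG")]) &&
        sig$rho[["CG"]] > 1.5 && mean(sig$rho[c("CC", "GG")]) < 0.9
      if (ok) return(cand)
    }
    stop("could not realize the monomer composition targets in ", max_tries,
         " tries", call. = FALSE)
  })
}

#' Generate a synthetic chromosome with ground truth
#'
#' Builds the chromosome described by a [genome_spec()]: Markov-background
#' arms and pericentromere, LTR-like element insertions on the
#' pericentromeric coverage ramp, and a mutated tandem satellite array at
#' the midpoint. Returns the sequence together with a truth table locating
#' every region, insertion, and the array — the ground truth against which
#' profile, repeat, and flip-evaluation behavior is validated.
#'
#' @param spec A `genome_spec`.
#' @param seed Optional integer seed; the same seed reproduces the output
#'   byte for byte.
#' @return A list of class `synthetic_genome` with `sequences` (named
#'   character vector of length 1) and `truth`: `regions` (data frame of
#'   labelled intervals: `arm_left`, `ramp_left`, `core`, `ramp_right`,
#'   `arm_right`), `satellite` (0-based half-open interval, or `NULL`),
#'   `monomer`, `insertions` (element intervals), and the `spec`.
#' @export
make_genome <- function(spec = genome_spec(), seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed_opt(seed, {
    bg_chain_arm <- markov_from_targets(spec$arm_gc, spec$background_bias)
    bg_chain_peri <- markov_from_targets(spec$peri_background_gc,
                                         spec$background_bias)
    ltr_chain <- markov_from_targets(spec$ltr_gc, spec$background_bias)

    arm_l <- .sample_chain(spec$arm_length, bg_chain_arm)
    peri <- .sample_chain(spec$peri_length, bg_chain_peri)
    arm_r <- .sample_chain(spec$arm_length, bg_chain_arm)

    ## LTR-like elements on an aligned grid of element-length bins; each bin
    ## is occupied independently with the local coverage probability, so a
    ## 50 kb window sees Binomial(window/ltr_length, coverage) occupancy.
    nbins <- spec$peri_length %/% spec$ltr_length
    centers <- ((seq_len(nbins) - 0.5) * spec$ltr_length) / spec$peri_length
    cov <- .ltr_coverage(centers, spec$ltr_ramp_fraction,
                         spec$ltr_peak_coverage)
    occupied <- which(runif(nbins) < cov)
    if (length(occupied) > 0L) {
      pool <- .sample_chain(length(occupied) * spec$ltr_length, ltr_chain)
      pos <- rep((occupied - 1L) * spec$ltr_length,
                 each = spec$ltr_length) +
        rep(seq_len(spec$ltr_length), times = length(occupied))
      peri[pos] <- pool
    }

    ## satellite array at the pericentromere midpoint, overwriting whatever
    ## is there (it stays one contiguous block)
    satellite <- NULL
    monomer <- NULL
    if (spec$satellite_length > 0L) {
      monomer <- satellite_monomer(spec$monomer_length, spec$monomer_gc,
                                   spec$monomer_bias)
      mono_int <- seq_to_int(monomer)
      arr <- rep_len(mono_int, spec$satellite_length)
      mut <- which(runif(spec$satellite_length) < spec$satellite_divergence)
      if (length(mut) > 0L) {
        arr[mut] <- ((arr[mut] - 1L +
                        sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
      }
      sat_rel <- as.integer(round(spec$peri_length / 2 -
                                    spec$satellite_length / 2))
      peri[sat_rel + seq_len(spec$satellite_length)] <- arr
      sat_start <- spec$arm_length + sat_rel
      satellite <- c(start = sat_start,
                     end = sat_start + spec$satellite_length)
    }

    chr <- int_to_seq(c(arm_l, peri, arm_r))
    A <- spec$arm_length
    P <- spec$peri_length
    R <- as.integer(round(spec$ltr_ramp_fraction * P))
    regions <- data.frame(
      label = c("arm_left", "ramp_left", "core", "ramp_right", "arm_right"),
      start = c(0L, A, A + R, A + P - R, A + P),
      end = c(A, A + R, A + P - R, A + P, A + P + spec$arm_length),
      stringsAsFactors = FALSE
    )
    insertions <- if (length(occupied) > 0L) {
      ins <- data.frame(start = A + (occupied - 1L) * spec$ltr_length)
      ins$end <- ins$start + spec$ltr_length
      if (!is.null(satellite)) {
        ins <- ins[ins$end <= satellite[["start"]] |
                     ins$start >= satellite[["end"]], , drop = FALSE]
      }
      rownames(ins) <- NULL
      ins
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    structure(
      list(
        sequences = setNames(chr, spec$name),
        truth = list(regions = regions, satellite = satellite,
                     monomer = monomer, insertions = insertions, spec = spec)
      ),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %s bases\n", names(x$sequences)[1L],
              format(nchar(x$sequences)[1L], big.mark = ",")))
  print.data.frame(x$truth$regions)
  if (!is.null(x$truth$satellite))
    cat(sprintf("satellite array: [%d, %d)\n", x$truth$satellite[["start"]],
                x$truth$satellite[["end"]]))
  invisible(x)
}

#' Specification for shredding a chromosome into scaffolds
#'
#' @param min_length,max_length Scaffold length bounds in bases (defaults
#'   0.5 and 2 Mb — ten to forty 50 kb windows).
#' @param fraction_flipped Probability that each scaffold is emitted
#'   reverse-complemented while the layout still records `+` (default 0.3).
#' @param gap_length N-gap inserted between consecutive scaffolds in the
#'   emitted object (default 100).
#' @param prefix Scaffold id prefix (default `"scaffold_"`).
#' @return A `shred_spec` object.
#' @export
shred_spec <- function(min_length = 5e5, max_length = 2e6,
                       fraction_flipped = 0.3, gap_length = 100L,
                       prefix = "scaffold_") {
  if (min_length > max_length)
    stop("min_length exceeds max_length", call. = FALSE)
  if (fraction_flipped < 0 || fraction_flipped > 1)
    stop("fraction_flipped must lie in [0, 1]", call. = FALSE)
  structure(list(min_length = as.numeric(min_length),
                 max_length = as.numeric(max_length),
                 fraction_flipped = fraction_flipped,
                 gap_length = as.integer(gap_length), prefix = prefix),
            class = "shred_spec")
}

#' Shred a chromosome into scaffolds with known orientation errors
#'
#' Cuts each sequence at random positions into scaffolds with lengths drawn
#' uniformly from the spec's bounds (the final scaffold absorbs the
#' remainder rather than fall below the minimum). A seeded subset is
#' reverse-complemented in the emitted object while the emitted layout
#' records `+` for every scaffold — i.e. the assembly's (partly wrong)
#' belief — and the truth table records which scaffolds are really flipped.
#' Scaffolds are joined by N-gaps of the specified length.
#'
#' @param sequences Named character vector, list, or `DNAStringSet` (or a
#'   `synthetic_genome`, whose sequences are used directly).
#' @param spec A [shred_spec()].
#' @param seed Optional integer seed.
#' @return A list of class `shredded_genome`: `objects` (named character
#'   vector of emitted pseudomolecules, same names as the input), `layout`
#'   (an `assembly_layout` with gap rows), and `truth` (data frame:
#'   `object`, `scaffold_id`, `object_start`, `object_end`, `source_start`,
#'   `source_end`, `flipped`).
#' @export
shred_genome <- function(sequences, spec = shred_spec(), seed = NULL) {
  stopifnot(inherits(spec, "shred_spec"))
  if (inherits(sequences, "synthetic_genome")) sequences <- sequences$sequences
  seqs <- as_seq_set(sequences)
  with_seed_opt(seed, {
    layout_rows <- list()
    truth_rows <- list()
    objects <- character(0)
    scaffold_counter <- 0L
    for (id in names(seqs)) {
      len <- nchar(seqs[[id]])
      if (len < 2 * spec$min_length)
        stop("sequence '", id, "' too short to shred at min_length ",
             spec$min_length, call. = FALSE)
      ## cut points
      lens <- numeric(0)
      pos <- 0
      repeat {
        l <- round(runif(1, spec$min_length, spec$max_length))
        if (pos + l + spec$min_length > len) {
          lens <- c(lens, len - pos)
          break
        }
        lens <- c(lens, l)
        pos <- pos + l
      }
      n <- length(lens)
      src_end <- cumsum(lens)
      src_start <- src_end - lens
      flipped <- runif(n) < spec$fraction_flipped
      pieces <- substring(seqs[[id]], src_start + 1, src_end)
      if (any(flipped))
        pieces[flipped] <- vapply(pieces[flipped], revcomp_chr, character(1),
                                  USE.NAMES = FALSE)
      gap <- strrep("N", spec$gap_length)
      objects[[id]] <- paste(pieces, collapse = gap)
      ids <- sprintf("%s%03d", spec$prefix, scaffold_counter + seq_len(n))
      scaffold_counter <- scaffold_counter + n
      obj_start <- src_start + (seq_len(n) - 1L) * spec$gap_length
      obj_end <- obj_start + lens
      for (i in seq_len(n)) {
        layout_rows[[length(layout_rows) + 1L]] <- data.frame(
          object = id, start = obj_start[i], end = obj_end[i],
          type = "sequence", component = ids[i], orientation = "+",
          gap_length = NA_integer_, stringsAsFactors = FALSE
        )
        if (i < n && spec$gap_length > 0L) {
          layout_rows[[length(layout_rows) + 1L]] <- data.frame(
            object = id, start = obj_end[i],
            end = obj_end[i] + spec$gap_length, type = "gap",
            component = NA_character_, orientation = NA_character_,
            gap_length = spec$gap_length, stringsAsFactors = FALSE
          )
        }
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        object = id, scaffold_id = ids, object_start = obj_start,
        object_end = obj_end, source_start = src_start,
        source_end = src_end, flipped = flipped, stringsAsFactors = FALSE
      )
    }
    structure(
      list(objects = objects,
           layout = new_assembly_layout(do.call(rbind, layout_rows)),
           truth = do.call(rbind, truth_rows)),
      class = "shredded_genome"
    )
  })
}

#' Reassemble a shredded genome using its truth table
#'
#' Reverse-complements the truly flipped scaffold slices of each emitted
#' object and drops the gaps, restoring the original chromosome byte for
#' byte — the round-trip guarantee of [shred_genome()].
#'
#' @param shredded A `shredded_genome`.
#' @return A named character vector of restored sequences.
#' @export
reassemble_genome <- function(shredded) {
  stopifnot(inherits(shredded, "shredded_genome"))
  out <- character(0)
  for (id in names(shredded$objects)) {
    tr <- shredded$truth[shredded$truth$object == id, , drop = FALSE]
    tr <- tr[order(tr$object_start), , drop = FALSE]
    pieces <- substring(shredded$objects[[id]], tr$object_start + 1,
                        tr$object_end)
    if (any(tr$flipped))
      pieces[tr$flipped] <- vapply(pieces[tr$flipped], revcomp_chr,
                                   character(1), USE.NAMES = FALSE)
    out[[id]] <- paste(pieces, collapse = "")
  }
  out
}
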