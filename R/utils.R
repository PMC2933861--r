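# Internal sequence helpers. The user-facing alphabet is {A,C,G,T,N} after
# uppercasing; anything else is rejected with the offending position so bad
# FASTA records are easy to track down.

.validate_chars <- function(s, what = "sequence") {
  bad <- regexpr("[^ACGTNacgtn]", s)
  if (bad > 0L) {
    stop(sprintf(
      "invalid character '%s' in %s at position %d (alphabet is A/C/G/T/N)",
      substr(s, bad, bad), what, as.integer(bad)
    ), call. = FALSE)
  }
  invisible(TRUE)
}

## Accepts a character scalar, DNAString, or length-1 DNAStringSet and
## returns an uppercase DNAString restricted to A/C/G/T/N.
as_dna <- function(sequence, what = "sequence") {
  if (is(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L)
      stop("expected a single sequence, got ", length(sequence), call. = FALSE)
    sequence <- sequence[[1L]]
  }
  if (is(sequence, "DNAString")) {
    s <- as.character(sequence)
  } else if (is.character(sequence) && length(sequence) == 1L) {
    s <- sequence
  } else {
    stop("sequence must be a single character string, DNAString, or ",
         "length-1 DNAStringSet", call. = FALSE)
  }
  .validate_chars(s, what)
  DNAString(toupper(s))
}

## Accepts a (named) character vector, DNAStringSet, or list of sequences and
## returns a named character vector of validated, uppercased sequences.
as_seq_set <- function(sequences, what = "sequence") {
  if (is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is(sequences, "DNAString")) {
    out <- as.character(sequences)
  } else if (is.list(sequences)) {
    out <- vapply(sequences, function(x) as.character(as_dna(x)), character(1))
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    stop("sequences must be a character vector, list, or DNAStringSet",
         call. = FALSE)
  }
  if (length(out) == 0L) stop("no sequences given", call. = FALSE)
  for (i in seq_along(out)) {
    .validate_chars(out[[i]], sprintf("%s %d", what, i))
  }
  out <- toupper(out)
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- if (length(out) == 1L) "seq1" else
      paste0("seq", seq_along(out))
  }
  out
}

## integer codes 1..4 for A,C,G,T; 0 for N (already-validated input only)
.CODE_LOOKUP <- local({
  tab <- integer(256L)
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab
})

seq_to_int <- function(s) {
  .CODE_LOOKUP[as.integer(charToRaw(s)) + 1L]
}

int_to_seq <- function(v) {
  rawToChar(charToRaw("ACGT")[v])
}

revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

## run code under a fixed seed without disturbing the caller's RNG stream;
## seed = NULL means "use the current stream"
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
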