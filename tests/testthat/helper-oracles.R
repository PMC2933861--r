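# Independent brute-force oracles. These deliberately share no code with the
# package internals: counting walks the sequence character by character,
# matching compares characters at every offset, clustering takes graph
# components of the pairwise gap relation.

random_dna <- function(len, n_fraction = 0) {
  if (len == 0L) return("")
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, len, replace = TRUE)
  if (n_fraction > 0) {
    nn <- rbinom(1, len, n_fraction)
    if (nn > 0) s[sample.int(len, nn)] <- "N"
  }
  paste(s, collapse = "")
}

## character-by-character dinucleotide counting
oracle_counts <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  mono <- setNames(integer(4), c("A", "C", "G", "T"))
  dinucs <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                   rep(c("A", "C", "G", "T"), times = 4))
  dinuc <- setNames(integer(16), dinucs)
  for (i in seq_along(chars)) {
    if (chars[i] %in% names(mono)) mono[chars[i]] <- mono[chars[i]] + 1L
    if (i > 1) {
      pair <- paste0(chars[i - 1], chars[i])
      if (pair %in% dinucs) dinuc[pair] <- dinuc[pair] + 1L
    }
  }
  list(mono = mono, dinuc = dinuc, informative = sum(mono))
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## identity of an ungapped alignment at one offset (1-based start)
oracle_identity_at <- function(genome_chars, pat_chars, start) {
  L <- length(pat_chars)
  sub <- genome_chars[start:(start + L - 1)]
  sum(sub == pat_chars) / L
}

## full scan at every offset on both strands, then greedy same-strand
## non-maximum suppression by identity (ties to the left)
oracle_hits <- function(genome, monomer, min_identity) {
  gch <- strsplit(genome, "")[[1]]
  L <- nchar(monomer)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") monomer else oracle_revcomp(monomer)
    pch <- strsplit(pat, "")[[1]]
    cand <- data.frame(start = integer(0), identity = numeric(0))
    for (st in seq_len(length(gch) - L + 1)) {
      id <- oracle_identity_at(gch, pch, st)
      if (id >= min_identity - 1e-12)
        cand <- rbind(cand, data.frame(start = st - 1L, identity = id))
    }
    if (nrow(cand) == 0) next
    ord <- order(-cand$identity, cand$start)
    keep <- rep(FALSE, nrow(cand))
    acc <- numeric(0)
    for (i in ord) {
      if (length(acc) == 0 || all(abs(acc - cand$start[i]) >= L)) {
        keep[i] <- TRUE
        acc <- c(acc, cand$start[i])
      }
    }
    kept <- cand[keep, , drop = FALSE]
    out[[strand]] <- data.frame(start = kept$start, strand = strand,
                                identity = kept$identity)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(start = integer(0),
                                      strand = character(0),
                                      identity = numeric(0)))
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## single-linkage clusters as connected components of the pairwise
## |start_i - start_j| <= threshold graph (igraph), arrays need >= 2 members
oracle_clusters <- function(starts, ends, threshold) {
  n <- length(starts)
  adj <- abs(outer(starts, starts, "-")) <= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 2) next
    out[[length(out) + 1]] <- data.frame(
      start = min(starts[idx]), end = max(ends[idx]),
      hit_count = length(idx)
    )
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      hit_count = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## energy linearity oracle: weighted mean of table values by oracle counts
oracle_energy <- function(s, dg) {
  cn <- oracle_counts(s)
  d <- sum(cn$dinuc)
  if (d == 0) return(NA_real_)
  sum(cn$dinuc * dg[names(cn$dinuc)]) / d
}

## build a signature_vector directly (for algebraic delta* checks)
make_sig <- function(rho, symmetrized = TRUE) {
  scaffsig:::new_signature_vector(rho, rep(TRUE, 16), symmetrized, NA_real_)
}

## small, quick synthetic chromosome used across module tests
small_spec <- function(...) {
  genome_spec(arm_length = 4e5, peri_length = 4e5, satellite_length = 4e4,
              ltr_length = 500L, ...)
}

## mutate a fraction of positions to a different base (per-position rate)
mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  idx <- which(runif(length(chars)) < rate)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

## mutate exactly k positions of a sequence
mutate_k <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  idx <- sample.int(length(chars), k)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}
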