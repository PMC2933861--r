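# First-order Markov backgrounds with controllable GC and dinucleotide bias.
#
# Construction: the stationary distribution pi is fixed by the GC target
# (pi_C = pi_G = gc/2, pi_A = pi_T = (1-gc)/2). The target dinucleotide
# joint distribution starts from independence, outer(pi, pi), multiplied by
# user odds-ratio biases (e.g. CG = 0.54 for plant-style CpG depletion), and
# is projected by iterative proportional fitting (IPF) so that both margins
# equal pi. The transition matrix P(y|x) = J[x,y]/pi[x] then has stationary
# distribution pi exactly, and the realized dinucleotide odds ratios
# approximate the requested biases. This makes dinucleotide structure
# tunable independently of GC, which is what separates delta* peaks from
# binding-energy peaks in generated genomes.

#' Build a first-order Markov chain from GC and dinucleotide-bias targets
#'
#' @param gc Target GC fraction in (0, 1).
#' @param bias Named numeric vector of dinucleotide odds-ratio multipliers
#'   relative to independence (names from the 16 dinucleotides; values must
#'   be positive). Strand symmetry is enforced: a bias given for XY is
#'   applied to revcomp(XY) as well, and conflicting values for a
#'   reverse-complement pair are an error.
#' @param tol,max_iter IPF convergence controls.
#' @return A list with `P` (4x4 transition matrix, rows A/C/G/T), `pi`
#'   (stationary distribution), and `joint` (the fitted dinucleotide joint).
#' @export
markov_from_targets <- function(gc, bias = NULL, tol = 1e-12,
                                max_iter = 500L) {
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("gc must lie in (0, 1)", call. = FALSE)
  pi <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
  B <- matrix(1, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  if (length(bias) > 0L) {
    if (is.null(names(bias)) || !all(names(bias) %in% DINUCS))
      stop("bias names must be dinucleotides (", paste(DINUCS, collapse = " "),
           ")", call. = FALSE)
    if (any(!is.finite(bias) | bias <= 0))
      stop("infeasible bias: multipliers must be positive and finite",
           call. = FALSE)
    seen <- setNames(rep(NA_real_, 16L), DINUCS)
    for (d in names(bias)) {
      rc <- RC_DINUC[[d]]
      for (m in unique(c(d, rc))) {
        if (!is.na(seen[m]) && seen[m] != bias[[d]])
          stop("conflicting bias for reverse-complement pair ", d, "/", rc,
               call. = FALSE)
        seen[m] <- bias[[d]]
        B[substr(m, 1, 1), substr(m, 2, 2)] <- bias[[d]]
      }
    }
  }
  J <- outer(pi, pi) * B
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- J * (pi / rowSums(J))
    J <- t(t(J) * (pi / colSums(J)))
    if (max(abs(rowSums(J) - pi)) < tol && max(abs(colSums(J) - pi)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("infeasible bias specification: IPF did not converge", call. = FALSE)
  P <- J / rowSums(J)
  list(P = P, pi = pi, joint = J)
}

## Sample n bases from a chain built by markov_from_targets(), as an integer
## vector (1..4 = A,C,G,T). Randomness flows through R's RNG.
.sample_chain <- function(n, chain) {
  cpp_markov_sample(as.integer(n), chain$pi, chain$P)
}

#' Generate i.i.d. random windows
#'
#' Draws `n` independent sequences of `window_size` i.i.d. bases with the
#' given composition — the null model used to calibrate the rho*
#' over-/under-representation thresholds (see [signature_thresholds()]).
#'
#' @param n Number of windows (0 gives an empty character vector).
#' @param window_size Bases per window.
#' @param composition Base probabilities in A, C, G, T order (default
#'   uniform); must sum to 1.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A character vector of `n` sequences.
#' @export
random_windows <- function(n, window_size,
                           composition = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                           seed = NULL) {
  stopifnot(n >= 0, window_size >= 1)
  if (abs(sum(composition) - 1) > 1e-8)
    stop("composition must sum to 1", call. = FALSE)
  if (n == 0L) return(character(0))
  with_seed_opt(seed, {
    draws <- sample.int(4L, n * window_size, replace = TRUE,
                        prob = composition)
    vapply(seq_len(n), function(i) {
      int_to_seq(draws[seq.int((i - 1L) * window_size + 1L,
                               i * window_size)])
    }, character(1))
  })
}
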