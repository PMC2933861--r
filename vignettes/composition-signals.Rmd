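---
title: "Genome composition signals for assembly quality control"
author: "scaffsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome composition signals for assembly quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffsig)
```

## The problem

Chromosome pseudomolecules are built by ordering and orienting whole-genome
shotgun scaffolds. Genetic markers do most of that work in euchromatic arms,
where recombination is frequent, but marker resolution collapses in
centromeric and pericentromeric regions. scaffsig implements two
sequence-intrinsic signals that remain informative there — the dinucleotide
signature and the nearest-neighbor (NN) DNA binding energy — together with
the scaffold-junction reasoning they enable: a large-scale compositional
gradient should run smoothly across a correctly assembled region, so an
abrupt break located precisely at a scaffold boundary points at a placement
or orientation error.

## The two signals

**Dinucleotide signature.** For nucleotide frequencies $f_X$ and overlapping
dinucleotide frequencies $f_{XY}$, the signature of dinucleotide $XY$ is the
odds ratio

$$\rho_{XY} = \frac{f_{XY}}{f_X\,f_Y},$$

near 1 for compositionally random DNA. Because genomic DNA is double
stranded, all counts are pooled with their reverse complements before
frequencies are formed (mononucleotides A with T, C with G; dinucleotides
$XY$ with $\widehat{XY}$), giving the symmetrized $\rho^*_{XY}$ with
$\rho^*_{XY} = \rho^*_{\widehat{XY}}$ exactly. The distance between two
signature vectors is

$$\delta^*(f,g) = \frac{1}{16}\sum_{XY}\left|\rho^*_{XY}(f) -
\rho^*_{XY}(g)\right|,$$

one sixteenth of an L1 norm — non-negative, symmetric, triangle-inequality
obedient. `delta_profile()` scans a chromosome in non-overlapping 50 kb
windows and reports each window's $\delta^*$ against the genome-wide
signature from `genome_signature()`. For random DNA an individual
$\rho^*_{XY}$ outside (0.78, 1.23) occurs less than once in a thousand
windows (`signature_thresholds()`); the test suite re-derives that tail on
10,000 simulated uniform 50 kb windows.

**Binding energy.** `default_energy_table()` carries the consensus NN free
energies of binding at 37 °C: ten unique reverse-complement pair parameters
(AA/TT −1.00 through GC −2.24 kcal/mol) expanded to all 16 dinucleotides.
`window_energy()` sums the table value of every counted overlapping
dinucleotide and divides by their number; `energy_profile()` does so per 50
kb window. Values are reported as positive magnitudes by default (the
conventional plotting scale); a flag restores the signed means.

**N handling (both signals).** Bases other than A/C/G/T contribute to no
count, and a dinucleotide is counted only when its two bases are physically
adjacent and informative — no pair is ever formed across an N run, so AGP
assembly gaps cannot create artifactual dinucleotides. Soft-masked
(lowercase) input is uppercased and counted; no masking rule is applied.
Windows are 0-based half-open; a window with fewer informative bases than
half the window size, or with any undefined $\rho^*$ entry, yields a
missing value rather than a number, and the terminal partial window is
retained but flagged.

## Junction scores and orientation flips

`junction_discontinuities()` scores every junction between consecutive
scaffolds as the absolute difference between the mean profile value of the
k (default 3) windows nearest the junction on each side, using only windows
fully contained in the flanking scaffold — windows straddling the junction
or an intervening gap are excluded, and gaps do not create junctions of
their own.

`evaluate_flip()` models reversing a scaffold by reversing the order of its
windows. For any strand-symmetric metric (binding energy, GC, symmetrized
$\delta^*$) this is exactly what reverse-complementing the sequence would
produce, so the sequence is never re-read; non-symmetric metrics are
refused. The flip is suggested when the improvement in the scaffold's
summed junction scores exceeds a threshold.

**Threshold choice.** The default threshold is 4× the median absolute
successive-window difference of the profile. The derivation, done before
any recovery experiment was run: write the four k-window means around an
unflipped scaffold as A (left neighbor), B and D (the scaffold's two ends),
C (right neighbor). Reversing the window order swaps B and D, so the
improvement is $(|A-B|+|C-D|) - (|A-D|+|C-B|)$, which the triangle
inequality bounds by $2|A-C|$ — noise scale $\approx 2\sigma/\sqrt{k}
\approx 1.6\sigma$ at $k=3$, where $\sigma$ is the single-window noise. The
median absolute successive difference is $\approx 0.95\sigma$, so 4× puts
the threshold near three standard deviations of the improvement statistic,
while a genuine orientation error in a gradient produces an improvement of
roughly twice the profile-level difference across the scaffold — typically
many multiples of $\sigma$. A 2× multiplier would sit inside the noise of
the improvement statistic and flood the output with false suggestions.

Two structural caveats are worth knowing. A scaffold whose two end levels
are equal (a palindromic interior, or a scaffold capping a local extremum
such as the centromere, where $B+D-A-C$ is swap-invariant) is flip-inert:
the statistic is exactly zero even if the scaffold is reversed. And
scaffolds with fewer than k fully contained windows return an
insufficient-resolution result, while those with fewer than 2k are
evaluated but flagged low-confidence and never suggested. Orientation is
the only thing evaluated; reordering scaffolds requires external evidence
(markers, physical maps) and is out of scope.

## Satellite arrays

`find_monomer_hits()` scans every offset of both strands for full-length
ungapped alignments of a monomer (~91 bp for the centromeric satellite this
package is motivated by) at ≥ 90% identity, reducing overlapping same-strand
hits to local identity maxima. At that identity over ~91 bp an indel-free
scan recovers satellite arrays without a gapped aligner; the exhaustive
early-abort scan does expected O(1) work per offset, and the test suite
holds it to 100% agreement with a per-offset oracle and with
`Biostrings::matchPattern`. `cluster_arrays()` chains hits whose starts lie
within 10 monomer lengths (910 bp for a 91-mer) into arrays of ≥ 2 hits,
strands pooled. `detect_tandem_periods()` provides a simple periodicity
scan: the fraction of positions matching at each lag, with a
dominant-length rule — any i.i.d.-mutated tandem array scores equally, up
to sampling noise, at the monomer length and at its multiples, so the
smallest divisor of the top-scoring period within three standard errors of
the top score is promoted to rank 1, mirroring how a consensus-based tandem
finder reports the shortest dominant length.

## The synthetic genome: what it emulates

`make_genome()` builds the ground-truth world for validation. The default
chromosome (15 Mb total) encodes the compositional architecture of a
repeat-dense plant chromosome:

| component | length | GC | dinucleotide bias ($\rho^*$ targets) |
|---|---|---|---|
| euchromatic arms (×2) | 5 Mb each | 0.32 | CG 0.54, CC/GG 1.21 |
| pericentromere backbone | 5 Mb | 0.33 | CG 0.54, CC/GG 1.21 |
| LTR-like elements | 1 kb each | 0.39 | CG 0.54, CC/GG 1.21 |
| satellite monomer | 91 bp | 0.42 | CG 2.85, CC/GG 0.567 |

The GC values and $\rho^*$ contrasts are the published genome-scale facts
the generator is meant to reproduce: euchromatin at 0.32, heterochromatin
at 0.37 overall but 0.33 with repeats removed, LTR retrotransposons at
0.39, a genome-wide CpG-depleted background, and a satellite monomer whose
CG enrichment and CC/GG depletion predict a $\delta^*$ excursion of about
$(|2.85-0.54| + 2\,|0.567-1.21|)/16 \approx 0.22$ over array windows — the
order of the observed centromeric peak. The monomer's GC is a free choice
(no reference monomer sequence is available); 0.42 is in the range of
CG-enriched centromeric satellites.

Backgrounds are first-order Markov chains, not i.i.d.: the stationary
distribution is pinned to the GC target and the dinucleotide joint is
fitted by iterative proportional fitting to the requested odds-ratio
biases, which makes dinucleotide structure tunable independently of GC —
necessary for $\delta^*$ peaks to be distinct from binding-energy peaks.
Sampling runs in compiled code through R's RNG, so a seed reproduces output
byte for byte.

LTR-like elements occupy an aligned grid of element-length bins, each bin
independently with the local target coverage: zero at the pericentromere
edges, ramping linearly over the first and last 26% of the region to a
0.9-coverage core. This trapezoid does two jobs: the mean coverage (0.666)
composites the backbone's 0.33 to the observed 0.37, and the ramps create
genuine ~1.3 Mb binding-energy gradients of the kind real pericentromeres
show — the terrain the flip-recovery experiment needs. The 1 kb element
length (solo-LTR scale rather than the 5–10 kb of intact elements) was
chosen a priori to keep window-level coverage variance small: a 50 kb
window holds ~50 bins, so the binomial coverage noise contributes only
~0.004 to window GC, keeping gradient steps well above window noise.

The satellite monomer is sampled from its biased chain and screened:
realized $\rho^*_{CG} > 1.5$, mean $\rho^*_{CC/GG} < 0.9$, and realized GC
within ±0.05 of target (a 91-mer realizes its composition targets noisily —
GC sd ≈ 0.05 — and the CG screen alone biases GC upward, enough to drag the
pericentromere composite off its ±0.01 contract). Copies are laid
head-to-tail over 200 kb at the chromosome midpoint with a 5% per-position
substitution rate, comfortably inside the 90% identity recovery band.

`shred_genome()` cuts the chromosome into scaffolds (uniform 0.5–2 Mb, ten
to forty windows), reverse-complements a seeded 30% in the emitted object
while the emitted AGP records `+` for all — the assembly's partly wrong
belief — and the truth table records reality. Reassembly per truth table
restores the source byte-exactly.

**What the generator does not emulate.** Real pericentromeres carry genes,
ribosomal arrays, and nested/fragmented transposons; element composition
here differs from the background only in GC; scaffold boundaries are clean
cuts rather than assembly artifacts; and there is no read-level error. A
green suite therefore shows the signals and the junction logic behave as
designed under the stated composition model — not that any particular real
assembly is correct.

## Validation experiments and their sizes

The acceptance-style tests (several minutes, one CPU) run at these sizes,
chosen to balance statistical resolution against test runtime:

- Null calibration: 10,000 i.i.d. uniform 50 kb windows; the observed
  frequency of any defined $\rho^*$ entry outside (0.78, 1.23) must be
  ≤ 0.001. (Uniform composition is used for the null; the original
  threshold derivation did not state its random-sequence model, and the
  generator exposes composition as a parameter.)
- Oracle agreement: 400 random sequences (lengths 0–5000, N fraction up to
  30%) for counting; a ~45 kb genome with planted 0–10-substitution copies
  for hit finding; 3000 random positions for clustering (the graph-component
  oracle is O(n²) in memory).
- One default 15 Mb chromosome for regional means and $\delta^*$ peak
  localization; a satellite-free 10 Mb chromosome for the energy–GC
  correlation (below); 50 seeded shredded chromosomes for flip recovery
  (≥ 90% of scaffolds flipped within gradient regions recovered, ≤ 5% false
  suggestions among unflipped scaffolds).

**Energy–GC correlation and the satellite caveat.** Over background and
LTR-gradient windows the windowed binding-energy magnitude and GC fraction
correlate at ≥ 0.999, reproducing the interchangeability observed at genome
scale on real data. Satellite-array windows, however, sit measurably off
the energy–GC line: the monomer's enriched CG/GC steps are the two most
stable stacks in the table, so an array binds ~0.04 kcal/mol/dinucleotide
more strongly than background of the same GC. On a 15 Mb chromosome where
the array is 1.3% of windows this drags the whole-chromosome correlation to
~0.986. Real shotgun assemblies underrepresent tandem arrays, so the
genome-wide correlation they exhibit is effectively the background one; the
correlation experiment accordingly runs on a satellite-free 10 Mb
chromosome, and the array's departure from the line is reported as what it
is — the thermodynamic face of the same compositional anomaly that the
$\delta^*$ profile detects.

## Numerical conventions and degenerate inputs

- Undefined $\rho^*$ entries (a component base frequency of zero) propagate
  as missing values, never 0 or infinity; `delta_star()` on vectors with
  undefined entries errors unless skip-and-renormalize is requested
  explicitly.
- `delta_star()` requires both vectors symmetrized the same way; windowed
  $\delta^*$ profiles always use symmetrized signatures (required for the
  window-reversal flip model to be exact).
- Sequences with fewer than 2 informative bases, or no countable adjacent
  pair, are degenerate-input errors for signatures; a window in the same
  state is simply missing.
- Energy tables must cover all 16 dinucleotides via valid
  reverse-complement pair labels; conflicting duplicate entries are errors.
- Region statistics use the sample (n−1) standard deviation; windows join
  the region containing their midpoint; empty regions are reported with
  n = 0 rather than dropped.
- AGP is validated to tile each object contiguously (1-based inclusive
  converted to 0-based half-open at the boundary); BED layouts must be
  non-overlapping. All internal coordinates are 0-based half-open.

## Known limitations

- The flip statistic cannot see orientation errors in compositionally flat
  terrain or at exact local extrema; it is a screen for gradient breaks,
  not a proof of orientation, and its suggestions should be weighed with
  marker and physical-map evidence.
- Monomer search is ungapped; a satellite with frequent indels would need a
  gapped aligner upstream, with hits fed to `cluster_arrays()` directly.
- The 0.78/1.23 single-entry thresholds are calibrated for ~50 kb windows;
  much smaller windows have wider nulls.
- `delta_profile()` recomputes window counts per call; profiles at multiple
  window sizes re-scan the sequence.
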