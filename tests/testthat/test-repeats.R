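# Monomer hit finding, array clustering, array signatures, periodicity.

make_monomer_fixture <- function(seed = 401) {
  set.seed(seed)
  random_dna(91)
}

test_that("exact tandem copies are all recovered at identity 1", {
  set.seed(402)
  monomer <- make_monomer_fixture()
  genome <- c(chr = paste0(random_dna(2000), strrep(monomer, 10),
                           random_dna(2000)))
  hits <- find_monomer_hits(genome, monomer)
  exact <- hits[hits$identity == 1 & hits$strand == "+", ]
  expect_gte(nrow(exact), 10L)
  expect_true(all(diff(exact$start[1:10]) == 91))
  expect_equal(attr(hits, "monomer_length"), 91L)
})

test_that("both strands are searched", {
  set.seed(403)
  monomer <- make_monomer_fixture()
  genome <- c(chr = paste0(random_dna(1000), monomer, random_dna(1000),
                           oracle_revcomp(monomer), random_dna(1000)))
  hits <- find_monomer_hits(genome, monomer)
  perfect <- hits[hits$identity == 1, ]
  expect_setequal(perfect$strand, c("+", "-"))
  expect_equal(perfect$start[perfect$strand == "+"], 1000L)
  expect_equal(perfect$start[perfect$strand == "-"], 2091L)
})

test_that("identity thresholding separates 8% from 15% divergence", {
  set.seed(404)
  monomer <- make_monomer_fixture()
  near <- vapply(1:5, function(i) mutate_k(monomer, 7L), character(1))
  far <- vapply(1:5, function(i) mutate_k(monomer, 14L), character(1))
  spacer <- function() random_dna(300)
  genome <- c(chr = paste0(
    spacer(), paste(vapply(near, function(m) paste0(m, spacer()),
                           character(1)), collapse = ""),
    paste(vapply(far, function(m) paste0(m, spacer()), character(1)),
          collapse = "")
  ))
  hits <- find_monomer_hits(genome, monomer, min_identity = 0.90)
  # 7 substitutions -> identity 84/91 = 0.923 kept; 14 -> 0.846 rejected
  expect_equal(sum(hits$identity >= 0.92), 5L)
  expect_true(all(hits$identity >= 0.90))
  expect_lte(nrow(hits), 6L)  # allow a chance background hit, none expected
})

test_that("hit finding matches the exhaustive oracle", {
  set.seed(405)
  monomer <- random_dna(30)
  copies <- c(monomer, mutate_k(monomer, 2L), mutate_k(monomer, 3L),
              oracle_revcomp(mutate_k(monomer, 1L)))
  genome_str <- paste0(random_dna(400), copies[1], random_dna(90), copies[2],
                       random_dna(11), copies[3], random_dna(200), copies[4],
                       random_dna(400))
  got <- find_monomer_hits(c(g = genome_str), monomer, min_identity = 0.9)
  want <- oracle_hits(genome_str, monomer, 0.9)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$identity, want$identity)
})

test_that("hit finding agrees with Biostrings matchPattern", {
  set.seed(406)
  monomer <- make_monomer_fixture()
  copies <- vapply(1:8, function(i) mutate_k(monomer, sample(0:9, 1)),
                   character(1))
  genome_str <- paste(c(random_dna(3000),
                        vapply(copies, function(m) paste0(m, random_dna(500)),
                               character(1))), collapse = "")
  got <- find_monomer_hits(c(g = genome_str), monomer, min_identity = 0.90)
  mp <- Biostrings::matchPattern(monomer, Biostrings::DNAString(genome_str),
                                 max.mismatch = 9, with.indels = FALSE)
  expect_setequal(got$start[got$strand == "+"],
                  BiocGenerics::start(mp) - 1L)
})

test_that("monomer validation rejects short or ambiguous queries", {
  expect_error(find_monomer_hits(c(g = random_dna(100)), "ACGT"),
               "at least 20")
  expect_error(find_monomer_hits(c(g = random_dna(100)),
                                 paste0(strrep("ACGT", 6), "N")),
               "N")
})

test_that("gap-rule clustering follows the threshold arithmetic", {
  hits <- data.frame(
    seqid = "chr", start = c(0L, 500L, 2000L),
    end = c(91L, 591L, 2091L), strand = "+", identity = 1
  )
  arrays <- cluster_arrays(hits, monomer_length = 91, max_gap_factor = 10)
  # 0 and 500 are within 910; 2000 is 1500 away -> singleton, discarded
  expect_equal(nrow(arrays), 1L)
  expect_equal(arrays$start, 0L)
  expect_equal(arrays$end, 591L)
  expect_equal(arrays$hit_count, 2L)

  all_close <- data.frame(seqid = "chr", start = seq(0L, 9000L, by = 900L),
                          end = seq(0L, 9000L, by = 900L) + 91L,
                          strand = "+", identity = 1)
  arr2 <- cluster_arrays(all_close, monomer_length = 91)
  expect_equal(nrow(arr2), 1L)
  expect_equal(arr2$hit_count, 11L)

  none <- cluster_arrays(hits[0, ], monomer_length = 91)
  expect_equal(nrow(none), 0L)
})

test_that("clustering matches a graph-component oracle and ignores order", {
  set.seed(407)
  starts <- sort(sample.int(500000L, 2500L))
  hits <- data.frame(seqid = "chr", start = starts, end = starts + 91L,
                     strand = sample(c("+", "-"), 2500L, replace = TRUE),
                     identity = runif(2500L, 0.9, 1))
  got <- cluster_arrays(hits, monomer_length = 91, max_gap_factor = 10)
  want <- oracle_clusters(hits$start, hits$end, 910)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$hit_count, want$hit_count)

  shuffled <- hits[sample.int(nrow(hits)), ]
  again <- cluster_arrays(shuffled, monomer_length = 91, max_gap_factor = 10)
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("array signatures contrast with the genome baseline", {
  # poly-A monomer array: rho*_AA == 2 closed form
  genome <- c(chr = paste0(random_dna(1000), strrep("A", 1000),
                           random_dna(1000)))
  sig <- array_signature(genome, list(seqid = "chr", start = 1000L,
                                      end = 2000L))
  expect_equal(sig$rho[["AA"]], 2)

  # array interval equal to the whole genome: delta* == 0 against baseline
  set.seed(408)
  g2 <- c(chr = random_dna(5000))
  whole <- array_signature(g2, list(seqid = "chr", start = 0L, end = 5000L))
  expect_equal(delta_star(whole, genome_signature(g2)), 0)

  expect_error(array_signature(g2, list(seqid = "chr", start = 0L,
                                        end = 6000L)), "outside")
})

test_that("periodicity scan finds exact and mutated periods", {
  set.seed(409)
  monomer <- make_monomer_fixture()
  exact <- strrep(monomer, 110)   # ~10 kb
  res <- detect_tandem_periods(exact, max_period = 200)
  expect_equal(res$period[1], 91L)
  expect_equal(res$score[1], 1.0)
  expect_equal(res$harmonic_of[res$period == 182], 91L)

  # i.i.d. sequence: every score near the 0.25 chance level
  rnd <- random_dna(10000)
  res_rnd <- detect_tandem_periods(rnd, max_period = 200)
  expect_lt(max(res_rnd$score), 0.30)
  expect_gt(min(res_rnd$score), 0.20)

  # per-position substitution rate r: adjacent copies match with probability
  # (1-r)^2 + r^2/3 = 0.8133 at r = 0.1
  mut <- mutate_seq(exact, 0.10)
  res_mut <- detect_tandem_periods(mut, max_period = 200)
  expect_equal(res_mut$period[1], 91L)
  expect_equal(res_mut$score[1], 0.9^2 + 0.1^2 / 3, tolerance = 0.03)

  expect_error(detect_tandem_periods(random_dna(100), max_period = 200),
               "too short")
})
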