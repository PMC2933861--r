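# Layout parsing, junction discontinuities, flip evaluation, region stats.

## profile fixture: values on a 1 kb grid for object "chr1"
grid_profile <- function(values, metric = "binding_energy", ws = 1000L) {
  n <- length(values)
  scaffsig:::new_window_profile(
    "chr1", seq(0L, (n - 1L)) * ws, seq_len(n) * ws, values,
    informative = rep(ws, n), metric = metric, window_size = ws, step = ws
  )
}

## layout fixture: scaffolds tiling chr1 at the given boundaries (bases)
tiling_layout <- function(bounds, ids = sprintf("S%d", seq_len(length(bounds) - 1L))) {
  n <- length(bounds) - 1L
  scaffsig:::new_assembly_layout(data.frame(
    object = "chr1", start = bounds[-length(bounds)], end = bounds[-1L],
    type = "sequence", component = ids, orientation = "+",
    gap_length = NA_integer_, stringsAsFactors = FALSE
  ))
}

test_that("AGP and BED layouts normalize to the same placements", {
  agp <- withr::local_tempfile(fileext = ".agp")
  writeLines(c(
    "# comment",
    "chr1\t1\t100\t1\tW\tscafA\t1\t100\t+",
    "chr1\t101\t200\t2\tN\t100\tscaffold\tyes\tpaired-ends",
    "chr1\t201\t300\t3\tW\tscafB\t1\t100\t-"
  ), agp)
  layA <- read_layout(agp)
  expect_s3_class(layA, "assembly_layout")
  expect_equal(layA$start, c(0L, 100L, 200L))
  expect_equal(layA$end, c(100L, 200L, 300L))
  expect_equal(layA$type, c("sequence", "gap", "sequence"))
  expect_equal(layA$component[c(1, 3)], c("scafA", "scafB"))
  expect_equal(layA$orientation[c(1, 3)], c("+", "-"))
  expect_equal(layA$gap_length[2], 100L)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tscafA\t0\t+",
               "chr1\t200\t300\tscafB\t0\t-"), bed)
  layB <- read_layout(bed)
  seqrows <- layA[layA$type == "sequence", c("object", "start", "end",
                                             "component", "orientation")]
  rownames(seqrows) <- NULL
  expect_equal(as.data.frame(layB[, names(seqrows)]), as.data.frame(seqrows))
})

test_that("malformed layouts are rejected with offending lines", {
  agp <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("chr1\t1\t100\t1\tW\tscafA\t1\t100\t+",
               "chr1\t50\t150\t2\tW\tscafB\t1\t101\t+"), agp)
  expect_error(read_layout(agp), "tile.*line")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tscafA\t0\t+",
               "chr1\t50\t150\tscafB\t0\t+"), bed)
  expect_error(read_layout(bed), "overlap")

  agp2 <- withr::local_tempfile(fileext = ".agp")
  writeLines("chr1\t1\t100\t1\tW\tscafA\t1\t100\t+", agp2)
  expect_error(read_layout(agp2, seq_lengths = c(chr1 = 50L)), "past")
})

test_that("AGP round-trips through write_agp", {
  agp <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("chr1\t1\t1000\t1\tW\tscafA\t1\t1000\t+",
               "chr1\t1001\t1100\t2\tN\t100\tscaffold\tyes\tpaired-ends",
               "chr1\t1101\t2100\t3\tW\tscafB\t1\t1000\t-"), agp)
  lay <- read_layout(agp)
  out <- withr::local_tempfile(fileext = ".agp")
  write_agp(lay, out)
  again <- read_layout(out)
  expect_equal(as.data.frame(again), as.data.frame(lay))
  # flips reverse the recorded orientation
  write_agp(lay, out, flip = "scafB")
  flipped <- read_layout(out)
  expect_equal(flipped$orientation[which(flipped$component == "scafB")], "+")
})

test_that("junction discontinuity is the step height of a piecewise profile", {
  prof <- grid_profile(c(rep(2, 10), rep(5, 10)))
  lay <- tiling_layout(c(0, 10000, 20000))
  js <- junction_discontinuities(prof, lay, k = 3)
  expect_equal(nrow(js), 1L)
  expect_equal(js$discontinuity, 3)
  expect_equal(js$left_scaffold, "S1")
  expect_equal(js$right_scaffold, "S2")
  expect_equal(js$junction_pos, 10000L)

  flat <- grid_profile(rep(1.5, 30))
  lay3 <- tiling_layout(c(0, 10000, 20000, 30000))
  js3 <- junction_discontinuities(flat, lay3, k = 3)
  expect_equal(js3$discontinuity, c(0, 0))
})

test_that("gaps between scaffolds do not create junctions of their own", {
  prof <- grid_profile(c(rep(2, 10), rep(5, 10)))
  lay <- scaffsig:::new_assembly_layout(data.frame(
    object = "chr1",
    start = c(0L, 9000L, 11000L), end = c(9000L, 11000L, 20000L),
    type = c("sequence", "gap", "sequence"),
    component = c("S1", NA, "S2"), orientation = c("+", NA, "+"),
    gap_length = c(NA, 2000L, NA), stringsAsFactors = FALSE
  ))
  js <- junction_discontinuities(prof, lay, k = 3)
  # one junction between the flanking scaffolds; the window overlapping the
  # gap (9000-11000 spans windows 10 and 11) is excluded from both sides
  expect_equal(nrow(js), 1L)
  expect_equal(js$left_scaffold, "S1")
  expect_equal(js$right_scaffold, "S2")
  expect_equal(js$discontinuity, 3)
})

test_that("junction scores shift-invariant, scale linearly, need k windows", {
  set.seed(301)
  vals <- rnorm(40, 1, 0.1)
  prof <- grid_profile(vals)
  lay <- tiling_layout(c(0, 12000, 25000, 40000))
  js <- junction_discontinuities(prof, lay, k = 3)
  shifted <- grid_profile(vals + 7)
  expect_equal(junction_discontinuities(shifted, lay, k = 3)$discontinuity,
               js$discontinuity)
  scaled <- grid_profile(vals * 3)
  expect_equal(junction_discontinuities(scaled, lay, k = 3)$discontinuity,
               3 * js$discontinuity)
  # a side with fewer than k non-missing windows -> NA
  vals2 <- vals
  vals2[1:11] <- NA
  js2 <- junction_discontinuities(grid_profile(vals2), lay, k = 3)
  expect_true(is.na(js2$discontinuity[1]))
  expect_false(is.na(js2$discontinuity[2]))
})

test_that("a reversed scaffold in a gradient is suggested with known algebra", {
  vals <- as.numeric(0:29)
  vals[11:20] <- rev(vals[11:20])      # scaffold S2's windows reversed
  prof <- grid_profile(vals)
  lay <- tiling_layout(c(0, 10000, 20000, 30000))
  fs <- evaluate_flip(prof, lay, "S2", k = 3)
  expect_s3_class(fs, "flip_suggestion")
  # junctions before: |mean(7,8,9)-mean(19,18,17)| + |mean(12,11,10)-mean(20,21,22)|
  expect_equal(fs$score_current, 10 + 10)
  expect_equal(fs$score_flipped, 3 + 3)
  expect_equal(fs$improvement, 14)
  expect_true(fs$suggested)
  expect_false(fs$low_confidence)

  # un-reversed scaffold in the same gradient: reversal only hurts
  clean <- grid_profile(as.numeric(0:29))
  fs2 <- evaluate_flip(clean, lay, "S2", k = 3)
  expect_equal(fs2$improvement, 6 - 20)
  expect_false(fs2$suggested)
})

test_that("flip evaluation is an involution and symmetric profiles are inert", {
  vals <- as.numeric(0:29)
  vals[11:20] <- rev(vals[11:20])
  prof <- grid_profile(vals)
  lay <- tiling_layout(c(0, 10000, 20000, 30000))
  fs <- evaluate_flip(prof, lay, "S2", k = 3)
  # applying the suggested flip and evaluating again reverses the verdict
  flipped <- grid_profile(as.numeric(0:29))
  fs2 <- evaluate_flip(flipped, lay, "S2", k = 3)
  expect_equal(fs2$score_current, fs$score_flipped)
  expect_equal(fs2$score_flipped, fs$score_current)
  expect_equal(fs2$improvement, -fs$improvement)

  # palindromic interior: reversal changes nothing
  pal <- grid_profile(c(0:9, c(1:5, 5:1), 9:0))
  fs3 <- evaluate_flip(pal, lay, "S2", k = 3)
  expect_equal(fs3$improvement, 0)
  expect_false(fs3$suggested)
})

test_that("edge scaffolds and short scaffolds are handled", {
  vals <- as.numeric(0:29)
  lay <- tiling_layout(c(0, 10000, 20000, 30000))
  prof <- grid_profile(vals)
  f_first <- evaluate_flip(prof, lay, "S1", k = 3)
  expect_equal(f_first$score_current, 3)  # only the right junction
  f_last <- evaluate_flip(prof, lay, "S3", k = 3)
  expect_equal(f_last$score_current, 3)

  tiny <- tiling_layout(c(0, 2000, 28000, 30000))
  f_tiny <- evaluate_flip(prof, tiny, "S1", k = 3)
  expect_equal(f_tiny$flag, "insufficient_windows")
  expect_false(f_tiny$suggested)

  # k <= windows < 2k: evaluated but low-confidence, never suggested
  low <- tiling_layout(c(0, 10000, 14000, 30000))
  vals2 <- as.numeric(0:29)
  vals2[11:14] <- rev(vals2[11:14])
  f_low <- evaluate_flip(grid_profile(vals2), low, "S2", k = 3)
  expect_true(f_low$low_confidence)
  expect_false(f_low$suggested)

  expect_error(evaluate_flip(prof, lay, "nope"), "not found")
})

test_that("flip evaluation refuses non-strand-symmetric metrics", {
  prof <- grid_profile(as.numeric(0:29), metric = "custom_metric")
  lay <- tiling_layout(c(0, 10000, 20000, 30000))
  expect_error(evaluate_flip(prof, lay, "S2"), "strand-symmetric")
})

test_that("suggest_flips evaluates every scaffold once", {
  vals <- as.numeric(0:29)
  vals[11:20] <- rev(vals[11:20])
  prof <- grid_profile(vals)
  lay <- tiling_layout(c(0, 10000, 20000, 30000))
  fl <- suggest_flips(prof, lay, k = 3)
  expect_equal(fl$scaffold_id, c("S1", "S2", "S3"))
  expect_equal(fl$suggested, c(FALSE, TRUE, FALSE))
})

test_that("region stats assign windows by midpoint and use sample sd", {
  prof <- grid_profile(rep(4, 20))
  rs <- region_stats(prof, c(7300))
  expect_equal(rs$n, c(7, 13))   # midpoints 500,1500,...; 6500 < 7300 < 7500
  expect_equal(rs$mean, c(4, 4))
  expect_equal(rs$sd, c(0, 0))

  two <- grid_profile(c(rep(1, 10), rep(9, 10)))
  rs2 <- region_stats(two, c(10000))
  expect_equal(rs2$mean, c(1, 9))
  # missing windows excluded; empty region reported with n = 0
  holed <- grid_profile(c(rep(NA_real_, 10), rep(2, 10)))
  rs3 <- region_stats(holed, c(10000))
  expect_equal(rs3$n, c(0, 10))
  expect_true(is.na(rs3$mean[1]))
  expect_error(region_stats(prof, c(-5)), "inside")
})
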