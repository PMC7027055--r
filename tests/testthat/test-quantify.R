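test_that("reads are counted by 5' position containment", {
  peaks <- peak_set("chr1", 100, 600, name = "pk1")
  reads <- peak_set("chr1", c(150, 160, 700), c(225, 235, 775),
                    name = paste0("r", 1:3), strand = rep("+", 3))
  expect_identical(count_reads_in_peaks(reads, peaks), c(pk1 = 2L))

  # same interval, opposite strands: only the minus-strand 5' end (end - 1)
  # falls inside the peak
  reads2 <- peak_set("chr1", c(80, 80), c(155, 155),
                     name = c("r1", "r2"), strand = c("+", "-"))
  expect_identical(count_reads_in_peaks(reads2, peaks), c(pk1 = 1L))

  empty <- peak_set(character(0), integer(0), integer(0), character(0))
  expect_identical(count_reads_in_peaks(empty, peaks), c(pk1 = 0L))
})

test_that("read counting agrees with the exhaustive containment oracle", {
  withr::local_seed(101)
  for (rep in 1:25) {
    peaks <- random_peaks(sample(3:12, 1))
    reads <- random_reads(sample(50:1000, 1))
    expect_identical(count_reads_in_peaks(reads, peaks),
                     oracle_count_reads(reads, peaks))
  }
})

test_that("background correction follows the stated arithmetic", {
  # peak width 500, 10 reads inside, 8 in 1000 bp of usable flank -> 6
  peaks <- peak_set("chr1", 10000, 10500, name = "pk1")
  inside <- peak_set("chr1", 10000 + seq(0, 450, by = 50),
                     10000 + seq(0, 450, by = 50) + 75,
                     name = paste0("in", 1:10), strand = rep("+", 10))
  flank_pos <- c(9500 + seq(0, 300, by = 100), 10500 + seq(0, 300, by = 100))
  flank <- peak_set("chr1", flank_pos, flank_pos + 75,
                    name = paste0("fl", 1:8), strand = rep("+", 8))
  reads <- peak_set(c(inside$chrom, flank$chrom),
                    c(inside$start, flank$start),
                    c(inside$end, flank$end),
                    name = c(inside$name, flank$name),
                    strand = c(inside$strand, flank$strand))
  raw <- count_matrix(matrix(10, 1, 1, dimnames = list("pk1", "s1")))
  corr <- background_correct(raw, peaks, list(s1 = reads), flank_bp = 1000L)
  expect_equal(unname(corr$values[1, 1]), 10 - 8 * (500 / 1000))
  expect_equal(corr$stage, "corrected")
})

test_that("over-subtraction clips at zero", {
  peaks <- peak_set("chr1", 10000, 10500, name = "pk1")
  flank_pos <- 9500 + seq(0, 475, by = 25)   # 20 reads left flank
  reads <- peak_set("chr1", flank_pos, flank_pos + 50,
                    name = paste0("fl", seq_along(flank_pos)),
                    strand = rep("+", length(flank_pos)))
  raw <- count_matrix(matrix(7, 1, 1, dimnames = list("pk1", "s1")))
  corr <- background_correct(raw, peaks, list(s1 = reads), flank_bp = 1000L)
  expect_equal(unname(corr$values[1, 1]), 0)
})

test_that("fully peak-covered flanks contribute no background, with warning", {
  # middle peak's flanks are entirely inside its neighbors
  peaks <- peak_set("chr1", c(0, 600, 1300), c(600, 1300, 2000),
                    name = c("a", "b", "c"))
  pos <- c(650, 700, 800)
  reads <- peak_set("chr1", pos, pos + 50, name = paste0("r", 1:3),
                    strand = rep("+", 3))
  raw <- count_matrix(matrix(c(0, 3, 0), 3, 1,
                             dimnames = list(c("a", "b", "c"), "s1")))
  expect_warning(
    corr <- background_correct(raw, peaks, list(s1 = reads),
                               flank_bp = 1000L),
    "unusable")
  expect_equal(unname(corr$values["b", 1]), 3)
})

test_that("background correction is the identity when all reads fall in peaks", {
  withr::local_seed(7)
  cfg <- synthetic_config(n_peaks = 60, n_samples = 3, background_rate = 0,
                          depth = 20, seed = 42)
  truth <- generate_truth(cfg)
  gen <- generate_counts(truth, reads = TRUE)
  corr <- background_correct(gen$counts, truth$peaks, gen$reads)
  expect_equal(corr$values, gen$counts$values)
})

test_that("between-sample normalization equalizes totals and conserves mass", {
  vals <- matrix(c(2, 6, 4, 8), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  m <- count_matrix(vals, stage = "corrected")
  nm <- normalize_between_samples(m)
  expect_equal(unname(nm$values[, "s1"]), c(2.5, 7.5))
  expect_equal(unname(nm$values[, "s2"]), c(10 / 3, 20 / 3))
  expect_equal(sum(nm$values), sum(vals), tolerance = 1e-12)

  # already-equal totals: identity
  vals2 <- matrix(c(2, 6, 3, 5), 2, 2,
                  dimnames = list(c("p1", "p2"), c("s1", "s2")))
  m2 <- normalize_between_samples(count_matrix(vals2, stage = "corrected"))
  expect_equal(m2$values, vals2)

  # single sample: scale factor 1
  v1 <- matrix(c(3, 9), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  expect_equal(normalize_between_samples(
    count_matrix(v1, stage = "corrected"))$values, v1)

  vz <- matrix(c(1, 1, 0, 0), 2, 2,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_error(normalize_between_samples(count_matrix(vz, stage = "corrected")),
               "s2")
})

test_that("minimum-signal filter keeps peaks supported by any sample", {
  vals <- matrix(c(1.5, 1.5, 5, 1.9, 2.0, 1), 3, 2,
                 dimnames = list(c("pA", "pB", "pC"), c("s1", "s2")))
  m <- count_matrix(vals, stage = "normalized")
  out <- filter_min_signal(m, 2)
  expect_identical(out$removed, "pA")          # max 1.9 < 2
  expect_true("pB" %in% out$matrix$peak_ids)   # max 2.0 is not < 2
  expect_identical(filter_min_signal(m, 0)$removed, character(0))
})

test_that("repeated filtering equals filtering at the larger threshold", {
  withr::local_seed(19)
  vals <- matrix(rexp(300, rate = 0.3), 75, 4)
  m <- as_norm_matrix(vals)
  once <- filter_min_signal(m, 3)$matrix
  twice <- filter_min_signal(filter_min_signal(m, 1.2)$matrix, 3)$matrix
  expect_identical(twice$peak_ids, once$peak_ids)
  expect_equal(twice$values, once$values)
})

test_that("presence calls use a strict threshold", {
  vals <- matrix(c(5, 10, 4, 3, 1, 4.0001), 3, 2,
                 dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  m <- count_matrix(vals, stage = "normalized")
  pres <- presence_matrix(m, 4)
  expect_identical(unname(pres$presence[, 1]), c(TRUE, TRUE, FALSE))
  expect_identical(unname(pres$presence[, 2]), c(FALSE, FALSE, TRUE))
  expect_equal(unname(pres$fraction), c(2 / 3, 1 / 3))

  z <- count_matrix(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                    c("s1", "s2"))),
                    stage = "normalized")
  expect_equal(unname(presence_matrix(z)$fraction), c(0, 0))
})

test_that("relative intensity scales every peak to mean 1", {
  m <- as_norm_matrix(matrix(c(2, 3, 4, 3, 6, 3), 2, 3, byrow = FALSE,
                             dimnames = list(c("p1", "p2"),
                                             c("s1", "s2", "s3"))))
  rel <- relative_intensity(m)
  expect_equal(unname(rel$values["p1", ]), c(0.5, 1, 1.5))
  expect_equal(unname(rel$values["p2", ]), c(1, 1, 1))
  expect_equal(rel$stage, "relative")

  withr::local_seed(23)
  m2 <- as_norm_matrix(matrix(rexp(60) + 0.1, 12, 5))
  rel2 <- relative_intensity(m2)
  expect_equal(unname(rowMeans(rel2$values)), rep(1, 12), tolerance = 1e-12)

  mz <- as_norm_matrix(matrix(c(0, 1, 0, 2), 2, 2))
  expect_error(relative_intensity(mz), "zero-mean")
})

test_that("stage transitions only move forward", {
  vals <- matrix(1:4 * 1.0, 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  m <- count_matrix(vals, stage = "normalized")
  expect_error(background_correct(m, peak_set("chr1", 1, 2),
                                  list(s1 = peak_set("chr1", 1, 2))),
               "raw")
  expect_error(filter_min_signal(count_matrix(vals, stage = "raw")),
               "normalized")
  expect_error(count_matrix(matrix(-1, 1, 1,
                                   dimnames = list("p", "s"))),
               "non-negative")
})
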