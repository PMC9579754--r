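test_that("a sync line parses into the expected counts and coverage", {
  cat_ <- marker_catalog("2L", 100, "A", "C")
  f <- withr::local_tempfile()
  writeLines("2L\t100\tA\t10:0:2:0:0:0", f)
  ct <- read_sync(f, cat_)
  expect_equal(unname(ct$counts[1, 1, c("A", "C")]), c(10L, 2L))
  ft <- focal_allele_frequency(ct)
  expect_equal(unname(ft$cov[1, 1]), 12)
  expect_equal(unname(ft$freq[1, 1]), 10 / 12)
})

test_that("markers come back in catalogue order regardless of file order", {
  cat_ <- toy_catalog("2L", n = 4, spacing = 100L)   # positions 100..400
  f <- withr::local_tempfile()
  writeLines(c("2L\t300\tA\t3:0:1:0:0:0", "2L\t100\tA\t1:0:1:0:0:0",
               "2L\t400\tA\t4:0:1:0:0:0", "2L\t200\tA\t2:0:1:0:0:0"), f)
  ct <- read_sync(f, cat_)
  expect_equal(unname(ct$counts[, 1, "A"]), 1:4)
})

test_that("multi-sample files agree with an independent line-by-line parser", {
  set.seed(42)
  cat_ <- toy_catalog(c("2L", "2R"), n = 25)
  f <- withr::local_tempfile()
  counts <- lapply(1:3, function(i)
    matrix(rpois(nrow(cat_) * 6, 5), ncol = 6))
  write_toy_sync(f, cat_$arm, cat_$pos, cat_$focal_allele, counts)
  ct <- read_sync(f, cat_)
  expect_equal(dim(ct$counts), c(50, 3, 6))
  got <- colSums(apply(ct$counts, c(1, 2), sum))
  expect_equal(unname(got), naive_sync_totals(f))
})

test_that("missing markers are flagged missing, never zero", {
  cat_ <- toy_catalog("2L", n = 3, spacing = 100L)
  f <- withr::local_tempfile()
  writeLines(c("2L\t100\tA\t5:0:5:0:0:0", "2L\t300\tA\t6:0:2:0:0:0"), f)
  ct <- read_sync(f, cat_)
  expect_true(all(is.na(ct$counts[2, 1, ])))
  ft <- focal_allele_frequency(ct)
  expect_true(is.na(ft$freq[2, 1]))
  # zero informative coverage is also missing, not 0
  f2 <- withr::local_tempfile()
  writeLines(c("2L\t100\tA\t0:9:0:0:0:0", "2L\t200\tA\t3:0:1:0:0:0",
               "2L\t300\tA\t1:0:0:0:0:0"), f2)
  ft2 <- focal_allele_frequency(read_sync(f2, cat_))
  expect_true(is.na(ft2$freq[1, 1]))   # 9 T reads, no A/C
  expect_equal(unname(ft2$ignored), 9)
})

test_that("malformed count columns and foreign chromosomes are handled", {
  cat_ <- marker_catalog("2L", c(100, 200), c("A", "A"), c("C", "C"))
  f <- withr::local_tempfile()
  writeLines(c("2L\t100\tA\t1:2:3:4:0", "2L\t200\tA\t1:2:3:4:0:0"), f)
  expect_error(read_sync(f, cat_), "line 1")
  writeLines(c("2L\t100\tA\t1:2:3:4:0:0", "2L\t200\tA\t1:x:3:4:0:0"), f)
  expect_error(read_sync(f, cat_), "line 2")
  writeLines(c("2L\t100\tA\t1:2:3:4:0:0", "U\t50\tA\t1:2:3:4:0:0"), f)
  expect_warning(ct <- read_sync(f, cat_), "skipping")
  expect_equal(unname(ct$counts[1, 1, "A"]), 1L)
})

test_that("third-allele reads are excluded from the frequency", {
  cat_ <- marker_catalog("2L", 100, "A", "C")
  f <- withr::local_tempfile()
  writeLines("2L\t100\tA\t5:1:4:0:0:0", f)   # A=5, T=1, C=4
  ft <- focal_allele_frequency(read_sync(f, cat_))
  expect_equal(unname(ft$freq[1, 1]), 5 / 9)
  expect_equal(unname(ft$cov[1, 1]), 9)
  expect_equal(unname(ft$ignored), 1)
  expect_equal(unname(ft$depth[1, 1]), 10)
})

test_that("boundary frequencies come out exactly 0 and 0.75", {
  cat_ <- marker_catalog("2L", c(100, 200), c("A", "A"), c("C", "C"))
  f <- withr::local_tempfile()
  writeLines(c("2L\t100\tA\t0:0:7:0:0:0", "2L\t200\tA\t9:0:3:0:0:0"), f)
  ft <- focal_allele_frequency(read_sync(f, cat_))
  expect_identical(unname(ft$freq[, 1]), c(0, 0.75))
})

test_that("sample intersection matches a brute-force loop under missingness", {
  set.seed(7)
  n <- 1000
  cat_ <- toy_catalog("2L", n = n)
  freq <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, paste0("S", 1:6)))
  cov <- matrix(20L, n, 6, dimnames = dimnames(freq))
  miss <- matrix(runif(n * 6) < 0.10, n, 6)
  freq[miss] <- NA
  ft <- structure(list(catalog = cat_,
                       samples = sample_info(paste0("S", 1:6),
                                             rep(c(18, 29), each = 3),
                                             rep(1:3, 2)),
                       freq = freq, cov = cov, depth = cov,
                       ignored = setNames(rep(0, 6), colnames(freq))),
                  class = "freq_table")
  kept <- suppressMessages(intersect_samples(ft))
  oracle <- which(vapply(seq_len(n), function(i) all(!is.na(freq[i, ])),
                         logical(1)))
  expect_equal(kept$catalog$pos, cat_$pos[oracle])
  # one marker missing in a single sample disappears everywhere
  drop1 <- which(rowSums(miss) == 1)[1]
  expect_false(cat_$pos[drop1] %in% kept$catalog$pos)
})

test_that("coverage down-sampling hits the target mean and stays unbiased", {
  n <- 1e5
  cat_ <- marker_catalog(rep("2L", n), seq_len(n), "A", "C")
  freq <- matrix(0.3, n, 1, dimnames = list(NULL, "S1"))
  ft <- structure(list(catalog = cat_, samples = sample_info("S1", 29, 1),
                       freq = freq,
                       cov = matrix(120L, n, 1), depth = matrix(120L, n, 1),
                       ignored = c(S1 = 0)),
                  class = "freq_table")
  ds <- downsample_coverage(ft, 12, seed = 11L)
  # mean coverage ~ Poisson(12): 3 SE tolerance
  se_cov <- sqrt(12 / n)
  expect_lt(abs(mean(ds$cov[, 1]) - 12), 3 * se_cov)
  # unbiasedness of the frequency: Monte-Carlo 3 SE
  se_f <- sqrt(0.3 * 0.7 / 12 / n)   # approx (coverage varies)
  expect_lt(abs(mean(ds$freq[, 1], na.rm = TRUE) - 0.3), 3.5 * se_f)
  # frequency 0 can only stay 0
  ft$freq[, 1] <- 0
  ds0 <- downsample_coverage(ft, 12, seed = 3L)
  expect_true(all(ds0$freq[!is.na(ds0$freq[, 1]), 1] == 0))
  ds0b <- downsample_coverage(ft, 12, seed = 3L)
  expect_identical(ds0$freq, ds0b$freq)   # same seed, same draw
  # a drawn coverage of zero flags the marker missing (target mean 1 makes
  # zero draws common)
  ds1 <- downsample_coverage(ft, 1, seed = 3L)
  expect_true(any(is.na(ds1$freq[, 1])))
  expect_true(all(ds1$cov[is.na(ds1$freq[, 1]), 1] == 0))
})

test_that("write_sync / read_sync round-trips a generated count table", {
  cfg <- small_generator(seed = 5L)
  exp <- generate_experiment(cfg)
  f <- withr::local_tempfile()
  write_sync(exp$counts18, f)
  back <- read_sync(f, exp$catalog, exp$counts18$samples)
  a <- exp$counts18$counts
  b <- back$counts
  # markers missing in every sample are omitted on write and NA on re-read
  allmiss <- apply(a, 1, function(m) all(m == 0 | is.na(m)))
  expect_equal(b[!allmiss, , ], a[!allmiss, , ])
})
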