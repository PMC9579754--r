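test_that("empirical p-values match exhaustive counting on small nulls", {
  null <- c(-0.2, -0.1, 0, 0.1, 0.2)
  expect_equal(empirical_pvalue(0.05, null), 2 / 5)   # {0.1, 0.2} above
  expect_equal(empirical_pvalue(-0.15, null), 1 / 5)  # {-0.2} below
  expect_equal(empirical_pvalue(0.3, null), 0)        # beyond every value
  expect_equal(empirical_pvalue(0, null), 1)          # zero change: p = 1
  # vectorized agreement with a brute-force loop on random data
  set.seed(12)
  nv <- rnorm(500)
  obs <- c(rnorm(200), 0, nv[7])   # include ties and an exact zero
  brute <- vapply(obs, function(x) {
    if (x > 0) mean(nv > x) else if (x < 0) mean(nv < x) else 1
  }, numeric(1))
  expect_equal(empirical_pvalue(obs, nv), brute)
  expect_error(empirical_pvalue(0.5, numeric(0)), "empty null")
})

test_that("empirical p-values are monotone in the observed AFC", {
  set.seed(3)
  null <- rnorm(1000, 0, 0.02)
  pos <- sort(runif(50, 0, 0.1))
  expect_true(all(diff(empirical_pvalue(pos, null)) <= 0))
  neg <- sort(-runif(50, 0, 0.1))
  expect_true(all(diff(empirical_pvalue(neg, null)) >= 0))
})

test_that("BH adjustment equals the textbook step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)                       # single p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))         # equal p's
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "must be in")
  expect_error(bh_adjust(c(-0.1, 0.5)), "must be in")
})

test_that("the window LM equals a pooled-variance t-test with 4 df", {
  r <- fit_window_lm(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(r$intercept, 0.2)
  expect_equal(r$temperature, 0.3)
  expect_equal(r$p, 2 * pt(-0.3 / (0.1 * sqrt(2 / 3)), df = 4))
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  # intercept is exactly the 18C mean; identity holds with the 29C mean
  set.seed(21)
  for (i in 1:25) {
    a <- rnorm(3); b <- rnorm(3)
    fit <- fit_window_lm(a, b)
    expect_identical(fit$intercept, mean(a))
    expect_equal(fit$intercept + fit$temperature, mean(b))
    expect_equal(fit$p, pooled_t_p(a, b), tolerance = 1e-10)
  }
})

test_that("degenerate replicate variance follows the documented convention", {
  same <- c(0.1, 0.1, 0.1)
  expect_equal(fit_window_lm(same, same)$p, 1)
  r <- fit_window_lm(same, c(0.5, 0.5, 0.5))
  expect_equal(r$p, 0)
  expect_equal(r$temperature, 0.4)
})

test_that("the six-class decision tree is exhaustive and exclusive", {
  grid <- expand.grid(sig18 = c(FALSE, TRUE), sig29 = c(FALSE, TRUE),
                      sig_lm = c(FALSE, TRUE), sign18 = c(-1, 1),
                      sign29 = c(-1, 1))
  lab <- classify_windows(grid$sig18, grid$sig29, grid$sig_lm,
                          grid$sign18 * 0.1, grid$sign29 * 0.4)
  expect_false(anyNA(lab))                       # every point gets a label
  expect_equal(length(lab), nrow(grid))          # exactly one per point
  # spot checks of every branch
  pick <- function(s18, s29, slm, a18, a29)
    as.character(classify_windows(s18, s29, slm, a18, a29))
  expect_equal(pick(FALSE, FALSE, FALSE, 0.8, 0.9), "drift only")
  expect_equal(pick(TRUE, FALSE, TRUE, 0.2, 0.01), "change 18C only")
  expect_equal(pick(FALSE, TRUE, TRUE, 0.01, 0.3), "change 29C only")
  expect_equal(pick(TRUE, TRUE, FALSE, 0.2, 0.25), "no temperature effect")
  expect_equal(pick(TRUE, TRUE, TRUE, 0.1, 0.4), "different magnitude")
  expect_equal(pick(TRUE, TRUE, TRUE, -0.1, 0.4), "different direction")
  # the sig_lm flag is irrelevant unless both temperatures are significant
  expect_equal(pick(TRUE, FALSE, FALSE, 0.2, 0.0), "change 18C only")
})

test_that("relabelling the temperatures swaps the change-only classes", {
  set.seed(5)
  n <- 200
  s18 <- runif(n) < 0.5; s29 <- runif(n) < 0.5; slm <- runif(n) < 0.5
  a18 <- rnorm(n); a29 <- rnorm(n)
  fwd <- classify_windows(s18, s29, slm, a18, a29)
  swp <- classify_windows(s29, s18, slm, a29, a18)
  m <- c("drift only" = "drift only",
         "change 18C only" = "change 29C only",
         "change 29C only" = "change 18C only",
         "no temperature effect" = "no temperature effect",
         "different magnitude" = "different magnitude",
         "different direction" = "different direction")
  expect_equal(as.character(swp), unname(m[as.character(fwd)]))
})

test_that("selection_scan wires p-values, LM and classes together", {
  # two chromosomes x 3 windows, synthetic window table built by hand
  idx <- structure(data.frame(chrom = rep(c("2", "3"), each = 3),
                              window = rep(1:3, 2), first = 1:6, last = 1:6,
                              n_markers = 1L, centre = rep(1:3, 2) * 1e5,
                              partial = FALSE),
                   class = c("window_index", "data.frame"))
  afc <- array(0, c(6, 3, 2), dimnames = list(NULL, paste0("rep", 1:3),
                                              c("T18", "T29")))
  afc[1, , ] <- c(0.30, 0.32, 0.34, 0.31, 0.33, 0.35)   # strong both temps
  afc[2, , ] <- c(0.001, -0.002, 0.002, 0.30, 0.32, 0.34) # 29C only
  afc[3, , ] <- 0.001 * matrix(c(1, -1, 2, -2, 1, 1), 1)  # drift
  afc[4, , ] <- c(0.10, 0.12, 0.11, 0.42, 0.44, 0.40)   # magnitude change
  afc[5, , ] <- c(-0.20, -0.22, -0.21, 0.30, 0.32, 0.31) # direction change
  afc[6, , ] <- c(0.25, 0.27, 0.26, 0.001, 0.002, -0.001) # 18C only
  wt <- structure(list(index = idx, temps = c(18, 29), reps = 1:3, p0 = 0.3,
                       freq = afc + 0.3, afc = afc,
                       mean = apply(afc, c(1, 3), mean),
                       se = apply(afc, c(1, 3), sd) / sqrt(3)),
                  class = "window_table")
  set.seed(2)
  null <- structure(data.frame(chrom = rep(c("2", "3"), each = 300),
                               run = 1, window = 1,
                               afc = rnorm(600, 0, 0.02)),
                    class = c("null_distribution", "data.frame"))
  scan <- selection_scan(wt, null, fdr = 0.10)
  expect_equal(as.character(scan$class),
               c("no temperature effect", "change 29C only", "drift only",
                 "different magnitude", "different direction",
                 "change 18C only"))
  # LM intercept reproduces the observed 18C mean AFC
  expect_equal(scan$alpha_intercept, scan$afc18)
  expect_equal(scan$alpha_intercept + scan$alpha_temperature, scan$afc29)
  # fdr sweep returns one scan per threshold
  sw <- fdr_sweep(wt, null)
  expect_named(sw, c("fdr5", "fdr10", "fdr15"))
})

test_that("class_summary fractions sum to one and track planted labels", {
  idx_df <- data.frame(chrom = rep(c("2", "3"), each = 4), window = rep(1:4, 2),
                       centre = 1:8)
  scan <- structure(data.frame(idx_df,
                               afc18 = c(rep(0.1, 4), rep(0.2, 4)),
                               afc29 = c(rep(0.4, 4), rep(0.1, 4)),
                               class = factor(c(rep("different magnitude", 4),
                                                rep("drift only", 4)),
                                              levels = levels(classify_windows(
                                                TRUE, TRUE, TRUE, 1, 1)))),
                    class = c("scan_result", "data.frame"))
  s <- class_summary(scan)
  expect_equal(colSums(s$fractions), c("2" = 1, "3" = 1, GW = 1))
  expect_equal(unname(s$fractions["different magnitude", "2"]), 1)
  # genome-wide is the unweighted chromosome mean
  expect_equal(unname(s$fractions["drift only", "GW"]), 0.5)
  expect_equal(s$more_extreme_at_29, 1)   # |0.4| > |0.1| everywhere planted
})
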