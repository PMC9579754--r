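# direct access to the meiosis internals for property tests
gamete <- function(a0, abp, b0, bbp, gpos, gcm, female = TRUE) {
  erscan:::.wf_gamete_cpp(a0, abp, b0, bbp, gpos, gcm, female)
}

test_that("founder frequencies equal the focal-genotype fraction", {
  cat_ <- marker_catalog(rep(c("2L", "X"), each = 5),
                         rep(1:5 * 1e5, 2), "A", "C")
  map <- recomb_map(c("2L", "X"), c(1, 1), c(1e6, 1e6), c(2, 2))
  cfg <- sim_config(cat_, map, N = 10, p_geno = 0.3, generations = 0)
  f <- simulate_replicate(cfg, 18, seed = 1)
  expect_equal(f[1:5], rep(0.3, 5))          # 3/10 flies = 6/20 copies
  # X counts copies: focal class of 3 = M,F,M -> 4 of 14 X copies
  expect_equal(f[6:10], rep(4 / 14, 5))
  # p_geno = 0 is absorbing
  cfg0 <- sim_config(cat_, map, N = 10, p_geno = 0, generations = 5)
  expect_true(all(simulate_replicate(cfg0, 18, seed = 2) == 0))
  # mono-founder rounding warns
  expect_warning(sim_config(cat_, map, N = 2, p_geno = 0.1, generations = 1),
                 "mono-founder")
})

test_that("a zero-rate map transmits unmodified parental copies", {
  g <- replicate(50, gamete(1L, c(5e5), 0L, numeric(0),
                            c(1, 1e6), c(0, 0))$anc0)
  gg <- replicate(50, length(gamete(1L, c(5e5), 0L, numeric(0),
                                    c(1, 1e6), c(0, 0))$breakpoints))
  expect_true(all(g %in% c(0, 1)))
  expect_true(all(gg %in% c(0, 1)))   # either copy, never a recombinant mix
  set.seed(1)
  one <- gamete(1L, c(2e5, 7e5), 1L, c(2e5, 7e5), c(1, 1e6), c(0, 0))
  expect_equal(one$breakpoints, c(2e5, 7e5))   # copy passed through intact
})

test_that("male meiosis never mixes ancestries within a chromosome", {
  set.seed(99)
  # heterozygous parent: one all-focal copy, one all-other copy
  n_mixed <- 0
  for (i in 1:10000) {
    g <- gamete(1L, numeric(0), 0L, numeric(0), c(1, 1e6), c(0, 0.01),
                female = FALSE)
    if (length(g$breakpoints) > 0) n_mixed <- n_mixed + 1
  }
  expect_equal(n_mixed, 0)
})

test_that("female crossover counts are Poisson with the map's genetic length", {
  set.seed(17)
  # 1 Morgan chromosome: mean 1 crossover per meiosis
  k <- replicate(1e4, length(gamete(1L, numeric(0), 0L, numeric(0),
                                    c(1, 1e6), c(0, 1))$breakpoints))
  expect_lt(abs(mean(k) - 1), 3 * sqrt(1 / 1e4))
  expect_lt(abs(var(k) - 1), 4 * sqrt(2 / 1e4))   # Poisson variance too
})

test_that("crossover positions follow the cumulative genetic map", {
  set.seed(23)
  # rate concentrated in the left half: [0,5e5] holds 0.9 of 1 Morgan
  bp <- unlist(replicate(4000, gamete(1L, numeric(0), 0L, numeric(0),
                                      c(1, 5e5, 1e6), c(0, 0.9, 1))$breakpoints))
  frac_left <- mean(bp <= 5e5)
  expect_lt(abs(frac_left - 0.9), 3 * sqrt(0.9 * 0.1 / length(bp)))
})

test_that("neutral drift variance matches the Wright-Fisher closed form", {
  # single unlinked marker, N = 1500, t = 20, p0 = 0.3, >= 300 runs
  cat_ <- marker_catalog("2L", 5e5, "A", "C")
  map <- recomb_map("2L", 1, 1e6, 2)
  cfg <- sim_config(cat_, map, N = 1500, p_geno = 0.3, generations = 20)
  f <- vapply(1:300, function(i) simulate_replicate(cfg, 18, seed = 1000 + i),
              numeric(1))
  expected <- 0.3 * 0.7 * (1 - (1 - 1 / 3000)^20)
  expect_lt(abs(var(f) - expected) / expected, 0.15)
  expect_lt(abs(mean(f) - 0.3), 3 * sqrt(expected / 300))
})

test_that("tightly linked markers drift as one block", {
  # 10 markers in 50 kb on a 2 cM/Mb map stay almost perfectly correlated
  cat_ <- marker_catalog("2L", seq(5e5, 5.5e5, length.out = 10), "A", "C")
  map <- recomb_map("2L", 1, 1e6, 2)
  cfg <- sim_config(cat_, map, N = 500, p_geno = 0.3, generations = 20)
  f <- t(vapply(1:40, function(i) simulate_replicate(cfg, 18, seed = 400 + i),
                numeric(10)))
  cors <- cor(f)
  expect_gt(min(cors), 0.99)
})

test_that("selection drives the focal allele according to the trajectory oracle", {
  cat_ <- marker_catalog("2L", seq(1e5, 9e5, length.out = 20), "A", "C")
  map <- recomb_map("2L", 1, 1e6, 2)
  tg <- selection_targets("2L", cat_$pos[10], s18 = 0.5, s29 = 0, h = 0.5)
  cfg <- sim_config(cat_, map, N = 1500, p_geno = 0.3, generations = 20,
                    targets = tg)
  f18 <- rowMeans(vapply(1:5, function(i)
    simulate_replicate(cfg, 18, seed = 600 + i), numeric(20)))
  f29 <- rowMeans(vapply(1:5, function(i)
    simulate_replicate(cfg, 29, seed = 700 + i), numeric(20)))
  pred <- det_trajectory(0.3, 0.5, 0.5, 20)
  expect_lt(abs(f18[10] - pred), 0.1)       # selected temperature follows
  expect_lt(abs(f29[10] - 0.3), 0.12)       # s29 = 0: drift only
  # an effectively lethal alternative: focal fixes fast
  tg2 <- selection_targets("2L", cat_$pos[10], s18 = 1e6, s29 = 0)
  cfg2 <- sim_config(cat_, map, N = 200, p_geno = 0.3, generations = 10,
                     targets = tg2)
  f <- simulate_replicate(cfg2, 18, seed = 42)
  expect_gt(f[10], 0.95)
})

test_that("the neutral null has the documented shape and a ~zero mean", {
  cat_ <- marker_catalog(rep(c("2L", "2R"), each = 30),
                         rep(seq(1e4, 9e5, length.out = 30), 2), "A", "C")
  map <- recomb_map(c("2L", "2R"), c(1, 1), c(1e6, 1e6), c(2, 2))
  cfg <- sim_config(cat_, map, N = 300, p_geno = 0.3, generations = 20)
  idx <- assign_windows(cat_, 20)            # 3 windows on chromosome 2
  null <- simulate_null(cfg, idx, n_runs = 30, seed = 5L)
  expect_equal(nrow(null), 30 * 3)
  expect_equal(unique(null$chrom), "2")
  se <- sd(null$afc) / sqrt(nrow(null))      # correlated, so indicative only
  expect_lt(abs(mean(null$afc)), 5 * se + 0.02)
  # t = 0: all null AFCs exactly the founder rounding offset (zero here)
  cfg0 <- sim_config(cat_, map, N = 300, p_geno = 0.3, generations = 0)
  null0 <- simulate_null(cfg0, idx, n_runs = 3, seed = 5L)
  expect_true(all(null0$afc == 0))
  expect_error(simulate_null(cfg, idx, n_runs = 0), "n_runs")
})

test_that("null simulation refuses selection targets and reproduces exactly", {
  cat_ <- marker_catalog("2L", c(1e5, 2e5), "A", "C")
  map <- recomb_map("2L", 1, 1e6, 2)
  tg <- selection_targets("2L", 1e5, 0.3, 0.3)
  cfgs <- sim_config(cat_, map, N = 50, generations = 2, targets = tg)
  idx <- assign_windows(cat_, 2)
  expect_error(simulate_null(cfgs, idx, n_runs = 2), "without selection")
  cfg <- sim_config(cat_, map, N = 50, generations = 2)
  n1 <- simulate_null(cfg, idx, n_runs = 5, seed = 9L)
  n2 <- simulate_null(cfg, idx, n_runs = 5, seed = 9L)
  expect_identical(n1$afc, n2$afc)
})

test_that("markers outside the map support are rejected at construction", {
  cat_ <- marker_catalog("2L", 2e6, "A", "C")
  map <- recomb_map("2L", 1, 1e6, 2)
  expect_error(sim_config(cat_, map), "outside recombination-map support")
})
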