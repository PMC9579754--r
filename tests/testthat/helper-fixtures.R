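# Fixture builders and independent oracles shared across test files.

# small catalogue: n markers per arm, evenly spaced, A/C alleles
toy_catalog <- function(arms = c("2L", "2R"), n = 10, spacing = 1000L) {
  marker_catalog(rep(arms, each = n),
                 rep(seq_len(n) * spacing, length(arms)), "A", "C")
}

# write a sync file from a data frame with columns arm, pos, ref and a list
# of per-sample count vectors c(A,T,C,G,N,del)
write_toy_sync <- function(path, arm, pos, ref, counts_per_sample) {
  cols <- vapply(counts_per_sample, function(m)
    apply(m, 1, paste, collapse = ":"), character(length(arm)))
  writeLines(apply(cbind(arm, pos, ref, cols), 1, paste, collapse = "\t"),
             path)
  path
}

# independent line-by-line sync parser used as an oracle for read_sync
naive_sync_totals <- function(path) {
  lines <- readLines(path)
  samp_sums <- NULL
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    cnt <- vapply(f[-(1:3)], function(s)
      sum(as.integer(strsplit(s, ":")[[1]])), numeric(1))
    samp_sums <- if (is.null(samp_sums)) cnt else samp_sums + cnt
  }
  unname(samp_sums)
}

# textbook step-up BH, written independently of stats::p.adjust
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# pooled-variance two-sample t-test (df = n1 + n2 - 2), the LM oracle
pooled_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = n1 + n2 - 2)
}

# deterministic one-locus selection trajectory (dominance h), the oracle for
# planted-target behaviour: expected frequency after t generations
det_trajectory <- function(p0, s, h, t) {
  p <- p0
  for (i in seq_len(t)) {
    wbar <- p^2 * (1 + s) + 2 * p * (1 - p) * (1 + h * s) + (1 - p)^2
    p <- (p^2 * (1 + s) + p * (1 - p) * (1 + h * s)) / wbar
  }
  p
}

# generator config for fast tests: small genome, same structure
small_generator <- function(seed = 7L, ...) {
  generator_config(
    markers_per_arm = c("2L" = 150, "2R" = 150, "3L" = 150, "3R" = 150,
                        "4" = 150, "X" = 150),
    arm_length = c("2L" = 2e6, "2R" = 2e6, "3L" = 2e6, "3R" = 2e6,
                   "4" = 2e6, "X" = 2e6),
    rate = c("2L" = 2.7, "2R" = 2.7, "3L" = 2.7, "3R" = 2.7, "4" = 2.7,
             "X" = 3.0),
    region_markers = 30,
    seed = seed, ...)
}
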