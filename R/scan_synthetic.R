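#' Scan a generated synthetic experiment end-to-end
#'
#' Convenience wrapper running the full analysis on the in-memory output of
#' [generate_experiment()]: focal-allele frequencies, intersection across
#' samples, down-sampling of the high-coverage regime to the target
#' coverage, windowing (all linkage groups of the synthetic genome
#' included), the neutral null (simulated with matching Pool-Seq noise
#' unless one is supplied), the selection scan at the given FDR, and the
#' comparison against the generator's truth table.
#'
#' Because the null distribution depends only on the experiment's geometry
#' (catalogue, map, window layout) and not on its planted targets, a null
#' simulated for one experiment can be reused for other experiments sharing
#' the same generator seed via the `null` argument.
#'
#' @param exp output of [generate_experiment()]
#' @param w markers per window (default 100: fine enough that a default
#'   500-marker truth region spans several windows)
#' @param fdr FDR threshold (default 0.10)
#' @param n_runs neutral runs when simulating the null (default 100)
#' @param null optional `null_distribution` to reuse
#' @param target_coverage down-sampling target and null noise coverage
#'   (default 12)
#' @param seed master seed for down-sampling and the null simulation
#'   (default: the generator's seed)
#' @return list with `scan` (a `scan_result`), `recovery` (from
#'   [recovery_report()]), `null`, `index`, `windows` (the `window_table`)
#'   and `freq` (the intersected, down-sampled `freq_table`)
#' @export
scan_synthetic_experiment <- function(exp, w = 100, fdr = 0.10, n_runs = 100,
                                      null = NULL, target_coverage = 12,
                                      seed = exp$config$seed) {
  ft <- bind_freq_tables(focal_allele_frequency(exp$counts18),
                         focal_allele_frequency(exp$counts29))
  ft <- suppressMessages(intersect_samples(ft))
  high <- ft$samples$id[colMeans(ft$cov, na.rm = TRUE) >
                          1.5 * target_coverage]
  if (length(high))
    ft <- downsample_coverage(ft, target_coverage, samples = high,
                              seed = seed)
  index <- assign_windows(ft$catalog, w, exclude = character(0),
                          arm_lengths = exp$config$arm_length)
  wt <- window_afc(ft, index, p0 = exp$config$p_geno)
  if (is.null(null)) {
    cfg <- sim_config(ft$catalog, exp$map, N = exp$config$N,
                      p_geno = exp$config$p_geno,
                      generations = exp$config$generations,
                      replicates = exp$config$replicates)
    null <- simulate_null(cfg, index, n_runs = n_runs,
                          p0 = exp$config$p_geno,
                          coverage = target_coverage, seed = seed)
  }
  scan <- selection_scan(wt, null, fdr = fdr)
  recovery <- recovery_report(scan, exp$truth, index, ft$catalog,
                              arm_lengths = exp$config$arm_length)
  list(scan = scan, recovery = recovery, null = null, index = index,
       windows = wt, freq = ft)
}

# single-class generator configurations used for recovery evaluation: the
# two regimes are separate populations, so an experiment planting only (say)
# a change-18C-only region has a genuinely neutral 29C genome -- planting
# several classes at once instead reproduces the real-data situation where
# genome-wide founder LD lets strong targets drag every chromosome early on.
#' Generator configuration planting a single class (or none)
#'
#' @param class one of the five selected class labels, or NULL for an
#'   all-neutral genome
#' @param seed master seed
#' @param ... further arguments passed to [generator_config()]
#' @return a `generator_config`
#' @export
single_class_config <- function(class = NULL, seed = 1L, ...) {
  rpc <- setNames(integer(5), setdiff(.CLASSES, "drift only"))
  if (!is.null(class)) {
    stopifnot(class %in% names(rpc))
    rpc[class] <- 1L
  }
  generator_config(regions_per_class = rpc, seed = seed, ...)
}
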