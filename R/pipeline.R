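#' Pipeline configuration
#'
#' Paths and parameters for the end-to-end scan: sync files per temperature,
#' marker catalogue, recombination map, and the analysis parameters with the
#' study defaults (window size 250 SNPs, FDR 10%, 100 neutral runs,
#' down-sampling target 12x, starting frequency 0.3, census 1500,
#' 20 generations).
#'
#' @param catalog path to the marker-catalogue file
#' @param map path to the recombination-map file
#' @param sync18,sync29 sync file path per temperature regime
#' @param out_dir output directory
#' @param w markers per window (default 250)
#' @param fdr FDR threshold (default 0.10)
#' @param n_runs neutral simulation runs (default 100)
#' @param target_coverage down-sampling target mean; samples whose observed
#'   mean informative coverage exceeds `1.5 * target_coverage` are
#'   down-sampled (default 12)
#' @param p0 starting focal frequency (default 0.3)
#' @param N census size for the neutral simulations (default 1500)
#' @param generations generations (default 20)
#' @param replicates replicates per regime (default 3)
#' @param exclude_chroms chromosomes excluded from windowing (default "4")
#' @param null_file optional path to a previously simulated null
#'   distribution; when given, the simulation stage is skipped
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(catalog, map, sync18, sync29, out_dir,
                            w = 250, fdr = 0.10, n_runs = 100,
                            target_coverage = 12, p0 = 0.3, N = 1500,
                            generations = 20, replicates = 3,
                            exclude_chroms = "4", null_file = NULL,
                            seed = 1L) {
  for (p in c(catalog, map, sync18, sync29, null_file))
    if (!file.exists(p)) stop("input file not found: ", p)
  stopifnot(w >= 1, fdr > 0, fdr < 1, n_runs >= 1, target_coverage > 0)
  structure(list(catalog = catalog, map = map, sync18 = sync18,
                 sync29 = sync29, out_dir = out_dir, w = w, fdr = fdr,
                 n_runs = n_runs, target_coverage = target_coverage, p0 = p0,
                 N = N, generations = generations, replicates = replicates,
                 exclude_chroms = exclude_chroms, null_file = null_file,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message("[", name, "] ...")
  val <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message("[", name, "] done in ",
          format(round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)),
          " s")
  val
}

#' Run the full selection scan end-to-end
#'
#' Reads the catalogue and sync files, computes focal-allele frequencies,
#' restricts to markers measured in every sample, down-samples high-coverage
#' samples, windows the frequencies, simulates (or loads) the neutral null,
#' scans and classifies windows at the configured FDR, summarizes class
#' fractions, and profiles window autocorrelation. All tables are written to
#' `out_dir` together with a manifest recording parameters, seed, package
#' version and input checksums. Progress is logged to stderr.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with `scan`, `summary`, `windows`, `null`,
#'   `acf`, `freq`, and `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- .stage("catalog", read_marker_catalog(config$catalog))
  map <- .stage("map", read_recomb_map(config$map))
  reps <- seq_len(config$replicates)
  ft <- .stage("read", {
    c18 <- read_sync(config$sync18, catalog,
                     sample_info(paste0("T18_R", reps), rep(18, length(reps)), reps))
    c29 <- read_sync(config$sync29, catalog,
                     sample_info(paste0("T29_R", reps), rep(29, length(reps)), reps))
    bind_freq_tables(focal_allele_frequency(c18), focal_allele_frequency(c29))
  })
  ft <- .stage("intersect", intersect_samples(ft))
  ft <- .stage("downsample", {
    mean_cov <- colMeans(ft$cov)
    high <- ft$samples$id[mean_cov > 1.5 * config$target_coverage]
    if (length(high)) {
      message("down-sampling ", length(high), " sample(s) to ",
              config$target_coverage, "x: ", paste(high, collapse = ", "))
      downsample_coverage(ft, config$target_coverage, samples = high,
                          seed = config$seed)
    } else ft
  })
  arm_len <- vapply(split(map$end, map$arm), max, numeric(1))
  index <- .stage("window",
                  assign_windows(ft$catalog, config$w,
                                 exclude = config$exclude_chroms,
                                 arm_lengths = arm_len))
  wt <- .stage("afc", window_afc(ft, index, p0 = config$p0))
  null <- .stage("null", {
    if (!is.null(config$null_file)) read_null(config$null_file, p0 = config$p0)
    else {
      cfg <- sim_config(ft$catalog, map, N = config$N,
                        p_geno = config$p0,
                        generations = config$generations,
                        replicates = config$replicates)
      simulate_null(cfg, index, n_runs = config$n_runs, p0 = config$p0,
                    coverage = config$target_coverage, seed = config$seed)
    }
  })
  scan <- .stage("scan", selection_scan(wt, null, fdr = config$fdr))
  summ <- .stage("summary", class_summary(scan))
  prof <- .stage("acf", acf_profiles(wt))

  out <- function(f) file.path(config$out_dir, f)
  .stage("write", {
    export_window_table(wt, out("windows.tsv"))
    write_null(null, out("null.tsv"))
    export_scan(scan, out("scan.tsv"))
    fr <- summ$fractions
    write.table(data.frame(class = rownames(fr), fr, check.names = FALSE),
                out("class_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    export_acf(prof, out("acf.tsv"))
    manifest <- c(
      package = paste0("erscan ", packageVersion("erscan")),
      w = config$w, fdr = config$fdr, n_runs = config$n_runs,
      target_coverage = config$target_coverage, p0 = config$p0,
      N = config$N, generations = config$generations,
      replicates = config$replicates, seed = config$seed,
      exclude_chroms = paste(config$exclude_chroms, collapse = ","),
      vapply(c(catalog = config$catalog, map = config$map,
               sync18 = config$sync18, sync29 = config$sync29),
             function(p) paste0(p, " md5=", unname(tools::md5sum(p))),
             character(1)))
    writeLines(paste(names(manifest), unname(manifest), sep = "="),
               out("manifest.txt"))
  })
  invisible(list(scan = scan, summary = summ, windows = wt, null = null,
                 acf = prof, freq = ft,
                 manifest = out("manifest.txt")))
}
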