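#' Configuration of a synthetic two-stressor E&R experiment
#'
#' Describes a complete synthetic experiment: a two-founder marker
#' catalogue, a recombination map, truth-labelled selection targets, and
#' Pool-Seq read sampling for three replicates at each of two temperature
#' regimes. The defaults mirror the study design the package analyses:
#' census 1500 flies, focal-genotype starting frequency 0.3, 20 generations,
#' three replicates per regime, low coverage in the cold regime
#' (12, 11, 9x) and high coverage in the hot one (123, 107, 133x), so the
#' coverage down-sampling step is exercised exactly as on real data.
#'
#' The synthetic genome has four linkage groups: chromosomes 2 and 3 with
#' two arms each, a third autosome labelled `4`, and X; 2,000 markers per
#' arm placed uniformly at random. Chromosome `4` is a convenience label for
#' a fourth, ordinary autosome used to separate planted classes onto
#' different linkage groups -- it is not a model of the real dot chromosome
#' (pass it to the windowing `exclude` argument to reproduce the study's
#' chromosome set).
#'
#' Planted selection-target regions are placed by a fixed compatibility
#' policy: 20-generation two-founder populations show chromosome-scale
#' hitchhiking, so classes whose definition requires *no* signal at one
#' temperature get a linkage group with no other selection at that
#' temperature. `change 18C only` regions go on chromosome 2,
#' `change 29C only` on chromosome 3, `no temperature effect` on chromosome
#' 4, and `different magnitude` / `different direction` on opposite ends of
#' X. Each region spans `region_markers` markers with a single selected
#' marker at its centre.
#'
#' @param markers_per_arm named integer vector of marker counts per arm
#' @param arm_length named vector of arm lengths (bp)
#' @param rate named vector of recombination rates (cM/Mb) per arm
#' @param regions_per_class named integer vector: number of planted regions
#'   for each non-drift class (names among `change 18C only`,
#'   `change 29C only`, `no temperature effect`, `different magnitude`,
#'   `different direction`); remaining genome drifts
#' @param region_markers markers per planted region (default 500)
#' @param s named list of per-class selection coefficients `c(s18, s29)`
#' @param h dominance coefficient of the focal allele (default 0.5)
#' @param coverage18,coverage29 per-replicate mean Pool-Seq coverages
#' @param N,p_geno,generations,replicates experiment parameters
#' @param seed master seed: the same configuration (including seed) yields
#'   byte-identical output files
#' @return list of class `generator_config`
#' @export
generator_config <- function(
    markers_per_arm = c("2L" = 2000, "2R" = 2000, "3L" = 2000, "3R" = 2000,
                        "4" = 2000, "X" = 2000),
    arm_length = c("2L" = 20e6, "2R" = 20e6, "3L" = 20e6, "3R" = 20e6,
                   "4" = 20e6, "X" = 22e6),
    rate = c("2L" = 2.7, "2R" = 2.7, "3L" = 2.7, "3R" = 2.7, "4" = 2.7,
             "X" = 3.0),
    regions_per_class = c("change 18C only" = 1, "change 29C only" = 1,
                          "no temperature effect" = 1,
                          "different magnitude" = 1,
                          "different direction" = 1),
    region_markers = 500,
    s = list("change 18C only" = c(0.4, 0),
             "change 29C only" = c(0, 0.4),
             "no temperature effect" = c(0.4, 0.4),
             "different magnitude" = c(0.3, 0.6),
             "different direction" = c(-0.4, 0.4)),
    h = 0.5,
    coverage18 = c(12, 11, 9), coverage29 = c(123, 107, 133),
    N = 1500, p_geno = 0.3, generations = 20, replicates = 3,
    seed = 1L) {
  stopifnot(all(names(markers_per_arm) %in% .ARM_ORDER),
            all(names(markers_per_arm) %in% names(arm_length)),
            all(names(markers_per_arm) %in% names(rate)),
            length(coverage18) == replicates,
            length(coverage29) == replicates,
            region_markers >= 1)
  bad <- setdiff(names(regions_per_class), setdiff(.CLASSES, "drift only"))
  if (length(bad)) stop("unknown class(es) in regions_per_class: ",
                        paste(bad, collapse = ", "))
  structure(list(markers_per_arm = markers_per_arm, arm_length = arm_length,
                 rate = rate, regions_per_class = regions_per_class,
                 region_markers = region_markers, s = s, h = h,
                 coverage18 = coverage18, coverage29 = coverage29,
                 N = N, p_geno = p_geno, generations = generations,
                 replicates = replicates, seed = as.integer(seed)),
            class = "generator_config")
}

# fixed class -> linkage-group placement (see generator_config details)
.CLASS_CHROM <- c("change 18C only" = "2", "change 29C only" = "3",
                  "no temperature effect" = "4",
                  "different magnitude" = "X",
                  "different direction" = "X")

# Place truth regions: for each class, its host chromosome's marker rows are
# split into equal blocks (X is halved first between its two classes, the
# different-magnitude half on the left) and one region is centred per block.
.plant_targets <- function(config, catalog) {
  rpc <- config$regions_per_class
  rpc <- rpc[rpc > 0]
  if (!length(rpc)) {
    return(list(truth = NULL, targets = NULL))
  }
  rows_of <- function(ch) which(catalog$chrom == ch)
  spans <- list()
  for (cl in names(rpc)) {
    ch <- .CLASS_CHROM[[cl]]
    rows <- rows_of(ch)
    if (!length(rows)) stop("class '", cl, "' needs chromosome ", ch,
                            " in the synthetic genome")
    if (ch == "X") {
      half <- length(rows) %/% 2
      rows <- if (cl == "different magnitude") rows[seq_len(half)] else
        rows[(half + 1):length(rows)]
    }
    n <- rpc[[cl]]
    if (n * config$region_markers > length(rows))
      stop("class '", cl, "' demands ", n, " region(s) of ",
           config$region_markers, " markers but only ", length(rows),
           " markers are available on its linkage group")
    block <- length(rows) %/% n
    for (k in seq_len(n)) {
      mid <- rows[(k - 1) * block + block %/% 2]
      first <- mid - config$region_markers %/% 2
      last <- first + config$region_markers - 1
      spans[[length(spans) + 1]] <- data.frame(
        class = cl, chrom = ch,
        row_first = first, row_last = last, row_target = mid,
        arm_target = catalog$arm[mid], pos_target = catalog$pos[mid],
        s18 = config$s[[cl]][1], s29 = config$s[[cl]][2], h = config$h,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, spans)
  o <- order(truth$row_first)
  truth <- truth[o, , drop = FALSE]
  if (any(truth$row_first[-1] <= truth$row_last[-nrow(truth)]))
    stop("planted regions overlap; reduce regions_per_class or region_markers")
  lin <- .linear_pos(catalog, config$arm_length)
  truth$lin_first <- lin[truth$row_first]
  truth$lin_last <- lin[truth$row_last]
  targets <- selection_targets(truth$arm_target, truth$pos_target,
                               truth$s18, truth$s29, truth$h)
  list(truth = truth, targets = targets)
}

#' Generate a complete synthetic experiment
#'
#' Builds the marker catalogue and recombination map, plants truth-labelled
#' selection targets, forward-simulates every replicate at both temperature
#' regimes, draws Pool-Seq read counts (coverage ~ Poisson of the
#' replicate's mean, focal reads ~ Binomial at the simulated frequency), and
#' writes one sync file per regime together with the catalogue, map and
#' truth table. Identical configurations produce byte-identical files.
#'
#' @param config a [generator_config()]
#' @param dir output directory (created if needed); NULL skips file output
#' @return list with `catalog`, `map`, `truth`, `targets`, `counts18`,
#'   `counts29` (count tables), `samples` (combined [sample_info()]),
#'   `files` (named paths, if `dir` given) and `config`
#' @export
generate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  # --- catalogue: uniform random marker positions, random biallelic pairs
  arms <- names(config$markers_per_arm)
  arm <- rep(arms, config$markers_per_arm)
  pos <- unlist(lapply(arms, function(a)
    sort(sample.int(config$arm_length[[a]] - 1L, config$markers_per_arm[[a]]))))
  nuc <- c("A", "T", "C", "G")
  focal <- sample(nuc, length(arm), replace = TRUE)
  other <- vapply(focal, function(f) sample(setdiff(nuc, f), 1), character(1))
  catalog <- marker_catalog(arm, pos, focal, other)
  map <- recomb_map(arms, rep(1, length(arms)),
                    config$arm_length[arms] + 1, config$rate[arms])
  planted <- .plant_targets(config, catalog)
  cfg <- sim_config(catalog, map, N = config$N, p_geno = config$p_geno,
                    generations = config$generations,
                    replicates = config$replicates,
                    targets = planted$targets)

  # --- simulate and sample reads; one derived stream per (regime, replicate)
  n <- nrow(catalog)
  make_counts <- function(temp, cov_means) {
    k <- config$replicates
    ids <- paste0("T", temp, "_R", seq_len(k))
    arr <- array(0L, dim = c(n, k, 6), dimnames = list(NULL, ids, .BASES))
    fi <- match(catalog$focal_allele, .BASES)
    oi <- match(catalog$other_allele, .BASES)
    for (r in seq_len(k)) {
      # stream tag 1000+temp keeps replicate streams disjoint from the
      # run-indexed streams of simulate_null under a shared master seed
      f <- simulate_replicate(cfg, temperature = temp,
                              seed = .derive_seed(config$seed, 1000 + temp, r))
      depth <- rpois(n, cov_means[r])      # continues the replicate's stream
      fc <- rbinom(n, depth, f)
      arr[cbind(seq_len(n), r, fi)] <- fc
      arr[cbind(seq_len(n), r, oi)] <- depth - fc
    }
    structure(list(catalog = catalog,
                   samples = sample_info(ids, rep(temp, k), seq_len(k)),
                   counts = arr),
              class = "count_table")
  }
  counts18 <- make_counts(18, config$coverage18)
  counts29 <- make_counts(29, config$coverage29)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(catalog = file.path(dir, "markers.tsv"),
                  map = file.path(dir, "recomb_map.tsv"),
                  sync18 = file.path(dir, "pool_18C.sync"),
                  sync29 = file.path(dir, "pool_29C.sync"),
                  truth = file.path(dir, "truth.tsv"))
    write_marker_catalog(catalog, files$catalog)
    write_recomb_map(map, files$map)
    write_sync(counts18, files$sync18)
    write_sync(counts29, files$sync29)
    if (!is.null(planted$truth))
      write.table(planted$truth, files$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  list(catalog = catalog, map = map, truth = planted$truth,
       targets = planted$targets, counts18 = counts18, counts29 = counts29,
       samples = rbind(counts18$samples, counts29$samples),
       files = files, config = config)
}

#' Compare a scan against the generator's truth table
#'
#' Maps each truth region to the scan windows lying entirely inside it (on
#' the chromosome-linear coordinate) and tabulates assigned class labels per
#' intended class. Windows outside every region are tabulated under intended
#' class `drift only`. Note that hitchhiking around planted targets makes
#' neighbouring drift windows pick up signal; the per-class recall of the
#' planted classes is the headline number.
#'
#' @param scan a `scan_result`
#' @param truth the generator's truth table
#' @param index the `window_index` the scan was run on
#' @param catalog the (intersected) catalogue the index refers to
#' @param arm_lengths arm lengths used for the chromosome-linear coordinate
#'   (use the generator's, via the map)
#' @return list with `confusion` (intended x assigned count matrix),
#'   `recall` (named per-class recall over planted classes) and
#'   `drift_only_fraction` (share of drift-intended windows labelled drift)
#' @export
recovery_report <- function(scan, truth, index, catalog, arm_lengths = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  lin <- .linear_pos(catalog, arm_lengths)
  win_start <- lin[index$first]
  win_end <- lin[index$last]
  key <- paste(index$chrom, index$window)
  skey <- paste(scan$chrom, scan$window)
  intended <- rep("drift only", nrow(scan))
  if (!is.null(truth)) for (i in seq_len(nrow(truth))) {
    inside <- index$chrom == truth$chrom[i] &
      win_start >= truth$lin_first[i] & win_end <= truth$lin_last[i]
    intended[skey %in% key[inside]] <- truth$class[i]
  }
  intended <- factor(intended, levels = .CLASSES)
  confusion <- table(intended = intended, assigned = scan$class)
  planted <- setdiff(rownames(confusion)[rowSums(confusion) > 0], "drift only")
  recall <- vapply(planted, function(cl)
    confusion[cl, cl] / sum(confusion[cl, ]), numeric(1))
  drift_frac <- if (any(intended == "drift only"))
    unname(confusion["drift only", "drift only"] /
             sum(confusion["drift only", ])) else NA_real_
  list(confusion = confusion, recall = recall,
       drift_only_fraction = drift_frac)
}
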