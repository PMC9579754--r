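#' Recombination map
#'
#' Piecewise-constant recombination rates along each arm, in cM/Mb over
#' 1-based intervals `[start, end)`. Intervals must be non-overlapping,
#' sorted, and cover every marker position of the catalogue the map is used
#' with. Males are achiasmatic, so the map applies to female meiosis only.
#'
#' @param arm arm label per interval
#' @param start,end interval bounds (1-based, inclusive start, exclusive end)
#' @param rate recombination rate in cM/Mb (>= 0)
#' @return data frame of class `recomb_map`
#' @export
recomb_map <- function(arm, start, end, rate) {
  m <- data.frame(arm = as.character(arm), start = as.numeric(start),
                  end = as.numeric(end), rate = as.numeric(rate),
                  stringsAsFactors = FALSE)
  .arm_chrom(m$arm)
  if (any(m$rate < 0)) stop("recombination rates must be >= 0")
  if (any(m$end <= m$start)) stop("map intervals must have end > start")
  m <- m[order(match(m$arm, .ARM_ORDER), m$start), , drop = FALSE]
  for (a in unique(m$arm)) {
    s <- m[m$arm == a, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping map intervals on arm ", a)
  }
  rownames(m) <- NULL
  class(m) <- c("recomb_map", "data.frame")
  m
}

#' @rdname recomb_map
#' @param path file path (tab-separated, one-line header:
#'   `arm  start  end  rate_cM_per_Mb`)
#' @export
read_recomb_map <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t")
  recomb_map(x$arm, x$start, x$end, x$rate_cM_per_Mb)
}

#' @rdname recomb_map
#' @param map a `recomb_map`
#' @export
write_recomb_map <- function(map, path) {
  x <- as.data.frame(map)
  names(x)[names(x) == "rate"] <- "rate_cM_per_Mb"
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Selection targets for the forward simulator
#'
#' Each target is one marker position under selection, with a selection
#' coefficient per temperature regime and a dominance coefficient. Genotype
#' fitnesses at a target are 1, 1+h*s, 1+s, multiplied across targets;
#' hemizygous males at X-linked targets have fitness 1 or 1+s.
#'
#' @param arm arm of each target
#' @param pos marker position (bp)
#' @param s18,s29 selection coefficient of the focal allele at 18C and 29C
#' @param h dominance (default 0.5, additive)
#' @return data frame of class `selection_targets`
#' @export
selection_targets <- function(arm, pos, s18, s29, h = 0.5) {
  d <- data.frame(arm = as.character(arm), pos = as.numeric(pos),
                  s18 = as.numeric(s18), s29 = as.numeric(s29),
                  h = as.numeric(h), stringsAsFactors = FALSE)
  .arm_chrom(d$arm)
  class(d) <- c("selection_targets", "data.frame")
  d
}

#' Configuration of a forward simulation
#'
#' Bundles the experiment parameters mirrored by the simulator: census size
#' `N` diploid flies bred each generation, starting fraction `p_geno` of
#' whole flies carrying the focal founder genotype, number of generations,
#' number of replicate populations, the recombination map, and optional
#' selection targets.
#'
#' @param catalog a [marker_catalog()]
#' @param map a [recomb_map()] covering all catalogue positions
#' @param N census size (diploid individuals; default 1500)
#' @param p_geno founder focal-genotype fraction (default 0.3)
#' @param generations generations of evolution (default 20)
#' @param replicates replicate populations per regime (default 3)
#' @param targets optional [selection_targets()]
#' @return list of class `sim_config`
#' @export
sim_config <- function(catalog, map, N = 1500, p_geno = 0.3,
                       generations = 20, replicates = 3, targets = NULL) {
  stopifnot(N >= 2, p_geno >= 0, p_geno <= 1, generations >= 0,
            replicates >= 1)
  if (p_geno > 0 && p_geno < 1) {
    nf <- round(N * p_geno)
    if (nf == 0 || nf == N)
      warning("round(N * p_geno) is ", nf, ": mono-founder population")
  }
  cfg <- structure(list(catalog = catalog, map = map, N = as.integer(N),
                        p_geno = p_geno, generations = as.integer(generations),
                        replicates = as.integer(replicates), targets = targets),
                   class = "sim_config")
  cfg$inputs <- .sim_inputs(cfg)   # validates map support eagerly
  cfg
}

# Translate catalogue + map (+ targets) into the chromosome-linear inputs the
# C++ core consumes: marker positions, piecewise-linear cumulative genetic
# map (Morgans), X flag per chromosome.
.sim_inputs <- function(cfg) {
  catalog <- cfg$catalog
  map <- cfg$map
  arms <- intersect(.ARM_ORDER, unique(catalog$arm))
  if (!all(arms %in% map$arm))
    stop("recombination map missing arm(s): ",
         paste(setdiff(arms, map$arm), collapse = ", "))
  arm_len <- vapply(arms, function(a) max(map$end[map$arm == a]), numeric(1))
  for (a in arms) {
    p <- catalog$pos[catalog$arm == a]
    s <- map[map$arm == a, ]
    if (min(p) < min(s$start) || max(p) >= max(s$end))
      stop("marker outside recombination-map support on arm ", a)
  }
  off <- .arm_offsets(catalog, arm_len)
  chroms <- unique(.arm_chrom(arms))
  chroms <- chroms[order(match(chroms, c("2", "3", "4", "X")))]
  marker_pos <- gmap_pos <- gmap_cm <- vector("list", length(chroms))
  marker_row <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    rows <- which(catalog$chrom == ch)
    marker_row[[ci]] <- rows
    marker_pos[[ci]] <- catalog$pos[rows] + unname(off[catalog$arm[rows]])
    # cumulative genetic map over the concatenated arms
    sub <- map[.arm_chrom(map$arm) == ch, , drop = FALSE]
    sub <- sub[order(match(sub$arm, .ARM_ORDER), sub$start), , drop = FALSE]
    starts <- sub$start + unname(off[sub$arm])
    ends <- sub$end + unname(off[sub$arm])
    morgans <- sub$rate * 1e-8 * (ends - starts)   # cM/Mb -> Morgans total
    k <- length(starts)
    nodes <- numeric(2 * k)
    cm <- numeric(2 * k)
    nodes[seq(1, 2 * k, 2)] <- starts
    nodes[seq(2, 2 * k, 2)] <- ends
    cmend <- cumsum(morgans)
    cm[seq(2, 2 * k, 2)] <- cmend
    cm[seq(1, 2 * k, 2)] <- c(0, cmend[-k])   # gaps add no genetic length
    if (any(diff(nodes) < 0)) stop("map intervals out of order on chromosome ", ch)
    gmap_pos[[ci]] <- nodes
    gmap_cm[[ci]] <- cm
  }
  tg <- cfg$targets
  sel <- list(chrom = integer(), pos = numeric(), s18 = numeric(),
              s29 = numeric(), h = numeric())
  if (!is.null(tg) && nrow(tg)) {
    tch <- .arm_chrom(tg$arm)
    sel$chrom <- match(tch, chroms)
    if (anyNA(sel$chrom)) stop("selection target on arm absent from catalogue")
    sel$pos <- tg$pos + unname(off[tg$arm])
    sel$s18 <- tg$s18
    sel$s29 <- tg$s29
    sel$h <- tg$h
  }
  list(chroms = chroms, marker_pos = marker_pos, marker_row = marker_row,
       gmap_pos = gmap_pos, gmap_cm = gmap_cm, is_x = chroms == "X",
       sel = sel)
}

#' Simulate one replicate population forward in time
#'
#' Runs the individual-based Wright-Fisher simulation (explicit sexes,
#' achiasmatic males, hemizygous X, Poisson crossovers along the genetic
#' map) and returns the focal-allele frequency at every catalogue marker
#' after `generations` generations. On X, allele copies are counted as two
#' per female and one per male.
#'
#' @param cfg a [sim_config()]
#' @param temperature 18 or 29; selects which selection coefficient column
#'   of the targets applies (ignored when there are no targets)
#' @param seed integer seed for this replicate's random stream
#' @return numeric vector of focal-allele frequencies, in catalogue order
#' @export
simulate_replicate <- function(cfg, temperature = 18, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  inp <- cfg$inputs
  s <- if (temperature == 18) inp$sel$s18 else inp$sel$s29
  res <- .wf_simulate_cpp(inp$marker_pos, inp$gmap_pos, inp$gmap_cm,
                          inp$is_x, cfg$N, cfg$p_geno, cfg$generations,
                          as.integer(inp$sel$chrom), inp$sel$pos,
                          as.numeric(s), inp$sel$h)
  out <- numeric(nrow(cfg$catalog))
  for (ci in seq_along(inp$chroms)) out[inp$marker_row[[ci]]] <- res[[ci]]
  out
}

# deterministic per-(run, replicate) stream from a master seed
.derive_seed <- function(master, run, rep) {
  as.integer((as.numeric(master) + 100003 * run + 10007 * rep) %%
               .Machine$integer.max)
}

#' Simulate the neutral null distribution of windowed AFCs
#'
#' Mimics the experimental set-up under pure drift: for each of `n_runs`
#' runs, `cfg$replicates` populations are simulated to generation
#' `cfg$generations`, marker frequencies are averaged per window, and the
#' replicate-mean AFC per window is recorded. All window values of a
#' chromosome, across runs and windows, are pooled into that chromosome's
#' null distribution.
#'
#' Each (run, replicate) pair gets a random stream derived deterministically
#' from `seed`, so the null is reproducible bit-for-bit.
#'
#' With `coverage` set, Pool-Seq measurement noise is layered on every
#' simulated replicate before windowing (per marker, depth ~
#' Poisson(`coverage`), focal reads ~ Binomial(depth, frequency)), so the
#' null reflects drift *and* the sampling noise of the sequenced data at
#' their common (down-sampled) coverage, matching how the observed windows
#' are measured.
#'
#' @param cfg a [sim_config()] without selection targets
#' @param index a `window_index` from [assign_windows()] on `cfg$catalog`
#' @param n_runs number of neutral runs (default 100)
#' @param p0 starting focal frequency used for the AFC (default `cfg$p_geno`)
#' @param coverage optional mean Pool-Seq coverage for measurement noise
#'   (default NULL: window drift-only frequencies)
#' @param seed integer master seed
#' @return a `null_distribution`: data frame `chrom, run, window, afc` with
#'   class attribute, plus attribute `p0`
#' @export
simulate_null <- function(cfg, index, n_runs = 100, p0 = cfg$p_geno,
                          coverage = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), n_runs >= 1)
  if (!is.null(cfg$targets) && nrow(cfg$targets) > 0)
    stop("the neutral null must be simulated without selection targets")
  nw <- nrow(index)
  out <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    reps <- matrix(NA_real_, nw, cfg$replicates)
    for (r in seq_len(cfg$replicates)) {
      f <- simulate_replicate(cfg, temperature = 18,
                              seed = .derive_seed(seed, run, r))
      if (!is.null(coverage)) {   # continues the replicate's stream
        depth <- rpois(length(f), coverage)
        f <- ifelse(depth > 0, rbinom(length(f), depth, f) / depth, NA_real_)
      }
      reps[, r] <- .window_means(f, index)
    }
    out[[run]] <- data.frame(chrom = index$chrom, run = run,
                             window = index$window,
                             afc = rowMeans(reps) - p0,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "p0") <- p0
  class(res) <- c("null_distribution", "data.frame")
  res
}

# unweighted window means of a per-marker vector (missing markers skipped,
# as in the windowing of observed frequencies)
.window_means <- function(x, index) {
  vapply(seq_len(nrow(index)),
         function(i) mean(x[index$first[i]:index$last[i]], na.rm = TRUE),
         numeric(1))
}

#' Read / write a null distribution
#'
#' Tab-separated `chrom, run, window, afc` with a one-line header, so scans
#' can be rerun without resimulating.
#'
#' @param null a `null_distribution`
#' @param path file path
#' @param p0 starting frequency recorded with the file on read
#' @return `read_null` returns a `null_distribution`
#' @export
write_null <- function(null, path) {
  write.table(as.data.frame(null), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path, p0 = 0.3) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(chrom = "character"))
  attr(x, "p0") <- p0
  class(x) <- c("null_distribution", "data.frame")
  x
}
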