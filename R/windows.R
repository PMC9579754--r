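#' Partition catalogue markers into non-overlapping SNP windows
#'
#' Markers are grouped into consecutive windows of exactly `w` markers per
#' chromosome. The two arms of a chromosome are concatenated in order
#' (2L then 2R, 3L then 3R) before windowing, so a window may span the
#' centromere; the trailing markers that do not fill a complete window are
#' dropped by default. The dot chromosome 4 is excluded by default: with two
#' founders it contributes almost no markers and no recombination.
#'
#' @param catalog a [marker_catalog()] (typically after [intersect_samples()])
#' @param w markers per window (>= 1), e.g. 50, 250 or 500
#' @param keep_partial if TRUE, trailing partial windows are kept and
#'   flagged `partial` (diagnostics only; default FALSE)
#' @param exclude chromosomes excluded from windowing (default `"4"`)
#' @param arm_lengths optional named vector of arm lengths (bp) used to place
#'   right-arm markers on the chromosome-linear coordinate; defaults to the
#'   maximum catalogue position per arm
#' @return a data frame of class `window_index`: `chrom`, `window` (ordinal
#'   within chromosome), `first`, `last` (catalogue row indices, inclusive),
#'   `n_markers`, `centre` (midpoint of the first and last marker on the
#'   chromosome-linear coordinate), `partial`
#' @export
assign_windows <- function(catalog, w, keep_partial = FALSE, exclude = "4",
                           arm_lengths = NULL) {
  stopifnot(w >= 1)
  lin <- .linear_pos(catalog, arm_lengths)
  chroms <- setdiff(unique(catalog$chrom), exclude)
  chroms <- chroms[order(match(chroms, c("2", "3", "4", "X")))]
  out <- list()
  for (ch in chroms) {
    idx <- which(catalog$chrom == ch)   # already in arm-concatenated order
    n <- length(idx)
    k <- n %/% w
    n_win <- if (keep_partial && n %% w > 0) k + 1L else k
    if (n_win == 0) next
    first <- idx[(seq_len(n_win) - 1L) * w + 1L]
    last <- idx[pmin(seq_len(n_win) * w, n)]
    out[[ch]] <- data.frame(
      chrom = ch, window = seq_len(n_win), first = first, last = last,
      n_markers = last - first + 1L,
      centre = (lin[first] + lin[last]) / 2,
      partial = seq_len(n_win) * w > n,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warning("no chromosome has at least ", w, " markers; empty window index")
    res <- data.frame(chrom = character(), window = integer(),
                      first = integer(), last = integer(),
                      n_markers = integer(), centre = numeric(),
                      partial = logical())
  } else res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("window_index", "data.frame")
  res
}

#' Windowed focal-allele frequencies and allele frequency changes
#'
#' Averages marker frequencies within each window (unweighted mean over the
#' window's non-missing markers, per replicate) and expresses the result as
#' an allele frequency change `AFC = window frequency - p0`, where `p0` is
#' the focal founder's starting frequency. Positive AFC means the focal
#' founder's allele rose. Per temperature, the window's AFC is the mean over
#' replicates, with standard error `sd / sqrt(R)` and 95% confidence
#' interval `mean +/- 1.96 se`.
#'
#' @param ft a `freq_table` covering all samples (see [bind_freq_tables()])
#' @param index a `window_index` from [assign_windows()] built on the same
#'   catalogue
#' @param p0 starting focal-genotype frequency (default 0.3)
#' @return a `window_table`: list with `index`, `temps`, `p0`, and arrays
#'   `freq` and `afc` (window x replicate x temperature), plus matrices
#'   `mean`, `se`, `lo`, `hi` (window x temperature). Windows where a sample
#'   has no measured marker are NA throughout.
#' @export
window_afc <- function(ft, index, p0 = 0.3) {
  stopifnot(inherits(ft, "freq_table"), inherits(index, "window_index"))
  temps <- sort(unique(ft$samples$temperature))
  reps <- sort(unique(ft$samples$replicate))
  nw <- nrow(index)
  freq <- array(NA_real_, c(nw, length(reps), length(temps)),
                dimnames = list(NULL, paste0("rep", reps), paste0("T", temps)))
  # window id per catalogue row (NA outside complete windows)
  wid <- rep(NA_integer_, nrow(ft$catalog))
  for (i in seq_len(nw)) wid[index$first[i]:index$last[i]] <- i
  inwin <- !is.na(wid)
  g <- wid[inwin]
  for (ti in seq_along(temps)) for (ri in seq_along(reps)) {
    col <- which(ft$samples$temperature == temps[ti] &
                 ft$samples$replicate == reps[ri])
    if (length(col) != 1) next
    x <- ft$freq[inwin, col]
    sums <- rowsum(ifelse(is.na(x), 0, x), g)
    ns <- rowsum(as.numeric(!is.na(x)), g)
    m <- ifelse(ns > 0, sums / ns, NA_real_)
    freq[as.integer(rownames(sums)), ri, ti] <- m
  }
  afc <- freq - p0
  mean_afc <- apply(afc, c(1, 3), mean)
  sd_afc <- apply(afc, c(1, 3), sd)
  se <- sd_afc / sqrt(length(reps))
  structure(list(index = index, temps = temps, reps = reps, p0 = p0,
                 freq = freq, afc = afc, mean = mean_afc, se = se,
                 lo = mean_afc - 1.96 * se, hi = mean_afc + 1.96 * se),
            class = "window_table")
}

#' Export a window table as a tidy tab-separated file
#'
#' One row per window and temperature: chromosome, window ordinal, centre,
#' per-replicate AFCs, replicate-mean AFC, standard error and 95% CI bounds.
#'
#' @param wt a `window_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_window_table <- function(wt, path) {
  stopifnot(inherits(wt, "window_table"))
  rows <- list()
  for (ti in seq_along(wt$temps)) {
    d <- data.frame(wt$index[, c("chrom", "window", "centre")],
                    temperature = wt$temps[ti])
    reps <- wt$afc[, , ti, drop = FALSE]
    for (ri in seq_along(wt$reps))
      d[[paste0("afc_rep", wt$reps[ri])]] <- reps[, ri, 1]
    d$afc_mean <- wt$mean[, ti]
    d$afc_se <- wt$se[, ti]
    d$ci_lo <- wt$lo[, ti]
    d$ci_hi <- wt$hi[, ti]
    rows[[ti]] <- d
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
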