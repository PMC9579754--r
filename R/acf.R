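#' Autocorrelation profile of a window series
#'
#' Sample autocorrelation of window-mean frequencies along one chromosome
#' (computed with [stats::acf()]): the value at lag `k` is the correlation
#' between windows `i` and `i + k`. The profile records the first lag at
#' which the autocorrelation drops below the 5% significance bound
#' `1.96 / sqrt(n)` (`n` = number of windows) -- a rough proxy for the
#' decorrelation distance -- and converts that lag to base pairs using the
#' mean spacing of the window centres.
#'
#' @param series numeric vector of window-mean frequencies along one
#'   chromosome (length >= 3, non-constant)
#' @param max_lag maximum lag, default `min(n - 1, 10 * log10(n))`
#' @param centres optional window-centre coordinates (bp) for the
#'   lag-to-distance conversion
#' @return list of class `acf_profile`: `lag`, `acf`, `n`, `bound`,
#'   `first_below` (smallest lag with acf below the bound, NA if none within
#'   `max_lag`), `spacing` (mean centre spacing, NA without `centres`) and
#'   `distance_bp` (`first_below * spacing`)
#' @export
acf_profile <- function(series, max_lag = NULL, centres = NULL) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains missing values")
  n <- length(series)
  if (n < 3) stop("need at least 3 windows")
  if (sd(series) == 0) stop("constant series: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- min(n - 1, floor(10 * log10(n)))
  a <- acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  vals <- as.numeric(a$acf)
  lags <- as.integer(a$lag)
  bound <- 1.96 / sqrt(n)
  below <- which(vals < bound & lags >= 1)
  first_below <- if (length(below)) lags[below[1]] else NA_integer_
  spacing <- if (!is.null(centres)) mean(diff(sort(centres))) else NA_real_
  structure(list(lag = lags, acf = vals, n = n, bound = bound,
                 first_below = first_below, spacing = spacing,
                 distance_bp = first_below * spacing),
            class = "acf_profile")
}

#' Autocorrelation profiles per chromosome and replicate
#'
#' Applies [acf_profile()] to the windowed frequency series of each
#' chromosome, replicate and temperature of a `window_table`. With
#' `pooled = TRUE` the replicate-mean series is profiled instead.
#'
#' @param wt a `window_table`
#' @param max_lag maximum lag passed to [acf_profile()]
#' @param pooled profile the replicate-mean series (default FALSE: one
#'   profile per replicate)
#' @return data frame: `chrom`, `temperature`, `replicate` (NA when pooled),
#'   `lag`, `acf`, `bound`, `below` flag
#' @export
acf_profiles <- function(wt, max_lag = NULL, pooled = FALSE) {
  stopifnot(inherits(wt, "window_table"))
  out <- list()
  for (ch in unique(wt$index$chrom)) {
    rows <- which(wt$index$chrom == ch)
    centres <- wt$index$centre[rows]
    for (ti in seq_along(wt$temps)) {
      series_set <- if (pooled) {
        list(pooled = rowMeans(wt$freq[rows, , ti, drop = FALSE][, , 1]))
      } else {
        setNames(lapply(seq_along(wt$reps),
                        function(ri) wt$freq[rows, ri, ti]),
                 wt$reps)
      }
      for (nm in names(series_set)) {
        s <- series_set[[nm]]
        if (anyNA(s) || sd(s) == 0) next
        pr <- acf_profile(s, max_lag = max_lag, centres = centres)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, temperature = wt$temps[ti],
          replicate = if (pooled) NA_integer_ else as.integer(nm),
          lag = pr$lag, acf = pr$acf, bound = pr$bound,
          below = pr$acf < pr$bound & pr$lag >= 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' @rdname acf_profiles
#' @param profiles output of [acf_profiles()]
#' @param path output path (tab-separated with header)
#' @export
export_acf <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
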