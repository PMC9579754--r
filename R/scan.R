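#' Empirical p-value of a windowed AFC against a simulated null
#'
#' Directional empirical p-value: for a positive observed AFC, the fraction
#' of null values strictly greater than it; for a negative observed AFC, the
#' fraction strictly smaller. An observed AFC of exactly 0 gives p = 1 (no
#' evidence of change). No pseudocount is added, so p = 0 is possible and is
#' a legal input to the BH correction.
#'
#' @param observed numeric vector of observed window AFCs
#' @param null numeric vector of simulated window-mean AFCs (the pooled null
#'   of the relevant chromosome)
#' @return numeric vector of p-values in `[0, 1]`
#' @export
empirical_pvalue <- function(observed, null) {
  if (!length(null)) stop("empty null distribution")
  n <- length(null)
  srt <- sort(null)
  # #{null > x} and #{null < x} via binary search on the sorted null
  gt <- n - findInterval(observed, srt)                      # strictly greater
  lt <- findInterval(observed, srt, left.open = TRUE)        # strictly smaller
  p <- ifelse(observed > 0, gt / n, ifelse(observed < 0, lt / n, 1))
  p[is.na(observed)] <- NA_real_
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()]), with input validation. The scan applies it per
#' chromosome.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed, passed
#'   through)
#' @return adjusted p-values in input order
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-window linear model contrasting the two temperature regimes
#'
#' Fits `AFC ~ temperature` with temperature as a categorical factor and the
#' colder regime as reference: the intercept estimates the mean AFC at 18C
#' and the temperature coefficient the 29C - 18C contrast. The p-value of
#' the temperature coefficient (equivalent to a pooled-variance two-sample
#' t-test on 4 degrees of freedom with three replicates per regime) tests
#' whether the response differs between regimes.
#'
#' Degenerate inputs: with zero residual variance the p-value is 1 when the
#' contrast is 0 and 0 otherwise.
#'
#' @param afc18,afc29 replicate AFCs of one window at 18C and 29C
#' @return list with `intercept`, `temperature` (contrast estimate) and
#'   `p` (two-sided p-value of the contrast)
#' @export
fit_window_lm <- function(afc18, afc29) {
  stopifnot(length(afc18) >= 2, length(afc29) >= 2,
            all(is.finite(afc18)), all(is.finite(afc29)))
  # OLS estimates of a one-factor model are the group means; computing them
  # directly keeps the intercept *exactly* the 18C mean
  intercept <- mean(afc18)
  ctr <- mean(afc29) - intercept
  if (var(afc18) + var(afc29) == 0) {
    p <- if (abs(ctr) < .Machine$double.eps^0.5) 1 else 0
  } else {
    d <- data.frame(afc = c(afc18, afc29),
                    temp = factor(rep(c("18", "29"),
                                      c(length(afc18), length(afc29))),
                                  levels = c("18", "29")))
    fit <- lm(afc ~ temp, data = d)
    p <- summary(fit)$coefficients["temp29", "Pr(>|t|)"]
  }
  list(intercept = intercept, temperature = ctr, p = p)
}

.CLASSES <- c("drift only", "change 18C only", "change 29C only",
              "no temperature effect", "different magnitude",
              "different direction")

#' Six-class selection-response decision tree
#'
#' Assigns each window exactly one label from the significance of its AFC
#' against the neutral null at each temperature (`sig18`, `sig29`), the
#' significance of the temperature contrast (`sig_lm`), and the signs of the
#' observed replicate-mean AFCs:
#'
#' * neither temperature significant: `drift only`
#' * significant at one temperature: `change 18C only` / `change 29C only`
#' * both significant, contrast not: `no temperature effect`
#' * both significant, contrast significant, AFCs of the same sign:
#'   `different magnitude`
#' * both significant, contrast significant, AFCs of opposite sign:
#'   `different direction`
#'
#' Direction is taken from the signs of the two observed mean AFCs. The
#' alternative reading based on the signs of the model coefficients
#' (intercept vs contrast) mislabels same-direction responses of smaller
#' magnitude (e.g. +0.2 at 18C and +0.1 at 29C have coefficients +0.2 and
#' -0.1) as direction changes, so it is not used. Windows significant at
#' both temperatures with opposite-sign AFCs but a non-significant contrast
#' fall in `no temperature effect` (the only remaining branch).
#'
#' @param sig18,sig29,sig_lm logical vectors of significance calls
#' @param afc18,afc29 observed replicate-mean AFCs per window
#' @return factor of class labels with levels in fixed order
#' @export
classify_windows <- function(sig18, sig29, sig_lm, afc18, afc29) {
  n <- length(sig18)
  stopifnot(length(sig29) == n, length(sig_lm) == n,
            length(afc18) == n, length(afc29) == n)
  lab <- character(n)
  same_dir <- afc18 * afc29 > 0
  lab[!sig18 & !sig29] <- "drift only"
  lab[sig18 & !sig29] <- "change 18C only"
  lab[!sig18 & sig29] <- "change 29C only"
  both <- sig18 & sig29
  lab[both & !sig_lm] <- "no temperature effect"
  lab[both & sig_lm & same_dir] <- "different magnitude"
  lab[both & sig_lm & !same_dir] <- "different direction"
  factor(lab, levels = .CLASSES)
}

#' Scan windows for selection signatures and classify them
#'
#' Runs the complete per-window inference: empirical p-values against the
#' chromosome's pooled neutral null at each temperature, BH adjustment per
#' chromosome, the per-window temperature-contrast linear model with BH
#' adjustment per chromosome over the non-neutral windows only (windows
#' already significant at at least one temperature), and the six-class
#' assignment at the given FDR threshold.
#'
#' @param wt a `window_table` from [window_afc()] holding both temperatures
#' @param null a `null_distribution` from [simulate_null()] on the same
#'   window index
#' @param fdr FDR threshold for all three significance calls (default 0.10)
#' @param temps the two temperatures compared (default `c(18, 29)`)
#' @return data frame of class `scan_result`: per window `chrom`, `window`,
#'   `centre`, `afc18`, `afc29`, `p18`, `p29`, `adj_p18`, `adj_p29`,
#'   `alpha_intercept`, `alpha_temperature`, `p_lm`, `adj_p_lm`, `class`,
#'   plus attribute `fdr`. Windows missing at either temperature are
#'   dropped, with the count reported in attribute `n_dropped`.
#' @export
selection_scan <- function(wt, null, fdr = 0.10, temps = c(18, 29)) {
  stopifnot(inherits(wt, "window_table"), inherits(null, "null_distribution"))
  t1 <- match(temps[1], wt$temps)
  t2 <- match(temps[2], wt$temps)
  if (anyNA(c(t1, t2))) stop("window table lacks temperature(s) ",
                             paste(temps, collapse = "/"))
  res <- data.frame(wt$index[, c("chrom", "window", "centre")],
                    afc18 = wt$mean[, t1], afc29 = wt$mean[, t2],
                    stringsAsFactors = FALSE)
  miss <- is.na(res$afc18) | is.na(res$afc29)
  n_dropped <- sum(miss)
  if (n_dropped)
    message(n_dropped, " window(s) missing in at least one temperature: excluded")
  keep <- which(!miss)
  res <- res[keep, , drop = FALSE]

  null_by_chrom <- split(null$afc, null$chrom)
  res$p18 <- NA_real_; res$p29 <- NA_real_
  res$adj_p18 <- NA_real_; res$adj_p29 <- NA_real_
  for (ch in unique(res$chrom)) {
    nv <- null_by_chrom[[ch]]
    if (is.null(nv)) stop("null distribution has no values for chromosome ", ch)
    i <- res$chrom == ch
    res$p18[i] <- empirical_pvalue(res$afc18[i], nv)
    res$p29[i] <- empirical_pvalue(res$afc29[i], nv)
    res$adj_p18[i] <- bh_adjust(res$p18[i])
    res$adj_p29[i] <- bh_adjust(res$p29[i])
  }

  lm_fit <- lapply(keep, function(i)
    fit_window_lm(wt$afc[i, , t1], wt$afc[i, , t2]))
  res$alpha_intercept <- vapply(lm_fit, `[[`, numeric(1), "intercept")
  res$alpha_temperature <- vapply(lm_fit, `[[`, numeric(1), "temperature")
  res$p_lm <- vapply(lm_fit, `[[`, numeric(1), "p")

  sig18 <- res$adj_p18 <= fdr
  sig29 <- res$adj_p29 <= fdr
  # contrast model adjusted per chromosome over non-neutral windows only
  res$adj_p_lm <- NA_real_
  nonneutral <- sig18 | sig29
  for (ch in unique(res$chrom)) {
    i <- which(res$chrom == ch & nonneutral)
    if (length(i)) res$adj_p_lm[i] <- bh_adjust(res$p_lm[i])
  }
  sig_lm <- !is.na(res$adj_p_lm) & res$adj_p_lm <= fdr
  res$class <- classify_windows(sig18, sig29, sig_lm, res$afc18, res$afc29)
  attr(res, "fdr") <- fdr
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Summarize class fractions per chromosome and genome-wide
#'
#' Fractions of windows per class, per chromosome (summing to 1 within each
#' chromosome) and genome-wide. The genome-wide value is the unweighted mean
#' of the per-chromosome fractions; `weighted = TRUE` instead weights
#' chromosomes by their window counts. Also reports, among
#' `different magnitude` windows, the share whose AFC is more extreme at
#' 29C.
#'
#' @param scan a `scan_result`
#' @param weighted use window-weighted genome-wide fractions (default FALSE)
#' @return list with `fractions` (class x chromosome matrix including a `GW`
#'   column) and `more_extreme_at_29` (proportion, NA if no
#'   different-magnitude window)
#' @export
class_summary <- function(scan, weighted = FALSE) {
  stopifnot(inherits(scan, "scan_result"))
  tab <- table(scan$class, scan$chrom)
  frac <- prop.table(tab, margin = 2)
  gw <- if (weighted) {
    as.numeric(table(scan$class) / nrow(scan))
  } else {
    rowMeans(frac)
  }
  fractions <- cbind(as.matrix(frac), GW = gw)
  dm <- scan$class == "different magnitude"
  more29 <- if (any(dm)) mean(abs(scan$afc29[dm]) > abs(scan$afc18[dm])) else NA_real_
  list(fractions = fractions, more_extreme_at_29 = more29)
}

#' Rerun the classification over several FDR thresholds
#'
#' @param wt a `window_table`
#' @param null a `null_distribution`
#' @param fdrs FDR thresholds (default 5%, 10%, 15%)
#' @return named list of `scan_result`s, one per threshold
#' @export
fdr_sweep <- function(wt, null, fdrs = c(0.05, 0.10, 0.15)) {
  setNames(lapply(fdrs, function(q) selection_scan(wt, null, fdr = q)),
           paste0("fdr", fdrs * 100))
}

#' Export a scan result as a tab-separated file
#'
#' @param scan a `scan_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
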