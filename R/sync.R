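#' @name sync-format
#' @title PoPoolation2 sync format conventions
#' @description
#' Pool-Seq allele counts are exchanged in the PoPoolation2 "sync" format:
#' tab-separated columns `chromosome` (arm name), `position` (1-based),
#' `reference base`, then one column per sample holding colon-separated
#' counts `A:T:C:G:N:del`. Throughout the package, *coverage* at a marker is
#' the nucleotide depth A+T+C+G; `N` and deletion counts are excluded.
#' Allele-frequency computation is biallelic: only reads matching the two
#' parental alleles are informative, third-allele reads are ignored and
#' tallied per sample.
NULL

.BASES <- c("A", "T", "C", "G", "N", "del")

#' Describe the samples of a Pool-Seq experiment
#'
#' @param id sample identifiers (unique)
#' @param temperature rearing temperature of each sample, in degrees Celsius
#'   (the study regimes are 18 and 29)
#' @param replicate replicate number within temperature (1, 2, 3, ...)
#' @return data frame with columns `id`, `temperature`, `replicate`
#' @export
sample_info <- function(id, temperature, replicate) {
  stopifnot(!anyDuplicated(id))
  data.frame(id = as.character(id), temperature = as.numeric(temperature),
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

#' Read a sync file at catalogue markers
#'
#' Parses a PoPoolation2 sync file and returns nucleotide counts at the
#' catalogue's markers, in catalogue order. Markers absent from the file are
#' flagged missing (NA counts). Lines on chromosomes (arms) not present in
#' the catalogue are skipped with a warning.
#'
#' @param path sync file path
#' @param catalog a [marker_catalog()]
#' @param samples optional [sample_info()] for the sample columns (defaults
#'   to ids `S1..Sk`, temperature and replicate NA)
#' @return a `count_table`: list with `catalog`, `samples`, and `counts`, a
#'   3-d array (marker x sample x base) with bases `A,T,C,G,N,del`
#' @export
read_sync <- function(path, catalog, samples = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty sync file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("sync line ", which(nf < 4)[1], ": fewer than 4 columns")
  if (length(unique(nf)) != 1)
    stop("sync line ", which(nf != nf[1])[1], ": inconsistent column count")
  n_samp <- nf[1] - 3L
  mat <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  arm <- mat[, 1]
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos)) stop("sync line ", which(is.na(pos))[1], ": bad position")

  known <- arm %in% unique(catalog$arm)
  if (!all(known)) {
    warning("skipping ", sum(!known), " line(s) on chromosome(s) not in the ",
            "catalogue: ", paste(unique(arm[!known]), collapse = ", "))
  }

  if (is.null(samples))
    samples <- sample_info(paste0("S", seq_len(n_samp)), rep(NA_real_, n_samp),
                           rep(NA_integer_, n_samp))
  if (nrow(samples) != n_samp)
    stop("sample_info has ", nrow(samples), " rows but file has ", n_samp,
         " sample columns")

  counts <- array(NA_integer_,
                  dim = c(nrow(catalog), n_samp, 6),
                  dimnames = list(NULL, samples$id, .BASES))
  hit <- match(paste(arm, pos), paste(catalog$arm, catalog$pos))
  use <- which(!is.na(hit) & known)
  for (j in seq_len(n_samp)) {
    col <- mat[, 3 + j]
    parts <- strsplit(col[use], ":", fixed = TRUE)
    bad <- lengths(parts) != 6
    if (any(bad))
      stop("sync line ", use[bad][1], ": count column ", j,
           " does not have 6 fields")
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      badline <- use[ceiling(which(is.na(v))[1] / 6)]
      stop("sync line ", badline, ": non-integer count in column ", j)
    }
    counts[hit[use], j, ] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  structure(list(catalog = catalog, samples = samples, counts = counts),
            class = "count_table")
}

#' Write a count table as a sync file
#'
#' Inverse of [read_sync()]: one line per catalogue marker in catalogue
#' order, reference base set to the focal allele. Markers missing in every
#' sample are omitted from the file, which is how absence is represented in
#' sync data; [read_sync()] flags them missing again on the way back in.
#'
#' @param counts a `count_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sync <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  cat_ <- counts$catalog
  arr <- counts$counts
  present <- apply(!is.na(arr[, , 1, drop = FALSE]), 1, any)
  cols <- apply(arr, 2, function(m) {
    m[is.na(m)] <- 0L
    apply(m, 1, paste, collapse = ":")
  })
  cols <- matrix(cols, nrow = nrow(cat_))
  out <- cbind(cat_$arm, cat_$pos, cat_$focal_allele, cols)[present, , drop = FALSE]
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Focal-allele frequencies from nucleotide counts
#'
#' For each sample and marker, the focal-founder allele frequency is
#' `focal / (focal + other)` using only reads matching the two parental
#' alleles. Markers with zero informative reads in a sample are flagged
#' missing (NA), never reported as frequency 0. Reads matching neither
#' parental allele are ignored and tallied per sample.
#'
#' @param counts a `count_table` aligned to its catalogue
#' @return a `freq_table`: list with `catalog`, `samples`, `freq` and `cov`
#'   (marker x sample matrices; `cov` is informative coverage focal+other),
#'   `depth` (nucleotide depth A+T+C+G) and `ignored` (per-sample tally of
#'   third-allele reads)
#' @export
focal_allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  cat_ <- counts$catalog
  arr <- counts$counts
  n <- nrow(cat_)
  k <- ncol(arr)
  fi <- match(cat_$focal_allele, .BASES)
  oi <- match(cat_$other_allele, .BASES)
  focal <- other <- depth <- matrix(NA_integer_, n, k,
                                    dimnames = list(NULL, counts$samples$id))
  for (j in seq_len(k)) {
    m <- matrix(arr[, j, ], nrow = n)
    focal[, j] <- m[cbind(seq_len(n), fi)]
    other[, j] <- m[cbind(seq_len(n), oi)]
    depth[, j] <- rowSums(m[, 1:4, drop = FALSE])
  }
  cov <- focal + other
  freq <- ifelse(cov > 0, focal / cov, NA_real_)
  ignored <- colSums(depth - cov, na.rm = TRUE)
  structure(list(catalog = cat_, samples = counts$samples, freq = freq,
                 cov = cov, depth = depth, ignored = ignored),
            class = "freq_table")
}

#' Combine frequency tables from several sync sources
#'
#' Column-binds `freq_table`s that share one catalogue (e.g. one table per
#' temperature) into a single table covering all samples.
#'
#' @param ... `freq_table`s sharing the same catalogue
#' @return a combined `freq_table`
#' @export
bind_freq_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1, all(vapply(tabs, inherits, TRUE, "freq_table")))
  cat_ <- tabs[[1]]$catalog
  for (t in tabs)
    if (!identical(as.data.frame(t$catalog), as.data.frame(cat_)))
      stop("frequency tables do not share one catalogue")
  structure(list(
    catalog = cat_,
    samples = do.call(rbind, lapply(tabs, `[[`, "samples")),
    freq = do.call(cbind, lapply(tabs, `[[`, "freq")),
    cov = do.call(cbind, lapply(tabs, `[[`, "cov")),
    depth = do.call(cbind, lapply(tabs, `[[`, "depth")),
    ignored = do.call(c, lapply(tabs, `[[`, "ignored"))),
    class = "freq_table")
}

#' Restrict to markers measured in every sample
#'
#' Keeps only markers with informative coverage in all samples (both
#' temperatures), so that windowed comparisons between regimes use an
#' identical marker set. Reports the retained count per arm.
#'
#' @param ft a `freq_table` holding all samples of the experiment
#' @return the filtered `freq_table`, with attribute `retained_per_arm`
#' @export
intersect_samples <- function(ft) {
  stopifnot(inherits(ft, "freq_table"))
  keep <- rowSums(is.na(ft$freq)) == 0
  if (!any(keep)) stop("no marker is measured in every sample")
  out <- ft
  cat_ <- ft$catalog[keep, , drop = FALSE]
  rownames(cat_) <- NULL
  class(cat_) <- class(ft$catalog)
  out$catalog <- cat_
  out$freq <- ft$freq[keep, , drop = FALSE]
  out$cov <- ft$cov[keep, , drop = FALSE]
  out$depth <- ft$depth[keep, , drop = FALSE]
  per_arm <- table(factor(cat_$arm, levels = intersect(.ARM_ORDER, unique(ft$catalog$arm))))
  attr(out, "retained_per_arm") <- per_arm
  message("retained ", sum(keep), "/", length(keep), " markers (",
          paste(names(per_arm), as.integer(per_arm), sep = ":", collapse = ", "), ")")
  out
}

#' Down-sample coverage to equalize Pool-Seq noise between regimes
#'
#' Re-samples each marker's measurement to a target mean coverage: a new
#' coverage is drawn from Poisson(`target_mean`), then a new focal-allele
#' count from Binomial(new coverage, old frequency), mimicking Pool-Seq
#' sampling noise at the lower depth. A drawn coverage of 0 flags the marker
#' missing in that sample.
#'
#' Each selected sample gets its own random stream, derived deterministically
#' from `seed` and the sample's column index (in `samples` order), so results
#' are reproducible regardless of which subset is down-sampled.
#'
#' @param ft a `freq_table`
#' @param target_mean target mean coverage (reads), e.g. 12
#' @param samples character ids of the samples to down-sample; default all
#' @param seed integer master seed
#' @return the `freq_table` with down-sampled `freq` and `cov` for the
#'   selected samples
#' @export
downsample_coverage <- function(ft, target_mean, samples = ft$samples$id,
                                seed = 1L) {
  stopifnot(inherits(ft, "freq_table"), target_mean > 0)
  cols <- match(samples, ft$samples$id)
  if (anyNA(cols)) stop("unknown sample id(s): ",
                        paste(samples[is.na(cols)], collapse = ", "))
  out <- ft
  n <- nrow(ft$freq)
  for (j in cols) {
    set.seed((seed + 7919L * j) %% .Machine$integer.max)
    cstar <- rpois(n, target_mean)
    old <- ft$freq[, j]
    newcount <- rep(NA_integer_, n)
    ok <- !is.na(old) & cstar > 0
    newcount[ok] <- rbinom(sum(ok), cstar[ok], old[ok])
    out$freq[, j] <- ifelse(ok, newcount / cstar, NA_real_)
    out$cov[, j] <- ifelse(is.na(old), NA_integer_, cstar)
    out$cov[!ok & !is.na(old), j] <- 0L
    out$freq[!ok & !is.na(old), j] <- NA_real_
  }
  out
}
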