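#' @useDynLib erscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats acf lm p.adjust rbinom rpois sd setNames var
#' @importFrom utils read.table write.table packageVersion
NULL

# canonical arm ordering: arms of one chromosome are adjacent, left arm first
.ARM_ORDER <- c("2L", "2R", "3L", "3R", "4", "X")

.arm_chrom <- function(arm) {
  chrom <- sub("[LR]$", "", arm)
  bad <- !chrom %in% c("2", "3", "4", "X")
  if (any(bad)) stop("unknown arm name(s): ", paste(unique(arm[bad]), collapse = ", "))
  chrom
}

#' Construct a marker-SNP catalogue
#'
#' A marker catalogue lists the sites at which the two founder strains carry
#' (nearly) fixed different alleles, so that the focal founder's allele
#' frequency in an evolved Pool-Seq sample measures founder ancestry at that
#' site. Records are sorted by chromosome, arm (left arm before right arm)
#' and position; positions are 1-based as in the sync format.
#'
#' @param arm chromosome arm label (one of 2L, 2R, 3L, 3R, 4, X)
#' @param pos 1-based base-pair position
#' @param focal_allele nucleotide carried by the focal founder
#' @param other_allele nucleotide carried by the alternative founder
#' @return a data frame of class `marker_catalog` with columns `chrom`,
#'   `arm`, `pos`, `focal_allele`, `other_allele`, sorted canonically.
#' @export
marker_catalog <- function(arm, pos, focal_allele, other_allele) {
  arm <- as.character(arm)
  if (length(arm) == 1) arm <- rep(arm, length(pos))
  chrom <- .arm_chrom(arm)
  if (length(focal_allele) == 1) focal_allele <- rep(focal_allele, length(arm))
  if (length(other_allele) == 1) other_allele <- rep(other_allele, length(arm))
  stopifnot(length(pos) == length(arm), length(focal_allele) == length(arm),
            length(other_allele) == length(arm))
  cat <- data.frame(chrom = chrom, arm = arm, pos = as.integer(pos),
                    focal_allele = toupper(as.character(focal_allele)),
                    other_allele = toupper(as.character(other_allele)),
                    stringsAsFactors = FALSE)
  if (any(cat$focal_allele == cat$other_allele))
    stop("focal and other allele identical at ",
         sum(cat$focal_allele == cat$other_allele), " site(s)")
  ok_nuc <- c("A", "T", "C", "G")
  if (!all(cat$focal_allele %in% ok_nuc) || !all(cat$other_allele %in% ok_nuc))
    stop("alleles must be A, C, G or T")
  o <- order(match(cat$arm, .ARM_ORDER), cat$pos)
  cat <- cat[o, , drop = FALSE]
  dup <- duplicated(cat[, c("arm", "pos")])
  if (any(dup))
    stop("duplicate (arm, position) pairs, e.g. ",
         cat$arm[dup][1], ":", cat$pos[dup][1])
  rownames(cat) <- NULL
  class(cat) <- c("marker_catalog", "data.frame")
  cat
}

#' Build a marker catalogue from two parental genotype call sets
#'
#' Retains sites that are (nearly) fixed differences between the two parents:
#' one parent genotyped 0/0 with alternate-allele frequency below
#' `freq_low`, the other 1/1 with alternate-allele frequency above
#' `freq_high`. The allele carried by the focal parent at each retained site
#' becomes the catalogue's focal allele.
#'
#' @param calls_focal,calls_other data frames with columns `arm`, `pos`,
#'   `ref`, `alt`, `gt` (genotype string, `"0/0"`, `"1/1"` or anything else),
#'   and `alt_freq` (alternate-allele frequency estimate), covering the same
#'   sites. `calls_focal` is the focal founder.
#' @param freq_low,freq_high residual-heterozygosity bounds on the
#'   alternate-allele frequency: a 0/0 call must have `alt_freq < freq_low`,
#'   a 1/1 call `alt_freq > freq_high`. Defaults 0.05 and 0.95.
#' @return a [marker_catalog()]
#' @export
build_marker_catalog <- function(calls_focal, calls_other,
                                 freq_low = 0.05, freq_high = 0.95) {
  need <- c("arm", "pos", "ref", "alt", "gt", "alt_freq")
  for (nm in list(calls_focal, calls_other))
    if (!all(need %in% names(nm)))
      stop("parental call tables need columns: ", paste(need, collapse = ", "))
  key_f <- paste(calls_focal$arm, calls_focal$pos)
  key_o <- paste(calls_other$arm, calls_other$pos)
  shared <- intersect(key_f, key_o)
  a <- calls_focal[match(shared, key_f), , drop = FALSE]
  b <- calls_other[match(shared, key_o), , drop = FALSE]
  bad_ref <- a$ref != b$ref
  if (any(bad_ref))
    stop("inconsistent reference allele between parents at ",
         a$arm[bad_ref][1], ":", a$pos[bad_ref][1])

  pass1 <- function(gt, af) gt == "0/0" & af < freq_low   # confidently ref
  pass2 <- function(gt, af) gt == "1/1" & af > freq_high  # confidently alt
  keep_fa <- pass1(a$gt, a$alt_freq) & pass2(b$gt, b$alt_freq)  # focal=ref
  keep_fb <- pass2(a$gt, a$alt_freq) & pass1(b$gt, b$alt_freq)  # focal=alt
  keep <- keep_fa | keep_fb
  if (!any(keep)) stop("no fixed-difference markers found")
  focal <- ifelse(keep_fa[keep], a$ref[keep], a$alt[keep])
  other <- ifelse(keep_fa[keep], a$alt[keep], a$ref[keep])
  marker_catalog(a$arm[keep], a$pos[keep], focal, other)
}

#' Read / write a marker catalogue
#'
#' Tab-separated with a one-line header: `chrom`, `arm`, `pos`,
#' `focal_allele`, `other_allele`.
#'
#' @param path file path
#' @param catalog a [marker_catalog()]
#' @return `read_marker_catalog` returns a [marker_catalog()];
#'   `write_marker_catalog` returns `path` invisibly.
#' @export
read_marker_catalog <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", colClasses = c(
    chrom = "character", arm = "character", pos = "integer",
    focal_allele = "character", other_allele = "character"))
  marker_catalog(x$arm, x$pos, x$focal_allele, x$other_allele)
}

#' @rdname read_marker_catalog
#' @export
write_marker_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# chromosome-linear coordinate: concatenate arms of a chromosome (2L then 2R,
# 3L then 3R) by offsetting right-arm positions with the left-arm length.
# Arm lengths default to the maximum catalogue position per arm.
.arm_offsets <- function(catalog, arm_lengths = NULL) {
  arms <- intersect(.ARM_ORDER, unique(catalog$arm))
  if (is.null(arm_lengths))
    arm_lengths <- vapply(arms, function(a) max(catalog$pos[catalog$arm == a]),
                          numeric(1))
  off <- setNames(numeric(length(arms)), arms)
  for (a in arms) {
    ch <- .arm_chrom(a)
    prev <- arms[.arm_chrom(arms) == ch]
    prev <- prev[match(prev, .ARM_ORDER) < match(a, .ARM_ORDER)]
    off[a] <- sum(arm_lengths[prev])
  }
  off
}

# position of each catalogue marker on the concatenated-arm coordinate
.linear_pos <- function(catalog, arm_lengths = NULL) {
  off <- .arm_offsets(catalog, arm_lengths)
  catalog$pos + unname(off[catalog$arm])
}
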