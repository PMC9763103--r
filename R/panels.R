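#' Construct a marker map
#'
#' Biallelic SNV markers on GRCh38-style 1-based inclusive coordinates, with
#' both physical (bp) and genetic (cM) positions, strictly increasing within
#' each chromosome.
#'
#' @param chrom character chromosome names.
#' @param pos_bp integer 1-based physical positions.
#' @param pos_cM numeric genetic positions (>= 0).
#' @param ref,alt single-character reference / alternate alleles.
#' @param id marker ids (rsID or synthetic); generated when `NULL`.
#' @return data.frame of class `fs_markers`.
#' @export
marker_map <- function(chrom, pos_bp, pos_cM, ref, alt, id = NULL) {
  if (is.null(id)) id <- sprintf("snv_%s_%d", chrom, pos_bp)
  m <- data.frame(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
                  pos_cM = as.numeric(pos_cM), ref = ref, alt = alt,
                  id = id)
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (is.unsorted(sub$pos_bp, strictly = TRUE) ||
        is.unsorted(sub$pos_cM, strictly = TRUE))
      stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  if (any(nchar(m$ref) != 1L) || any(nchar(m$alt) != 1L))
    stop("markers must be biallelic SNVs with single-character alleles")
  class(m) <- c("fs_markers", "data.frame")
  m
}

#' Construct a phased haplotype panel
#'
#' Holds, for each sampled individual, the two phased allele sequences
#' (0 = ref, 1 = alt, `NA` = missing) over a common marker map. Haplotype
#' copies are stored as rows `2i-1` (copy 0, paternal) and `2i` (copy 1,
#' maternal) of an integer matrix.
#'
#' @param markers an `fs_markers` map.
#' @param haps integer matrix, `2 * length(samples)` rows by `nrow(markers)`
#'   columns, entries in `{0, 1, NA}`.
#' @param samples character sample ids.
#' @return Object of class `fs_phased`.
#' @export
phased_panel <- function(markers, haps, samples) {
  stopifnot(inherits(markers, "fs_markers"))
  if (nrow(haps) != 2L * length(samples))
    stop("haps must have two rows per sample")
  if (ncol(haps) != nrow(markers))
    stop("haps column count must equal marker count")
  storage.mode(haps) <- "integer"
  rownames(haps) <- paste0(rep(samples, each = 2), "_", rep(0:1, length(samples)))
  structure(list(markers = markers, haps = haps, samples = samples),
            class = "fs_phased")
}

#' @export
print.fs_phased <- function(x, ...) {
  cat(sprintf("<fs_phased> %d samples x %d markers (%d chromosome(s))\n",
              length(x$samples), nrow(x$markers), length(unique(x$markers$chrom))))
  invisible(x)
}

#' Construct a genotype (dosage) panel
#'
#' Unphased alternate-allele dosages in `{0, 1, 2, NA}`; used for
#' array-genotyped control cohorts and for the WGS genotype view of the
#' pedigree.
#'
#' @inheritParams phased_panel
#' @param geno integer matrix, samples x markers, entries in `{0, 1, 2, NA}`.
#' @return Object of class `fs_geno`.
#' @export
genotype_panel <- function(markers, geno, samples) {
  stopifnot(inherits(markers, "fs_markers"))
  if (nrow(geno) != length(samples)) stop("geno must have one row per sample")
  if (ncol(geno) != nrow(markers)) stop("geno column count must equal marker count")
  storage.mode(geno) <- "integer"
  rownames(geno) <- samples
  structure(list(markers = markers, geno = geno, samples = samples),
            class = "fs_geno")
}

#' @export
print.fs_geno <- function(x, ...) {
  cat(sprintf("<fs_geno> %d samples x %d markers\n",
              length(x$samples), nrow(x$markers)))
  invisible(x)
}

#' Collapse a phased panel to dosages
#'
#' Dosage at every non-missing site is the sum of the two haplotype alleles;
#' a site is missing when either haplotype allele is missing.
#'
#' @param panel an `fs_phased`.
#' @return An `fs_geno` over the same markers and samples.
#' @export
as_genotype_panel <- function(panel) {
  stopifnot(inherits(panel, "fs_phased"))
  n <- length(panel$samples)
  g <- panel$haps[seq(1, 2 * n, 2), , drop = FALSE] +
       panel$haps[seq(2, 2 * n, 2), , drop = FALSE]
  genotype_panel(panel$markers, g, panel$samples)
}

#' Per-marker alternate-allele frequencies
#'
#' Frequency is the count of alt alleles over the count of non-missing
#' alleles; markers where every allele is missing are returned as `NA`
#' (undefined).
#'
#' @param panel an `fs_phased` or `fs_geno`.
#' @return Numeric vector, one frequency per marker.
#' @export
allele_frequencies <- function(panel) {
  if (inherits(panel, "fs_phased")) {
    x <- panel$haps
    colSums(x == 1L, na.rm = TRUE) / pmax(colSums(!is.na(x)), 0L) *
      ifelse(colSums(!is.na(x)) > 0, 1, NA)
  } else if (inherits(panel, "fs_geno")) {
    x <- panel$geno
    tot <- 2L * colSums(!is.na(x))
    f <- colSums(x, na.rm = TRUE) / tot
    f[tot == 0L] <- NA_real_
    f
  } else stop("panel must be fs_phased or fs_geno")
}

#' Subset a panel by marker index and/or samples
#'
#' @param panel an `fs_phased` or `fs_geno`.
#' @param markers integer indices into the marker map (kept in order).
#' @param samples character sample ids to retain.
#' @return Panel of the same class.
#' @export
subset_panel <- function(panel, markers = NULL, samples = NULL) {
  if (is.null(markers)) markers <- seq_len(nrow(panel$markers))
  m <- panel$markers[markers, , drop = FALSE]
  class(m) <- c("fs_markers", "data.frame")
  keep <- panel$samples
  if (!is.null(samples)) keep <- intersect(panel$samples, samples)
  if (inherits(panel, "fs_phased")) {
    rows <- as.vector(rbind(2L * match(keep, panel$samples) - 1L,
                            2L * match(keep, panel$samples)))
    phased_panel(m, panel$haps[rows, markers, drop = FALSE], keep)
  } else {
    genotype_panel(m, panel$geno[match(keep, panel$samples), markers, drop = FALSE],
                   keep)
  }
}

hap_rows <- function(panel, id) {
  i <- match(id, panel$samples)
  if (is.na(i)) stop("unknown sample id: ", id)
  c(2L * i - 1L, 2L * i)
}
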