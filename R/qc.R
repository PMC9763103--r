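#' QC thresholds
#'
#' Marker/sample quality-control parameters applied before IBD analysis:
#' genotype (per-marker) missingness < 0.01, individual missingness < 0.05,
#' exact Hardy-Weinberg p >= 0.001, MAF > 0.05, Mendelian-error removal, and
#' LD pruning in 500 kb windows advanced by 50 markers at an r-squared
#' threshold of 0.6.
#'
#' @param max_genotype_missing,max_individual_missing missingness bounds.
#' @param min_hwe_p exact-test p-value below which a marker is removed.
#' @param min_maf minor-allele-frequency bound (strict: MAF must exceed it).
#' @param ld_window_bp,ld_step,max_r2 LD-pruning window (bp), step (markers)
#'   and r-squared threshold.
#' @param drop_mendelian_errors remove markers with Mendelian
#'   inconsistencies in any genotyped parent-offspring pair.
#' @return list of class `fs_qc_thresholds`.
#' @export
qc_thresholds <- function(max_genotype_missing = 0.01,
                          max_individual_missing = 0.05,
                          min_hwe_p = 0.001,
                          min_maf = 0.05,
                          ld_window_bp = 500000L,
                          ld_step = 50L,
                          max_r2 = 0.6,
                          drop_mendelian_errors = TRUE) {
  rates <- c(max_genotype_missing, max_individual_missing, min_hwe_p, min_maf)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (ld_window_bp <= 0) stop("ld_window_bp must be > 0")
  structure(list(max_genotype_missing = max_genotype_missing,
                 max_individual_missing = max_individual_missing,
                 min_hwe_p = min_hwe_p, min_maf = min_maf,
                 ld_window_bp = as.integer(ld_window_bp),
                 ld_step = as.integer(ld_step), max_r2 = max_r2,
                 drop_mendelian_errors = isTRUE(drop_mendelian_errors)),
            class = "fs_qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts (of the same
#' parity as the observed one) whose conditional probability does not exceed
#' that of the observed count. Probabilities follow the exact distribution
#' of heterozygote counts given allele counts and are computed by a
#' mode-anchored recurrence, which stays stable for the small samples this
#' test is meant for (an asymptotic chi-square test would be invalid at
#' n = 19).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1]. Monomorphic sites return 1.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)
  probs <- hwe_het_probs(n, n_minor)
  obs <- as.character(n_het)
  if (is.na(probs[obs])) return(0)  # impossible parity (cannot occur with integer input)
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-12)])
  min(p, 1)
}

# Exact conditional distribution of the heterozygote count given the minor
# allele count n_minor among 2n alleles. Recurrence around the mode:
#   P(h + 2) / P(h) = n_minor_hom * n_major_hom * 4 / ((h + 2) * (h + 1))
# where the homozygote counts are implied by h.
hwe_het_probs <- function(n, n_minor) {
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  hs <- hs[(n_minor - hs) / 2 + hs <= n & (2 * n - n_minor - hs) >= 0]
  logp <- numeric(length(hs))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    logp[k] <- logp[k - 1] +
      log(4 * hom_minor * hom_major) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  stats::setNames(p, hs)
}

#' Squared correlation between dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete observations; returns
#' 0 (treated as unlinked for pruning) when either vector has zero variance
#' over the complete pairs.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("fewer than two pairwise-complete observations")
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) return(0)
  stats::cor(a[ok], b[ok])^2
}

#' LD pruning
#'
#' Sliding windows of `ld_window_bp` starting every `ld_step` markers;
#' within a window, while any retained pair exceeds `max_r2`, the pair with
#' the largest r-squared is resolved by removing its lower-MAF member (ties
#' broken by removing the later-positioned marker). Because a fixed marker
#' step can leave pairs that straddle adjacent windows unexamined on sparse
#' panels, a closing sweep scans every retained pair within one window
#' width and resolves residual violations the same way, so the output
#' carries a guarantee: no retained pair closer than `ld_window_bp` exceeds
#' `max_r2`. The retained set depends only on positions, dosages and MAFs
#' (not marker labels) and is stable under re-running.
#'
#' @param panel an `fs_geno` or `fs_phased` panel (one or more chromosomes;
#'   markers must be position-sorted within chromosome).
#' @param thresholds an [qc_thresholds()] object.
#' @return Integer vector of retained marker indices (into the panel's
#'   marker map).
#' @export
ld_prune <- function(panel, thresholds = qc_thresholds()) {
  geno <- if (inherits(panel, "fs_phased")) as_genotype_panel(panel) else panel
  m <- geno$markers
  dos <- geno$geno
  f <- allele_frequencies(geno)
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, nrow(m))
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    pos <- m$pos_bp[idx]
    starts <- seq(1L, length(idx), by = thresholds$ld_step)
    for (s in starts) {
      live <- idx[seq(s, length(idx))]
      live <- live[m$pos_bp[live] <= pos[s] + thresholds$ld_window_bp]
      repeat {
        w <- live[keep[live]]
        if (length(w) < 2) break
        r2 <- suppressWarnings(stats::cor(dos[, w, drop = FALSE],
                                          use = "pairwise.complete.obs")^2)
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx <= thresholds$max_r2) break
        pair <- which(r2 == mx, arr.ind = TRUE)[1, ]
        i <- w[pair[1]]; j <- w[pair[2]]
        drop <- if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else max(i, j)  # tie: later position
        keep[drop] <- FALSE
      }
    }
    # closing sweep: resolve any surviving within-window pair
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (!keep[i]) next
      js <- idx[idx > i & keep[idx] & m$pos_bp[idx] <= m$pos_bp[i] +
                  thresholds$ld_window_bp]
      if (!length(js)) next
      r2 <- suppressWarnings(
        as.vector(stats::cor(dos[, i], dos[, js, drop = FALSE],
                             use = "pairwise.complete.obs"))^2)
      r2[is.na(r2)] <- 0
      for (v in which(r2 > thresholds$max_r2)) {
        j <- js[v]
        if (!keep[i] || !keep[j]) next
        drop <- if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else max(i, j)
        keep[drop] <- FALSE
      }
    }
  }
  which(keep)
}

#' Apply marker and sample QC
#'
#' Fixed filter order: individual missingness, then per-marker genotype
#' missingness, exact HWE, MAF, Mendelian consistency in genotyped
#' parent-offspring pairs, and finally LD pruning. The report counts
#' removals per filter in application order and telescopes exactly to the
#' input/output sizes.
#'
#' @param panel an `fs_phased` panel of the sampled individuals.
#' @param ped the `fs_pedigree` (used for parent-offspring pairs).
#' @param thresholds an [qc_thresholds()] object.
#' @param hwe_samples optional character vector restricting the HWE test to
#'   a founder-independent subset; default uses all sampled individuals.
#' @param prune run LD pruning as the final step.
#' @param marker_predicate optional function(markers) returning a logical
#'   keep-vector, applied before all other marker filters (hook for e.g.
#'   rsID-presence screens).
#' @return list with `panel` (pruned `fs_phased`), `panel_preprune` (after
#'   all filters except pruning; the "full phased data" used for boundary
#'   refinement), `report` (named removal counts) and `retained` (marker
#'   indices into the input panel).
#' @export
apply_qc <- function(panel, ped, thresholds = qc_thresholds(),
                     hwe_samples = NULL, prune = TRUE,
                     marker_predicate = NULL) {
  stopifnot(inherits(panel, "fs_phased"))
  report <- list(n_markers_in = nrow(panel$markers),
                 n_samples_in = length(panel$samples))

  geno <- as_genotype_panel(panel)
  ind_miss <- rowMeans(is.na(geno$geno))
  keep_samples <- panel$samples[ind_miss <= thresholds$max_individual_missing]
  report$individuals_removed <- length(panel$samples) - length(keep_samples)
  panel <- subset_panel(panel, samples = keep_samples)
  geno <- as_genotype_panel(panel)

  keep <- rep(TRUE, nrow(panel$markers))
  if (!is.null(marker_predicate)) {
    keep <- keep & marker_predicate(panel$markers)
    report$predicate_removed <- sum(!keep)
  }

  miss <- colMeans(is.na(geno$geno))
  fail <- keep & miss > thresholds$max_genotype_missing
  report$missingness_removed <- sum(fail)
  keep[fail] <- FALSE

  hwe_set <- if (is.null(hwe_samples)) panel$samples else
    intersect(hwe_samples, panel$samples)
  gh <- geno$geno[match(hwe_set, panel$samples), , drop = FALSE]
  hwe_p <- vapply(which(keep), function(j) {
    g <- gh[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  fail_idx <- which(keep)[hwe_p < thresholds$min_hwe_p]
  report$hwe_removed <- length(fail_idx)
  keep[fail_idx] <- FALSE

  f <- allele_frequencies(geno)
  maf <- pmin(f, 1 - f)
  fail <- keep & (is.na(maf) | maf <= thresholds$min_maf)
  report$maf_removed <- sum(fail)
  keep[fail] <- FALSE

  if (thresholds$drop_mendelian_errors) {
    bad <- mendelian_error_markers(geno, ped)
    fail <- keep & bad
    report$mendelian_removed <- sum(fail)
    keep[fail] <- FALSE
  } else report$mendelian_removed <- 0L

  pre <- subset_panel(panel, markers = which(keep))
  if (prune) {
    pr <- ld_prune(pre, thresholds)
    report$ld_pruned <- nrow(pre$markers) - length(pr)
    out <- subset_panel(pre, markers = pr)
    retained <- which(keep)[pr]
  } else {
    report$ld_pruned <- 0L
    out <- pre
    retained <- which(keep)
  }
  report$n_markers_out <- nrow(out$markers)
  report$n_samples_out <- length(out$samples)
  if (report$n_markers_out == 0 || report$n_samples_out == 0)
    stop("QC removed all markers or all individuals")
  list(panel = out, panel_preprune = pre, report = report, retained = retained)
}

# markers with an impossible parent-offspring dosage combination
# (parent 0 with child 2, or parent 2 with child 0) in any genotyped pair
mendelian_error_markers <- function(geno, ped) {
  bad <- rep(FALSE, nrow(geno$markers))
  ind <- ped$ind
  for (id in intersect(geno$samples, ind$id)) {
    for (par in c(ind[id, "father"], ind[id, "mother"])) {
      if (is.na(par) || !(par %in% geno$samples)) next
      gc <- geno$geno[match(id, geno$samples), ]
      gp <- geno$geno[match(par, geno$samples), ]
      bad <- bad | (!is.na(gc) & !is.na(gp) &
                      ((gp == 0L & gc == 2L) | (gp == 2L & gc == 0L)))
    }
  }
  bad
}
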