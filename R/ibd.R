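#' IBD detection parameters
#'
#' @param min_length_bp minimum segment length (strict; the reported
#'   thresholds are in Mb so lengths are filtered in bp).
#' @param min_lod minimum LOD score (log10 likelihood ratio of IBD vs
#'   non-IBD; strict).
#' @param allele_error per-allele haplotype error rate used in the
#'   likelihood; also caps mismatch penalties so the LOD stays finite.
#' @param seed_length minimum run of identical non-missing alleles that
#'   seeds a candidate segment (markers).
#' @param lod_backoff LOD drop from the running maximum at which outward
#'   extension stops.
#' @param merge_gap_cm same-pair segments separated by less than this
#'   genetic distance are merged after detection (isolated haplotype errors
#'   split long true segments; post-detection gap merging is the standard
#'   remedy).
#' @return list of class `fs_ibd_params`.
#' @export
ibd_params <- function(min_length_bp = 1e6, min_lod = 3.0,
                       allele_error = 0.0025, seed_length = 64L,
                       lod_backoff = 2.0, merge_gap_cm = 0.6) {
  if (allele_error <= 0 || allele_error >= 0.5)
    stop("allele_error must lie in (0, 0.5)")
  if (min_lod < 0) stop("min_lod must be >= 0")
  structure(list(min_length_bp = min_length_bp, min_lod = min_lod,
                 allele_error = allele_error,
                 seed_length = as.integer(seed_length),
                 lod_backoff = lod_backoff, merge_gap_cm = merge_gap_cm),
            class = "fs_ibd_params")
}

#' Per-site LOD contributions for a haplotype pair
#'
#' For observed alleles a, b with alt frequency f and allele-error rate
#' eps, the IBD likelihood marginalises over the latent shared allele c:
#' `P(a, b | IBD) = sum_c f_c q(a|c) q(b|c)` with `q(x|c) = 1 - eps` if
#' `x == c` else `eps`; the non-IBD likelihood is `f_a * f_b`. The
#' contribution is the log10 ratio; it is additive over sites, so interval
#' LOD scores are cumulative sums of this vector. Sites with missing
#' alleles contribute 0; sites with degenerate frequency (0 or 1) are
#' skipped with a warning.
#'
#' @param hap_a,hap_b integer allele vectors in `{0, 1, NA}`.
#' @param freqs alt-allele frequencies per site.
#' @param eps allele-error rate.
#' @return Numeric vector of per-site log10 likelihood-ratio contributions.
#' @export
lod_contributions <- function(hap_a, hap_b, freqs, eps = 0.0025) {
  degenerate <- !is.na(freqs) & (freqs <= 0 | freqs >= 1)
  if (any(degenerate & !is.na(hap_a) & !is.na(hap_b)))
    warning("skipping ", sum(degenerate), " site(s) with allele frequency 0 or 1")
  f1 <- freqs
  f0 <- 1 - freqs
  qa1 <- ifelse(hap_a == 1L, 1 - eps, eps)  # q(a | c = 1)
  qa0 <- ifelse(hap_a == 1L, eps, 1 - eps)
  qb1 <- ifelse(hap_b == 1L, 1 - eps, eps)
  qb0 <- ifelse(hap_b == 1L, eps, 1 - eps)
  p_ibd <- f1 * qa1 * qb1 + f0 * qa0 * qb0
  fa <- ifelse(hap_a == 1L, f1, f0)
  fb <- ifelse(hap_b == 1L, f1, f0)
  contrib <- log10(p_ibd) - log10(fa * fb)
  contrib[is.na(hap_a) | is.na(hap_b) | degenerate] <- 0
  contrib
}

#' Interval LOD score
#'
#' Sum of [lod_contributions()] over a marker-index interval.
#'
#' @inheritParams lod_contributions
#' @param interval integer `c(from, to)` marker indices (inclusive); default
#'   spans all sites.
#' @return LOD score (log10 likelihood ratio).
#' @export
lod_score <- function(hap_a, hap_b, freqs, eps = 0.0025, interval = NULL) {
  if (is.null(interval)) interval <- c(1L, length(hap_a))
  if (interval[1] < 1 || interval[2] > length(hap_a))
    stop("interval outside marker range")
  idx <- interval[1]:interval[2]
  sum(lod_contributions(hap_a[idx], hap_b[idx], freqs[idx], eps))
}

#' Pairwise IBD segment detection on phased haplotypes
#'
#' Transparent seed-and-extend detector with a likelihood-ratio score: for
#' each pair of haplotype copies from different individuals, maximal runs of
#' at least `seed_length` identical non-missing alleles seed candidate
#' segments, each extended outward while the cumulative LOD stays within
#' `lod_backoff` of its running maximum, then trimmed to the argmax-LOD
#' interval. Overlapping segments from the same haplotype pair are merged;
#' emitted segments satisfy the strict length (> `min_length_bp`) and LOD
#' (> `min_lod`) thresholds.
#'
#' @param panel an `fs_phased` panel (one or more chromosomes).
#' @param params an [ibd_params()] object.
#' @param freqs optional per-marker alt frequencies; recomputed from the
#'   panel when `NULL`.
#' @return data.frame with columns `id_a, hap_a, id_b, hap_b, chrom, start,
#'   end, n_markers, lod` (1-based inclusive bp coordinates).
#' @export
pairwise_ibd <- function(panel, params = ibd_params(), freqs = NULL) {
  stopifnot(inherits(panel, "fs_phased"))
  if (length(panel$samples) < 2) stop("need at least two individuals")
  if (is.null(freqs)) freqs <- allele_frequencies(panel)
  freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
  m <- panel$markers
  out <- list()
  n <- length(panel$samples)
  rows <- expand.grid(i = seq_len(n), j = seq_len(n))
  rows <- rows[rows$i < rows$j, ]
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    pos <- m$pos_bp[idx]
    for (r in seq_len(nrow(rows))) {
      i <- rows$i[r]; j <- rows$j[r]
      for (ci in 0:1) for (cj in 0:1) {
        a <- panel$haps[2L * i - 1L + ci, idx]
        b <- panel$haps[2L * j - 1L + cj, idx]
        segs <- seed_extend(a, b, freqs[idx], pos, m$pos_cM[idx], params)
        if (!is.null(segs) && nrow(segs)) {
          segs$id_a <- panel$samples[i]; segs$hap_a <- ci
          segs$id_b <- panel$samples[j]; segs$hap_b <- cj
          segs$chrom <- ch
          out[[length(out) + 1L]] <- segs
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(id_a = character(0), hap_a = integer(0),
                      id_b = character(0), hap_b = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), n_markers = integer(0),
                      lod = numeric(0)))
  res <- do.call(rbind, out)
  res[, c("id_a", "hap_a", "id_b", "hap_b", "chrom", "start", "end",
          "n_markers", "lod")]
}

# Seed-and-extend on one chromosome for one haplotype pair. Returns a
# data.frame(start, end, n_markers, lod) in bp, already threshold-filtered
# and merged.
seed_extend <- function(a, b, f, pos, cm, params) {
  match_ok <- !is.na(a) & !is.na(b) & a == b
  informative <- !is.na(a) & !is.na(b)
  rl <- rle(match_ok | !informative)  # missing sites do not break a seed run
  ends <- cumsum(rl$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  run_inf <- vapply(seq_along(rl$values), function(k)
    if (rl$values[k]) sum(informative[starts[k]:ends[k]]) else 0L, integer(1))
  seeds <- which(rl$values & run_inf >= params$seed_length)
  if (!length(seeds)) return(NULL)
  contrib <- lod_contributions(a, b, f, params$allele_error)
  cs <- cumsum(contrib)
  lod_between <- function(from, to) cs[to] - if (from > 1) cs[from - 1] else 0

  ivals <- list()
  for (k in seeds) {
    s <- starts[k]; e <- ends[k]
    e2 <- extend_dir(contrib, e, length(a), params$lod_backoff)
    s2 <- length(a) + 1L - extend_dir(rev(contrib), length(a) + 1L - s,
                                      length(a), params$lod_backoff)
    # trim to the argmax-LOD sub-interval anchored on the seed
    s_best <- s2 - 1L + which.max(rev(cumsum(rev(contrib[s2:s]))))
    e_best <- (e:e2)[which.max(cumsum(contrib[e:e2]))]
    ivals[[length(ivals) + 1L]] <- c(s_best, e_best)
  }
  iv <- do.call(rbind, ivals)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    gap_cm <- if (iv[k, 1] > last[2]) cm[iv[k, 1]] - cm[last[2]] else 0
    if (iv[k, 1] <= last[2] + 1L || gap_cm < params$merge_gap_cm)
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[k, 2]))
    else merged[[length(merged) + 1L]] <- iv[k, ]
  }
  res <- NULL
  for (v in merged) {
    len <- pos[v[2]] - pos[v[1]]
    lod <- lod_between(v[1], v[2])
    if (len > params$min_length_bp && lod > params$min_lod)
      res <- rbind(res, data.frame(start = pos[v[1]], end = pos[v[2]],
                                   n_markers = v[2] - v[1] + 1L, lod = lod))
  }
  res
}

# furthest index reachable extending rightward from `from` while the
# cumulative LOD stays within `backoff` of its running maximum
extend_dir <- function(contrib, from, n, backoff) {
  if (from >= n) return(from)
  cum <- cumsum(contrib[(from + 1L):n])
  running_max <- cummax(c(0, cum))
  drop <- running_max[-length(running_max)] - cum
  stop_at <- which(drop > backoff)
  if (!length(stop_at)) from + length(cum) else from + stop_at[1] - 1L
}

#' Copies of a cluster haplotype carried by an individual
#'
#' Counts how many of the individual's two haplotype copies belong to a
#' multi-IBD cluster over its interval: 0 (not a carrier), 1 (IBD1) or 2
#' (IBD2, both chromosomes).
#'
#' @param id individual id.
#' @param cluster a cluster from [multi_ibd_clusters()].
#' @return Integer in `{0, 1, 2}`.
#' @export
ibd_copy_number <- function(id, cluster) {
  sum(cluster$members$id == id)
}

#' Relatedness degree from genome-wide IBD sharing
#'
#' Kinship is estimated as (sum of IBD1 lengths / 2 + sum of IBD2 lengths) /
#' (2 * genome length); IBD2 regions are those covered by segments on both
#' haplotype copies of both individuals. The degree label follows standard
#' kinship bins with boundaries at `2^-(d + 1.5)` (duplicate/MZ at kinship
#' 1/2, 1st degree at 1/4, and so on); kinship below the `max_degree` bin is
#' labelled unrelated.
#'
#' @param segments segment data.frame (as from [pairwise_ibd()]) for one
#'   pair of individuals.
#' @param genome_length_bp total genome length in bp.
#' @param max_degree deepest degree bin before "unrelated".
#' @return list with `kinship` and `degree` (0 = duplicate/MZ, 1 = 1st
#'   degree, ..., `Inf` = unrelated) plus a text `label`.
#' @export
relatedness_degree <- function(segments, genome_length_bp, max_degree = 9L) {
  if (genome_length_bp <= 0) stop("genome length must be > 0")
  if (!nrow(segments)) {
    return(list(kinship = 0, degree = Inf, label = "unrelated"))
  }
  total_ibd1 <- 0
  total_ibd2 <- 0
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    brk <- sort(unique(c(s$start, s$end + 1)))
    if (length(brk) < 2) next
    lo <- utils::head(brk, -1); hi <- utils::tail(brk, -1) - 1
    for (k in seq_along(lo)) {
      cov <- s$start <= lo[k] & s$end >= hi[k]
      if (!any(cov)) next
      # IBD2: both copies of both individuals engaged over this slice
      n_a <- length(unique(s$hap_a[cov]))
      n_b <- length(unique(s$hap_b[cov]))
      len <- hi[k] - lo[k] + 1
      if (n_a == 2 && n_b == 2) total_ibd2 <- total_ibd2 + len
      else total_ibd1 <- total_ibd1 + len
    }
  }
  kin <- (total_ibd1 / 2 + total_ibd2) / (2 * genome_length_bp)
  if (kin <= 0 || kin < 2^-(max_degree + 1.5))
    return(list(kinship = kin, degree = Inf, label = "unrelated"))
  degree <- max(0L, round(-log2(kin)) - 1L)
  label <- if (degree == 0) "duplicate/MZ" else sprintf("degree-%d", degree)
  list(kinship = kin, degree = degree, label = label)
}
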