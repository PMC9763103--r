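# The risk-haplotype filter cascade: length -> founder-pair clustering ->
# control absence -> carrier phenotype -> boundary refinement on the full
# phased data. Every stage records in/out counts in a telescoping trace.

#' Length filter
#'
#' Keeps clusters strictly longer than `min_bp` (end - start).
#'
#' @param clusters list of clusters from [multi_ibd_clusters()].
#' @param min_bp length threshold (strict).
#' @return Filtered cluster list.
#' @export
filter_by_length <- function(clusters, min_bp = 1e6) {
  Filter(function(cl) (cl$end - cl$start) > min_bp, clusters)
}

#' Founder-pair filter
#'
#' Keeps clusters in which at least `min_same_fp` carriers descend from the
#' same founder pair, and records the main founder pair(s) - the label(s)
#' attaining the maximal carrier count (ties are kept as a set, so a
#' haplotype can have main pair "A/B").
#'
#' @param clusters list of clusters.
#' @param ped the `fs_pedigree`.
#' @param min_same_fp minimum carriers sharing one founder pair.
#' @return Filtered list; each kept cluster gains `fp_sets` (per carrier),
#'   `main_fp` (character vector of labels) and `main_fp_count`.
#' @export
filter_by_founder_pair <- function(clusters, ped, min_same_fp = 3L) {
  out <- list()
  for (cl in clusters) {
    fp_sets <- lapply(cl$carriers, function(id) founder_ancestry(ped, id))
    names(fp_sets) <- cl$carriers
    if (any(lengths(fp_sets) == 0))
      stop("carrier with empty founder-pair ancestry: pedigree inconsistency")
    counts <- table(unlist(lapply(fp_sets, unique)))
    if (!length(counts) || max(counts) < min_same_fp) next
    cl$fp_sets <- fp_sets
    cl$main_fp <- sort(names(counts)[counts == max(counts)])
    cl$main_fp_count <- as.integer(max(counts))
    out[[length(out) + 1L]] <- cl
  }
  out
}

#' Control-cohort screen
#'
#' A control "carries" the candidate haplotype when, at every array marker
#' shared with the candidate interval, its unphased genotype is consistent
#' with carrying the backbone allele (dosage of that allele >= 1), allowing
#' at most `max_mismatch_frac` inconsistent markers; missing control
#' genotypes are non-constraining. The candidate passes only if no control
#' in any panel carries it. Genotype-consistency (rather than phased
#' matching) is used because control cohorts are array-genotyped and
#' unphased; the default `max_mismatch_frac = 0` means any fully consistent
#' control removes the candidate, which also removes common haplotypes that
#' controls match by chance - the designed behaviour.
#'
#' @param cluster a cluster (its members define the backbone).
#' @param panel the phased panel the cluster was called on (provides the
#'   backbone alleles).
#' @param control_panels list of `fs_geno` control panels.
#' @param max_mismatch_frac tolerated fraction of inconsistent markers.
#' @param min_shared minimum shared markers for the screen to be evaluable.
#' @return list with `status` (`"absent"` or `"present_in"`), `panel`
#'   (offending panel name or `NA`) and `n_shared`.
#' @export
screen_controls <- function(cluster, panel, control_panels,
                            max_mismatch_frac = 0, min_shared = 20L) {
  bb <- cluster_backbone(cluster, panel)
  for (nm in names(control_panels)) {
    cp <- control_panels[[nm]]
    shared <- match(paste(cp$markers$chrom, cp$markers$pos_bp),
                    paste(bb$chrom, bb$pos_bp))
    here <- which(!is.na(shared) & !is.na(bb$allele[shared]))
    if (length(here) < min_shared)
      stop("control screen not evaluable: only ", length(here),
           " shared markers (need >= ", min_shared, ")")
    allele <- bb$allele[shared[here]]
    if (!length(cp$samples)) next
    g <- cp$geno[, here, drop = FALSE]
    # dosage of the backbone allele: alt dosage if allele == 1 else 2 - dosage
    dos_bb <- sweep(g, 2, allele, function(d, a) ifelse(a == 1L, d, 2L - d))
    inconsistent <- !is.na(dos_bb) & dos_bb < 1L
    frac <- rowSums(inconsistent) / length(here)
    if (any(frac <= max_mismatch_frac))
      return(list(status = "present_in", panel = nm, n_shared = length(here)))
  }
  list(status = "absent", panel = NA_character_,
       n_shared = NA_integer_)
}

# Consensus backbone of a cluster over the interval: per marker the
# majority allele across member haplotype copies (NA when tied or all
# missing).
cluster_backbone <- function(cluster, panel) {
  m <- panel$markers
  idx <- which(m$chrom == cluster$chrom & m$pos_bp >= cluster$start &
                 m$pos_bp <= cluster$end)
  rows <- 2L * match(cluster$members$id, panel$samples) - 1L + cluster$members$hap
  H <- panel$haps[rows, idx, drop = FALSE]
  ones <- colSums(H == 1L, na.rm = TRUE)
  zeros <- colSums(H == 0L, na.rm = TRUE)
  allele <- ifelse(ones > zeros, 1L, ifelse(zeros > ones, 0L, NA_integer_))
  data.frame(chrom = cluster$chrom, pos_bp = m$pos_bp[idx],
             idx = idx, allele = allele)
}

#' Phenotype filter
#'
#' Keeps clusters whose every carrier satisfies the affected predicate
#' (confirmed or probable tic-spectrum diagnosis, TS or CMVT); with
#' `confirmed_only = TRUE` probable diagnoses do not qualify.
#'
#' @param clusters list of clusters.
#' @param ped the `fs_pedigree` (diagnoses loaded).
#' @param confirmed_only restrict to confirmed TS/CMVT.
#' @return Filtered cluster list.
#' @export
filter_by_phenotype <- function(clusters, ped, confirmed_only = FALSE) {
  ok_labels <- if (confirmed_only) c("TS", "CMVT") else
    c("TS", "TS_probable", "CMVT", "CMVT_probable")
  Filter(function(cl) {
    all(vapply(cl$carriers, function(id) {
      dx <- ped$diagnosis[[id]]
      !is.null(dx) && length(intersect(dx, ok_labels)) > 0
    }, logical(1)))
  }, clusters)
}

#' Boundary refinement on the full phased data
#'
#' Clusters are called on LD-pruned markers; this re-defines their
#' boundaries on the full phased marker set. Each member haplotype copy is
#' compared with the member consensus, and its own boundary is found by
#' extending outward from the interval midpoint: up to `max_mismatches`
#' isolated mismatches per flank are crossed, but extension stops where
#' mismatches become dense (`dense_count` within any `dense_window`
#' markers - the signature of the copy leaving the shared haplotype for its
#' own background) and the boundary is trimmed back to the end of the last
#' run of `clean_run` consecutive matching markers. The refined interval is
#' the intersection of the member boundaries, i.e. the largest core on
#' which all members remain mutually identical up to isolated errors. With
#' `max_mismatches = 0` a single flanking mismatch stops that member's
#' extension at the site before it.
#'
#' @param cluster a cluster (pruned-marker interval).
#' @param panel the full phased panel (must include the pruned markers).
#' @param max_mismatches isolated mismatches crossable per member flank.
#' @param dense_window,dense_count density stop: `dense_count` mismatches
#'   of one member within `dense_window` markers end its extension.
#' @param clean_run trailing-trim length (markers).
#' @return The cluster with `start`/`end` replaced by the refined interval
#'   (bp of the outermost retained markers) and `refined = TRUE`.
#' @export
refine_boundaries <- function(cluster, panel, max_mismatches = 0L,
                              dense_window = 20L, dense_count = 5L,
                              clean_run = 10L) {
  m <- panel$markers
  idx <- which(m$chrom == cluster$chrom)
  pos <- m$pos_bp[idx]
  rows <- 2L * match(cluster$members$id, panel$samples) - 1L + cluster$members$hap
  H <- panel$haps[rows, idx, drop = FALSE]
  ones <- colSums(H == 1L, na.rm = TRUE)
  zeros <- colSums(H == 0L, na.rm = TRUE)
  consensus <- ifelse(ones > zeros, 1L, ifelse(zeros > ones, 0L, NA_integer_))
  in_iv <- pos >= cluster$start & pos <= cluster$end
  unanimous <- ones == 0L | zeros == 0L
  if (mean(!unanimous[in_iv]) > 0.5)
    stop("cluster members disagree across most of the interval; spurious cluster")
  mid_j <- which.min(abs(pos - (cluster$start + cluster$end) / 2))
  s <- 1L
  e <- length(idx)
  for (r in seq_len(nrow(H))) {
    mm <- !is.na(H[r, ]) & !is.na(consensus) & H[r, ] != consensus
    e <- min(e, member_flank(mm, mid_j, +1L, max_mismatches,
                             dense_window, dense_count, clean_run))
    s <- max(s, member_flank(mm, mid_j, -1L, max_mismatches,
                             dense_window, dense_count, clean_run))
  }
  if (e < s) stop("refinement collapsed the interval; spurious cluster")
  cluster$start <- pos[s]
  cluster$end <- pos[e]
  cluster$refined <- TRUE
  cluster
}

# boundary of one member copy in direction `dir` from index `from`:
# crosses up to `budget` isolated mismatches, stops at a dense mismatch
# burst or budget exhaustion, trims back to the last clean run
member_flank <- function(mm, from, dir, budget, dense_window, dense_count,
                         clean_run) {
  n <- length(mm)
  seq_idx <- if (dir > 0) from:n else from:1
  hits <- seq_idx[mm[seq_idx]]
  if (!length(hits)) return(if (dir > 0) n else 1L)
  k_stop <- length(hits) + 1L
  if (length(hits) >= dense_count) {
    span <- abs(hits[seq_len(length(hits) - dense_count + 1L) + dense_count - 1L] -
                  hits[seq_len(length(hits) - dense_count + 1L)])
    dense_at <- which(span < dense_window)
    if (length(dense_at)) k_stop <- min(k_stop, dense_at[1])
  }
  k_stop <- min(k_stop, budget + 1L)
  stop_idx <- if (k_stop > length(hits)) (if (dir > 0) n + 1L else 0L)
              else hits[k_stop]
  # trim back to the end of the last `clean_run` consecutive clean markers
  i <- stop_idx - dir
  while (abs(i - from) + 1L >= clean_run) {
    window <- i - dir * (seq_len(clean_run) - 1L)
    if (!any(mm[window])) return(i)
    i <- i - dir
  }
  max(1L, min(n, i))
}

#' Run the full haplotype filter cascade
#'
#' Fixed stage order: length, founder pair, control absence, carrier
#' phenotype, boundary refinement. Returns the surviving candidates and a
#' telescoping trace of in/out counts per stage.
#'
#' @param clusters list of clusters (any chromosome mix).
#' @param ped the `fs_pedigree`.
#' @param panel the pruned phased panel the clusters were called on.
#' @param full_panel the full phased panel for refinement.
#' @param control_panels list of `fs_geno` control panels.
#' @param min_length_bp,min_same_fp,max_mismatch_frac,confirmed_only,max_mismatches
#'   stage parameters (see the individual filters).
#' @return list with `candidates` (refined clusters) and `trace`
#'   (data.frame stage/n_in/n_out).
#' @export
filter_cascade <- function(clusters, ped, panel, full_panel, control_panels,
                           min_length_bp = 1e6, min_same_fp = 3L,
                           max_mismatch_frac = 0, confirmed_only = FALSE,
                           max_mismatches = 20L) {
  trace <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  note <- function(stage, n_in, n_out)
    rbind(trace, data.frame(stage = stage, n_in = n_in, n_out = n_out))

  n0 <- length(clusters)
  cl1 <- filter_by_length(clusters, min_length_bp)
  trace <- note("length", n0, length(cl1))
  cl2 <- filter_by_founder_pair(cl1, ped, min_same_fp)
  trace <- note("founder_pair", length(cl1), length(cl2))
  # a candidate whose screen is not evaluable (too few shared array markers)
  # cannot demonstrate absence from controls and is removed conservatively
  cl3 <- Filter(function(cl) {
    res <- tryCatch(
      screen_controls(cl, panel, control_panels,
                      max_mismatch_frac = max_mismatch_frac),
      error = function(e) list(status = "not_evaluable"))
    res$status == "absent"
  }, cl2)
  trace <- note("controls", length(cl2), length(cl3))
  cl4 <- filter_by_phenotype(cl3, ped, confirmed_only)
  trace <- note("phenotype", length(cl3), length(cl4))
  cl5 <- lapply(cl4, refine_boundaries, panel = full_panel,
                max_mismatches = max_mismatches)
  trace <- note("refine", length(cl4), length(cl5))
  list(candidates = cl5, trace = trace)
}
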