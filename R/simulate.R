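#' Simulation configuration
#'
#' Defines the study conditions the synthetic generator emulates: a deep
#' pedigree descending from six labelled founder pairs, 19 sampled
#' individuals (17 affected by design), two ~50 Mb chromosomes with WGS-like
#' and array-like marker densities, Poisson-count crossovers, haplotype
#' allele error, and a penetrance/phenocopy phenotype model. The 11
#' generations of the real design are emulated at desk scale with 6
#' generations; sampled individuals remain separated by at least
#' `min_meioses` meioses.
#'
#' @param n_generations total generations including the founder generation.
#' @param n_founder_pairs number of labelled founder couples (A, B, ...).
#' @param n_sampled,n_affected sampled individuals and design affected count.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param wgs_density,array_density markers per Mb for the WGS-like panel and
#'   the array-like control subset.
#' @param recomb_rate_cM_per_Mb genetic-map rate (cM/Mb).
#' @param common_af_range background allele-frequency spectrum (uniform).
#' @param error_rate per-allele haplotype error rate applied to sampled
#'   individuals' phased data.
#' @param penetrance,phenocopy probability a planted-haplotype carrier /
#'   non-carrier is affected.
#' @param min_meioses minimum pairwise meiotic distance among sampled
#'   individuals.
#' @param match_design force the affected count to `n_affected` (emulating
#'   affected-proband ascertainment); deterministic assignments
#'   (penetrance/phenocopy equal to 0 or 1) are never overridden.
#' @param recipes optional list of founder-pair ancestry sets, one per
#'   sampled individual; defaults to a composition mirroring the study's
#'   carrier table.
#' @param seed integer random seed.
#' @return A list of class `fs_sim_config`.
#' @export
sim_config <- function(n_generations = 6L,
                       n_founder_pairs = 6L,
                       n_sampled = 19L,
                       n_affected = 17L,
                       chrom_lengths = c(`1` = 5e7, `2` = 5e7),
                       wgs_density = 100,
                       array_density = 20,
                       recomb_rate_cM_per_Mb = 1.0,
                       common_af_range = c(0.05, 0.5),
                       error_rate = 0.001,
                       penetrance = 0.8,
                       phenocopy = 0.1,
                       min_meioses = 6L,
                       match_design = TRUE,
                       recipes = NULL,
                       seed = 1L) {
  probs <- c(error_rate, penetrance, phenocopy)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (wgs_density <= 0 || array_density <= 0) stop("marker density must be > 0")
  if (n_affected > n_sampled) stop("n_affected cannot exceed n_sampled")
  cfg <- list(n_generations = as.integer(n_generations),
              n_founder_pairs = as.integer(n_founder_pairs),
              n_sampled = as.integer(n_sampled),
              n_affected = as.integer(n_affected),
              chrom_lengths = chrom_lengths,
              wgs_density = wgs_density, array_density = array_density,
              recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
              common_af_range = common_af_range,
              error_rate = error_rate,
              penetrance = penetrance, phenocopy = phenocopy,
              min_meioses = as.integer(min_meioses),
              match_design = isTRUE(match_design),
              recipes = recipes, seed = as.integer(seed))
  class(cfg) <- "fs_sim_config"
  cfg
}

# default ancestry recipes: 17 affected-design individuals mirroring the
# carrier table's founder-pair composition, plus two control-design ones
default_recipes <- function(n_founder_pairs = 6L) {
  labs <- LETTERS[seq_len(n_founder_pairs)]
  base <- list(c("C", "D"), c("D", "F"), "D", "D", c("C", "E"),
               c("A", "B", "C", "D"), c("A", "B"), c("A", "B", "C"),
               c("A", "B", "C"), "B", "B", "B", "B", "C", "E",
               c("A", "B", "C"), "F",
               "B", "C")  # final two: control-design ancestries
  lapply(base, function(s) intersect(s, labs))
}

#' Simulate a founder pedigree
#'
#' Builds an acyclic pedigree in which the labelled founder pairs occupy
#' generation 0 and each sampled individual descends, through its own chain
#' of intermediate ancestors (married-in spouses are unlabelled generation-0
#' founders), from exactly the founder pairs of its ancestry recipe. Sampled
#' individuals sit in the last two generations, so any two that share a
#' founder pair are separated by at least `2 * (n_generations - 2)` meioses.
#'
#' The descent chains to each sampled individual are attached as
#' `attr(ped, "paths")`: `paths[[sample_id]][[fp_label]]` is the id sequence
#' from the founder couple's generation-1 child down to the sampled
#' individual, used by [gene_drop()] transmission steering.
#'
#' @param config an [sim_config()] object.
#' @return An `fs_pedigree` with `n_sampled` sampled members.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  G <- config$n_generations
  labs <- LETTERS[seq_len(config$n_founder_pairs)]
  recipes <- config$recipes
  if (is.null(recipes)) recipes <- default_recipes(config$n_founder_pairs)
  if (length(recipes) != config$n_sampled) {
    pool <- recipes
    recipes <- pool[1 + (seq_len(config$n_sampled) - 1) %% length(pool)]
  }
  max_set <- max(lengths(recipes))
  need <- max(2L, ceiling(log2(max(max_set, 1L))) + 1L) + 1L  # deepest recipe + last-2-gen slack
  if (G < need)
    stop("n_generations = ", G, " cannot host the ancestry recipes; ",
         "increase n_generations to at least ", need)
  if (2L * (G - 2L) < config$min_meioses)
    stop("sampled individuals would be closer than min_meioses = ",
         config$min_meioses, "; increase n_generations")

  rows <- list()
  fp <- list()
  counter <- new.env()
  counter$n <- 0L
  new_id <- function(prefix = "I") {
    counter$n <- counter$n + 1L
    sprintf("%s%03d", prefix, counter$n)
  }
  add <- function(id, father, mother, sex, generation, sampled = FALSE) {
    rows[[id]] <<- data.frame(id = id, father = father, mother = mother,
                              sex = sex, generation = generation,
                              sampled = sampled)
    id
  }
  for (lab in labs) {
    fa <- add(paste0(lab, "_f"), NA, NA, "male", 0L)
    mo <- add(paste0(lab, "_m"), NA, NA, "female", 0L)
    fp[[lab]] <- c(fa, mo)
  }
  marry_in <- function() add(new_id("M"), NA, NA,
                             sample(c("male", "female"), 1), 0L)

  # returns list(id, paths = list(label -> chain of ids ending at id))
  make_descendant <- function(S, depth, sex) {
    if (length(S) == 1L) {
      lab <- S
      chain <- character(0)
      parent_f <- fp[[lab]][1]; parent_m <- fp[[lab]][2]
      for (g in seq_len(depth)) {
        sx <- if (g == depth) sex else sample(c("male", "female"), 1)
        kid <- add(new_id(), parent_f, parent_m, sx, g)
        chain <- c(chain, kid)
        if (g < depth) {
          sp <- marry_in()
          if (sx == "male") { parent_f <- kid; parent_m <- sp }
          else { parent_f <- sp; parent_m <- kid }
          rows[[sp]]$sex <<- if (sx == "male") "female" else "male"
        }
      }
      list(id = chain[depth], paths = stats::setNames(list(chain), lab))
    } else {
      half <- seq_len(ceiling(length(S) / 2))
      p1 <- make_descendant(S[half], depth - 1L, "male")
      p2 <- make_descendant(S[-half], depth - 1L, "female")
      kid <- add(new_id(), p1$id, p2$id, sex, depth)
      paths <- c(lapply(p1$paths, c, kid), lapply(p2$paths, c, kid))
      list(id = kid, paths = paths)
    }
  }

  paths <- list()
  sampled_ids <- character(config$n_sampled)
  for (i in seq_along(recipes)) {
    S <- recipes[[i]]
    dmin <- if (length(S) == 1L) 1L else ceiling(log2(length(S))) + 1L
    depth <- sample(max(G - 2L, dmin):(G - 1L), 1)
    d <- make_descendant(S, depth, sample(c("male", "female"), 1))
    sid <- sprintf("P%02d", i)
    rows[[d$id]]$id <- sid
    rows[[d$id]]$sampled <- TRUE
    names(rows)[match(d$id, names(rows))] <- sid
    paths[[sid]] <- lapply(d$paths, function(ch) { ch[length(ch)] <- sid; ch })
    sampled_ids[i] <- sid
  }
  ind <- do.call(rbind, rows)
  ped <- new_pedigree(ind, founder_pairs = fp)
  attr(ped, "paths") <- paths
  attr(ped, "recipes") <- stats::setNames(recipes, sampled_ids)
  ped
}

#' Build a WGS-like marker map for simulation
#'
#' Uniformly placed common background markers at `wgs_density` per Mb on each
#' chromosome; extra positions (planted rare variants) can be merged in. The
#' genetic map is linear at `recomb_rate_cM_per_Mb`.
#'
#' @param config an [sim_config()] object.
#' @param extra optional data.frame with columns `chrom`, `pos_bp`, `ref`,
#'   `alt`, `id` of additional (rare) variant sites.
#' @return `fs_markers` map; attribute `"is_extra"` flags the merged sites.
#' @export
sim_marker_map <- function(config, extra = NULL) {
  out <- NULL
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    n <- round(config$wgs_density * len / 1e6)
    pos <- sort(sample.int(len - 2L, n))
    df <- data.frame(chrom = ch, pos_bp = pos,
                     ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     alt = NA_character_,
                     id = sprintf("snv_%s_%d", ch, pos), extra = FALSE)
    out <- rbind(out, df)
  }
  if (!is.null(extra)) {
    extra$pos_bp <- as.integer(extra$pos_bp)
    ex <- data.frame(chrom = as.character(extra$chrom),
                     pos_bp = extra$pos_bp,
                     ref = extra$ref, alt = extra$alt, id = extra$id,
                     extra = TRUE)
    out <- rbind(out[!paste(out$chrom, out$pos_bp) %in%
                       paste(ex$chrom, ex$pos_bp), ], ex)
  }
  out <- out[order(match(out$chrom, names(config$chrom_lengths)), out$pos_bp), ]
  bases <- c("A", "C", "G", "T")
  need_alt <- is.na(out$alt)
  out$alt[need_alt] <- vapply(out$ref[need_alt],
                              function(r) sample(setdiff(bases, r), 1),
                              character(1))
  m <- marker_map(out$chrom, out$pos_bp,
                  out$pos_bp / 1e6 * config$recomb_rate_cM_per_Mb,
                  out$ref, out$alt, out$id)
  attr(m, "is_extra") <- out$extra
  m
}

#' Draw founder haplotypes from the background spectrum
#'
#' Every generation-0 individual (labelled founders and married-in spouses)
#' receives two haplotypes drawn i.i.d. Bernoulli(f) from the common-marker
#' frequency spectrum; extra (rare) sites start as all-reference and are only
#' introduced by [plant_risk_haplotype()].
#'
#' @param ped an `fs_pedigree`.
#' @param markers `fs_markers` from [sim_marker_map()].
#' @param config an [sim_config()] object.
#' @return list with `haps` (matrix `2 * n_founders` x markers), `ids`
#'   (founder-haplotype labels `"<id>.0"`, `"<id>.1"`) and `freqs` (the
#'   background frequencies used; 0 at extra sites).
#' @export
sim_founder_haplotypes <- function(ped, markers, config) {
  founders <- ped$ind$id[is.na(ped$ind$father) & is.na(ped$ind$mother)]
  m <- nrow(markers)
  is_extra <- attr(markers, "is_extra")
  if (is.null(is_extra)) is_extra <- rep(FALSE, m)
  f <- stats::runif(m, config$common_af_range[1], config$common_af_range[2])
  f[is_extra] <- 0
  H <- matrix(stats::rbinom(2L * length(founders) * m, 1L, rep(f, each = 2L * length(founders))),
              nrow = 2L * length(founders), ncol = m)
  ids <- paste0(rep(founders, each = 2), ".", rep(0:1, length(founders)))
  rownames(H) <- ids
  list(haps = H, ids = ids, freqs = f)
}

#' Plant a risk haplotype into a founder
#'
#' Marks one chromosome copy of one founder as the risk backbone over a
#' multi-megabase interval and embeds rare annotated variants on it. The
#' embedded alternate alleles are guaranteed absent from every other founder
#' haplotype.
#'
#' @param founder_haps list from [sim_founder_haplotypes()].
#' @param markers the `fs_markers` map (must already contain the variant
#'   sites, via `extra` in [sim_marker_map()]).
#' @param spec list with `label` (founder-pair label), `founder_id`, `copy`
#'   (0/1), `chrom`, `start_bp`, `end_bp`, and `variants` (data.frame with at
#'   least `pos_bp` and `id`; remaining columns are annotation fields).
#' @return list with the modified `founder_haps` and `planted`, a record
#'   holding the founder-haplotype id, interval, backbone alleles and
#'   embedded variants.
#' @export
plant_risk_haplotype <- function(founder_haps, markers, spec) {
  ch_idx <- which(markers$chrom == spec$chrom)
  if (!length(ch_idx)) stop("planted interval outside the marker map")
  if (spec$start_bp < 1 || spec$end_bp > max(markers$pos_bp[ch_idx]) + 1e6)
    stop("planted interval outside the marker map")
  hap_id <- paste0(spec$founder_id, ".", spec$copy)
  row <- match(hap_id, founder_haps$ids)
  if (is.na(row)) stop("founder ", spec$founder_id, " has no haplotypes")
  in_iv <- which(markers$chrom == spec$chrom &
                 markers$pos_bp >= spec$start_bp & markers$pos_bp <= spec$end_bp)
  vpos <- match(paste(spec$chrom, as.integer(spec$variants$pos_bp)),
                paste(markers$chrom, markers$pos_bp))
  if (anyNA(vpos)) stop("planted variant site(s) missing from the marker map")
  founder_haps$haps[row, vpos] <- 1L
  other <- setdiff(seq_len(nrow(founder_haps$haps)), row)
  founder_haps$haps[other, vpos] <- 0L
  planted <- list(label = spec$label, founder_hap = hap_id,
                  chrom = spec$chrom, start_bp = spec$start_bp,
                  end_bp = spec$end_bp,
                  backbone = founder_haps$haps[row, in_iv],
                  backbone_idx = in_iv,
                  variants = spec$variants, variant_idx = vpos)
  list(founder_haps = founder_haps, planted = planted)
}

#' Gene-drop simulation down a pedigree
#'
#' Standard gene dropping: each meiosis draws a crossover count from
#' Poisson(map length in Morgans) with breakpoints uniform on the cM map and
#' no interference, then copies a mosaic of the parental haplotypes to the
#' child. Founder-haplotype origins are propagated alongside the alleles, so
#' the transmitted mosaic of every individual is known exactly. Haplotype
#' allele errors are applied i.i.d. at `config$error_rate` to sampled
#' individuals' phased alleles (after the truth is recorded).
#'
#' Optional transmission steering conditions designated meioses so that a
#' designated founder haplotype is carried at a designated position: the
#' crossover pattern is drawn unconditionally and only the (symmetric)
#' starting-phase choice is fixed, which leaves recombination at the segment
#' edges unbiased. This emulates the ascertainment of haplotype carriers in
#' a densely affected pedigree.
#'
#' @param ped an `fs_pedigree`.
#' @param founder_haps list from [sim_founder_haplotypes()] (possibly after
#'   [plant_risk_haplotype()]).
#' @param markers the `fs_markers` map.
#' @param config an [sim_config()] object.
#' @param steer optional data.frame with columns `child`, `parent`,
#'   `origin` (founder-haplotype id) and `chrom`, `mid_bp`: for the meiosis
#'   from `parent` into `child`, force carriage of `origin` at `mid_bp`.
#' @return list with `panel` (an `fs_phased` over the sampled individuals,
#'   errors applied) and `truth` (per sampled individual and copy, the
#'   origin mosaic as intervals tiling each chromosome; see
#'   [truth_mosaics()]).
#' @export
gene_drop <- function(ped, founder_haps, markers, config, steer = NULL) {
  if (nrow(markers) == 0) stop("marker map is empty")
  ind <- ped$ind
  n <- nrow(ind)
  m <- nrow(markers)
  chroms <- unique(markers$chrom)
  ch_idx <- lapply(chroms, function(ch) which(markers$chrom == ch))
  names(ch_idx) <- chroms
  Lcm <- vapply(chroms, function(ch) {
    len_bp <- config$chrom_lengths[[ch]]
    if (is.null(len_bp)) len_bp <- max(markers$pos_bp[ch_idx[[ch]]])
    len_bp / 1e6 * config$recomb_rate_cM_per_Mb
  }, numeric(1))

  H <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  O <- matrix(NA_integer_, nrow = 2L * n, ncol = m)  # founder-hap origin index
  row_of <- function(id, copy) 2L * match(id, ind$id) - 1L + copy

  founders <- ind$id[is.na(ind$father) & is.na(ind$mother)]
  for (fid in founders) {
    for (copy in 0:1) {
      hid <- paste0(fid, ".", copy)
      r <- match(hid, founder_haps$ids)
      H[row_of(fid, copy), ] <- founder_haps$haps[r, ]
      O[row_of(fid, copy), ] <- r
    }
  }

  steer_key <- if (!is.null(steer) && nrow(steer))
    paste(steer$child, steer$parent) else character(0)

  meiosis_pattern <- function(cM, L) {
    k <- stats::rpois(1, L / 100)
    phase <- sample(0:1, 1)
    if (k == 0) return(rep(phase, length(cM)))
    br <- sort(stats::runif(k, 0, L))
    (phase + findInterval(cM, br)) %% 2L
  }

  ord <- order(ind$generation)
  for (i in ord) {
    if (is.na(ind$father[i])) next
    kid <- ind$id[i]
    for (copy in 0:1) {
      par <- if (copy == 0) ind$father[i] else ind$mother[i]
      r0 <- row_of(par, 0L); r1 <- row_of(par, 1L)
      target <- row_of(kid, copy)
      for (ch in chroms) {
        idx <- ch_idx[[ch]]
        cM <- markers$pos_cM[idx]
        act <- meiosis_pattern(cM, Lcm[[ch]])
        sk <- which(steer_key == paste(kid, par))
        if (length(sk)) {
          s <- steer[sk[1], ]
          if (s$chrom == ch) {
            j <- idx[which.min(abs(markers$pos_bp[idx] - s$mid_bp))]
            want <- match(s$origin, founder_haps$ids)
            jj <- match(j, idx)
            have <- if (act[jj] == 0L) O[r0, j] else O[r1, j]
            alt_have <- if (act[jj] == 0L) O[r1, j] else O[r0, j]
            if (!identical(have, want) && identical(alt_have, want))
              act <- 1L - act
          }
        }
        pick0 <- act == 0L
        H[target, idx] <- ifelse(pick0, H[r0, idx], H[r1, idx])
        O[target, idx] <- ifelse(pick0, O[r0, idx], O[r1, idx])
      }
    }
  }

  samples <- ind$id[ind$sampled]
  rows <- as.vector(rbind(2L * match(samples, ind$id) - 1L,
                          2L * match(samples, ind$id)))
  Hs <- H[rows, , drop = FALSE]
  truth <- truth_mosaics(O[rows, , drop = FALSE], samples, markers,
                         founder_haps$ids, config$chrom_lengths)
  if (config$error_rate > 0) {
    flip <- matrix(stats::runif(length(Hs)) < config$error_rate, nrow = nrow(Hs))
    flip[is.na(Hs)] <- FALSE
    Hs[flip] <- 1L - Hs[flip]
  }
  list(panel = phased_panel(markers, Hs, samples), truth = truth)
}

# Convert per-marker origin indices to interval mosaics tiling each
# chromosome; boundaries are placed at the midpoint between markers where
# the origin changes (resolution = inter-marker spacing).
truth_mosaics <- function(O, samples, markers, hap_ids, chrom_lengths) {
  chroms <- unique(markers$chrom)
  mos <- list()
  for (si in seq_along(samples)) {
    per_copy <- list()
    for (copy in 0:1) {
      r <- 2L * si - 1L + copy
      per_chrom <- list()
      for (ch in chroms) {
        idx <- which(markers$chrom == ch)
        o <- O[r, idx]
        pos <- markers$pos_bp[idx]
        rl <- rle(o)
        ends_i <- cumsum(rl$lengths)
        starts_i <- c(1L, utils::head(ends_i, -1) + 1L)
        len <- chrom_lengths[[ch]]
        if (is.null(len)) len <- max(pos)
        start_bp <- c(1, round((pos[utils::head(ends_i, -1)] +
                                pos[utils::head(ends_i, -1) + 1L]) / 2) + 1)
        end_bp <- c(start_bp[-1] - 1, len)
        per_chrom[[ch]] <- data.frame(start_bp = start_bp, end_bp = end_bp,
                                      origin = hap_ids[rl$values])
      }
      per_copy[[copy + 1L]] <- per_chrom
    }
    mos[[samples[si]]] <- per_copy
  }
  structure(list(mosaics = mos, samples = samples, hap_ids = hap_ids),
            class = "fs_truth")
}

#' Derive the carrier truth for a planted haplotype
#'
#' A sampled haplotype copy carries the planted haplotype when its origin
#' mosaic assigns the planted founder haplotype across the planted
#' interval's midpoint; the carried interval is the overlap of that mosaic
#' segment with the planted interval.
#'
#' @param truth `fs_truth` from [gene_drop()].
#' @param planted planted-haplotype record from [plant_risk_haplotype()].
#' @return data.frame with one row per carrying copy: `id`, `copy`,
#'   `start_bp`, `end_bp` (carried overlap with the planted interval) and
#'   `run_start_bp`, `run_end_bp` (the full founder-haplotype run around the
#'   midpoint, which can extend beyond the planted interval). Attribute
#'   `"core"` is the carrier intersection clipped to the planted interval;
#'   attribute `"shared"` is the unclipped intersection - the ground-truth
#'   IBD segment shared by the carrier set, against which detected and
#'   refined boundaries should be compared.
#' @export
planted_carriers <- function(truth, planted) {
  mid <- (planted$start_bp + planted$end_bp) / 2
  out <- NULL
  for (id in truth$samples) {
    for (copy in 0:1) {
      mo <- truth$mosaics[[id]][[copy + 1L]][[planted$chrom]]
      hit <- mo$origin == planted$founder_hap &
        mo$start_bp <= mid & mo$end_bp >= mid
      if (any(hit)) {
        seg <- mo[which(hit)[1], ]
        out <- rbind(out, data.frame(
          id = id, copy = copy,
          start_bp = max(seg$start_bp, planted$start_bp),
          end_bp = min(seg$end_bp, planted$end_bp),
          run_start_bp = seg$start_bp, run_end_bp = seg$end_bp))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(id = character(0), copy = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      run_start_bp = numeric(0), run_end_bp = numeric(0))
  attr(out, "core") <- if (nrow(out)) c(max(out$start_bp), min(out$end_bp))
                       else c(NA_real_, NA_real_)
  attr(out, "shared") <- if (nrow(out)) c(max(out$run_start_bp), min(out$run_end_bp))
                         else c(NA_real_, NA_real_)
  out
}

#' Founder-haplotype origins of cluster members
#'
#' Truth-based evaluation helper: the recorded founder-haplotype origin of
#' every member copy of a detected cluster at the cluster midpoint. Used to
#' decide whether a detected cluster corresponds to a specific planted
#' founder haplotype.
#'
#' @param truth `fs_truth` from [gene_drop()].
#' @param cluster a cluster from [multi_ibd_clusters()] (or a refined
#'   candidate).
#' @return Character vector of origin ids, one per member copy.
#' @export
member_origins <- function(truth, cluster) {
  mid <- (cluster$start + cluster$end) / 2
  vapply(seq_len(nrow(cluster$members)), function(k) {
    mo <- truth$mosaics[[cluster$members$id[k]]][[cluster$members$hap[k] + 1L]][[cluster$chrom]]
    seg <- mo[mo$start_bp <= mid & mo$end_bp >= mid, ]
    if (nrow(seg)) seg$origin[1] else NA_character_
  }, character(1))
}

#' Assign phenotypes from carrier status
#'
#' Penetrance/phenocopy Bernoulli model: carriers of at least one planted
#' haplotype are affected (diagnosis TS) with probability `penetrance`,
#' non-carriers with probability `phenocopy`. When `match_design` is set, the
#' affected count among sampled individuals is forced to `n_affected` by
#' flipping stochastic assignments (ascertainment emulation); assignments
#' that are deterministic under the configuration (probability 0 or 1) are
#' never overridden. Affected individuals receive occasional co-morbid
#' probable labels to exercise diagnosis-set handling.
#'
#' @param ped an `fs_pedigree`.
#' @param carrier_ids character vector of sampled carrier ids (union over
#'   planted haplotypes).
#' @param config an [sim_config()] object.
#' @return The pedigree with an updated `diagnosis` list.
#' @export
assign_phenotypes <- function(ped, carrier_ids, config) {
  samples <- ped$ind$id[ped$ind$sampled]
  carrier <- samples %in% carrier_ids
  p <- ifelse(carrier, config$penetrance, config$phenocopy)
  affected <- stats::runif(length(samples)) < p
  deterministic <- p %in% c(0, 1)
  if (config$match_design) {
    want <- config$n_affected
    excess <- sum(affected) - want
    if (excess > 0) {
      flippable <- which(affected & !deterministic & !carrier)
      if (length(flippable) < excess)
        flippable <- c(flippable, which(affected & !deterministic & carrier))
      drop <- utils::head(flippable, excess)
      affected[drop] <- FALSE
    } else if (excess < 0) {
      flippable <- which(!affected & !deterministic & carrier)
      if (length(flippable) < -excess)
        flippable <- c(flippable, which(!affected & !deterministic & !carrier))
      affected[utils::head(flippable, -excess)] <- TRUE
    }
  }
  dx <- ped$diagnosis
  for (i in seq_along(samples)) {
    if (affected[i]) {
      d <- "TS"
      if (stats::runif(1) < 0.3) d <- c(d, "ADHD_probable")
      if (stats::runif(1) < 0.15) d <- c(d, "OCD_probable")
      dx[[samples[i]]] <- d
    } else {
      dx[[samples[i]]] <- "unaffected"
    }
  }
  ped$diagnosis <- dx
  ped
}

#' Simulate array-genotyped control cohorts
#'
#' Two control panels (default sizes 49 and 42, emulating the two real
#' cohorts) drawn i.i.d. from the background allele-frequency pool,
#' restricted to the array marker subset; planted alternate alleles are
#' absent by construction (their background frequency is 0). Controls are
#' unphased, matching array data. A planted haplotype can optionally be
#' spiked into controls (`contaminate`), giving the named number of controls
#' one chromosome carrying the planted backbone.
#'
#' @param markers full `fs_markers` map.
#' @param freqs background allele frequencies (from
#'   [sim_founder_haplotypes()]).
#' @param array_idx integer indices of the array marker subset.
#' @param n_controls integer vector of cohort sizes.
#' @param contaminate optional data.frame (`chrom`, `pos_bp`, `allele`)
#'   giving a haplotype to spike into controls - typically a planted founder
#'   haplotype's alleles across its chromosome, emulating a haplotype that
#'   is common in the population; `n_contam` controls of each cohort receive
#'   it as one chromosome copy.
#' @param n_contam controls per cohort receiving the contaminating haplotype.
#' @return list of `fs_geno` panels, one per cohort.
#' @export
make_controls <- function(markers, freqs, array_idx, n_controls = c(49L, 42L),
                          contaminate = NULL, n_contam = 3L) {
  if (!length(array_idx)) stop("array marker subset is empty")
  m <- length(array_idx)
  f <- freqs[array_idx]
  sub <- markers[array_idx, , drop = FALSE]
  class(sub) <- c("fs_markers", "data.frame")
  panels <- list()
  for (k in seq_along(n_controls)) {
    nk <- n_controls[k]
    if (nk == 0) {
      panels[[k]] <- genotype_panel(sub, matrix(integer(0), 0, m), character(0))
      next
    }
    h1 <- matrix(stats::rbinom(nk * m, 1L, rep(f, each = nk)), nrow = nk)
    h2 <- matrix(stats::rbinom(nk * m, 1L, rep(f, each = nk)), nrow = nk)
    if (!is.null(contaminate)) {
      j <- match(paste(sub$chrom, sub$pos_bp),
                 paste(contaminate$chrom, contaminate$pos_bp))
      hit <- which(!is.na(j))
      for (i in seq_len(min(n_contam, nk)))
        h1[i, hit] <- contaminate$allele[j[hit]]
    }
    panels[[k]] <- genotype_panel(sub, h1 + h2,
                                  sprintf("C%d_%03d", k, seq_len(nk)))
  }
  names(panels) <- paste0("cohort", seq_along(panels))
  panels
}

# Table-2-style annotation rows for the default planted variants; intervals
# scale with the configured chromosome lengths (3.53 Mb / 3.0 Mb at the
# default 50 Mb chromosomes, the published length scale).
default_planted_specs <- function(config) {
  len1 <- config$chrom_lengths[[1]]
  s1 <- round(0.40 * len1)
  e1 <- s1 + min(3.53e6, round(0.25 * len1))
  mid1 <- (s1 + e1) / 2
  specs <- list(
    clean = list(
      label = "B", chrom = names(config$chrom_lengths)[1],
      start_bp = s1, end_bp = e1, copy = 0L,
      variants = data.frame(
        # near the interval midpoint, so every steered carrier inherits them
        pos_bp = round(c(mid1 - 0.05 * (e1 - s1), mid1 + 0.04 * (e1 - s1))),
        id = c("sim_rv_mis", "sim_rv_int"),
        consequence = c("missense", "intronic"),
        gene = c("GENE1", "GENE2"), aa_sub = c("S/L", NA),
        sift_pred = c("deleterious_low_confidence", NA),
        sift_score = c(0, NA),
        polyphen_pred = c("probably_damaging", NA),
        polyphen_score = c(0.999, NA),
        cadd_phred = c(23.8, 17.7), ncer = c(NA, 94.0),
        af_amr = c(0.001976, 0.000661)))
  )
  if (length(config$chrom_lengths) >= 2) {
    len2 <- config$chrom_lengths[[2]]
    s2 <- round(0.50 * len2)
    e2 <- s2 + min(3e6, round(0.2 * len2))
    specs$contaminated <- list(
      label = "D", chrom = names(config$chrom_lengths)[2],
      start_bp = s2, end_bp = e2, copy = 0L,
      variants = data.frame(
        pos_bp = round((s2 + e2) / 2), id = "sim_rv_contam",
        consequence = "intronic", gene = "GENE3", aa_sub = NA,
        sift_pred = NA, sift_score = NA,
        polyphen_pred = NA, polyphen_score = NA,
        cadd_phred = 21.2, ncer = 97.3, af_amr = 0.000661))
  }
  specs
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator: pedigree, marker map with planted rare-variant
#' sites, founder haplotypes, planted risk haplotypes (one clean, one
#' spiked into the controls when `contaminate_controls`), steered gene drop
#' so each planted haplotype reaches its designated carriers, phenotypes,
#' control cohorts, and a variant-annotation table covering every site.
#'
#' @param config an [sim_config()] object.
#' @param planted_specs list of planting specifications (see
#'   [plant_risk_haplotype()]); `founder_id` defaults to the father of the
#'   named pair. Defaults emulate the study: a ~3.5 Mb haplotype from pair B
#'   carrying one qualifying deleterious missense plus one sub-threshold
#'   intronic variant, and a second haplotype from pair D used as the
#'   control-contamination probe.
#' @param n_carriers designated carriers per planted haplotype.
#' @param contaminate_controls spike the second planted haplotype into the
#'   control cohorts.
#' @return list of class `fs_study` with elements `pedigree`, `panel`
#'   (phased, all markers), `wgs` (dosage view), `controls`, `truth`,
#'   `planted`, `carriers` (per planted haplotype), `annotations`,
#'   `array_idx`, `freqs`, `config`.
#' @export
simulate_study <- function(config = sim_config(), planted_specs = NULL,
                           n_carriers = 3L, contaminate_controls = TRUE) {
  set.seed(config$seed)
  ped <- local({
    cfg2 <- config
    cfg2$seed <- sample.int(2^31 - 1, 1)
    simulate_pedigree(cfg2)
  })
  if (is.null(planted_specs)) planted_specs <- default_planted_specs(config)
  extra <- do.call(rbind, lapply(planted_specs, function(s)
    data.frame(chrom = s$chrom, pos_bp = s$variants$pos_bp,
               ref = "C", alt = "A", id = s$variants$id)))
  markers <- sim_marker_map(config, extra = extra)
  fh <- sim_founder_haplotypes(ped, markers, config)
  planted <- list()
  for (nm in names(planted_specs)) {
    s <- planted_specs[[nm]]
    if (is.null(s$founder_id)) s$founder_id <- ped$founder_pairs[[s$label]][1]
    res <- plant_risk_haplotype(fh, markers, s)
    fh <- res$founder_haps
    planted[[nm]] <- res$planted
  }
  # designate carriers and build the steering table
  paths <- attr(ped, "paths")
  recipes <- attr(ped, "recipes")
  steer <- NULL
  carriers <- list()
  for (nm in names(planted)) {
    pl <- planted[[nm]]
    eligible <- names(recipes)[vapply(recipes, function(s) pl$label %in% s, logical(1))]
    eligible <- eligible[order(lengths(recipes[eligible]))]
    ids <- utils::head(eligible, n_carriers)
    if (length(ids) < min(3L, n_carriers))
      stop("fewer than three sampled individuals descend from founder pair ",
           pl$label, "; adjust the recipes")
    carriers[[nm]] <- ids
    mid <- (pl$start_bp + pl$end_bp) / 2
    for (id in ids) {
      chain <- paths[[id]][[pl$label]]
      parents <- c(pl$founder_hap, utils::head(chain, -1))
      parents[1] <- sub("\\.\\d$", "", parents[1])
      steer <- rbind(steer, data.frame(
        child = chain, parent = parents, origin = pl$founder_hap,
        chrom = pl$chrom, mid_bp = mid))
    }
  }
  drop <- gene_drop(ped, fh, markers, config, steer = steer)
  carrier_union <- unique(unlist(lapply(planted, function(pl)
    unique(planted_carriers(drop$truth, pl)$id))))
  ped <- assign_phenotypes(ped, carrier_union, config)

  # array subset: every k-th common marker
  is_extra <- attr(markers, "is_extra")
  common_idx <- which(!is_extra)
  k <- max(1L, round(config$wgs_density / config$array_density))
  array_idx <- common_idx[seq(1, length(common_idx), by = k)]
  contam <- NULL
  if (contaminate_controls && !is.null(planted$contaminated)) {
    pl <- planted$contaminated
    row <- match(pl$founder_hap, fh$ids)
    on_ch <- which(markers$chrom == pl$chrom)
    contam <- data.frame(chrom = pl$chrom, pos_bp = markers$pos_bp[on_ch],
                         allele = fh$haps[row, on_ch])
  }
  controls <- make_controls(markers, fh$freqs, array_idx, contaminate = contam)

  anno <- sim_annotations(markers, fh$freqs, planted_specs)
  structure(list(pedigree = ped, panel = drop$panel,
                 wgs = as_genotype_panel(drop$panel),
                 controls = controls, truth = drop$truth, planted = planted,
                 carriers = carriers, annotations = anno,
                 array_idx = array_idx, freqs = fh$freqs, config = config),
            class = "fs_study")
}

# Annotation table: planted variants carry their specified (Table-2-style)
# annotations; background markers get population frequencies equal to their
# simulation frequencies and unremarkable deleteriousness scores.
sim_annotations <- function(markers, freqs, planted_specs) {
  anno <- data.frame(id = markers$id, chrom = markers$chrom,
                     pos = markers$pos_bp, ref = markers$ref,
                     alt = markers$alt,
                     af_AMR = round(freqs, 6),
                     consequence = "intergenic", gene = NA_character_,
                     aa_sub = NA_character_,
                     sift_pred = NA_character_, sift_score = NA_real_,
                     polyphen_pred = NA_character_, polyphen_score = NA_real_,
                     cadd_phred = round(stats::runif(nrow(markers), 0, 9.5), 2),
                     ncer = round(stats::runif(nrow(markers), 0, 90), 2))
  for (s in planted_specs) {
    v <- s$variants
    i <- match(v$id, anno$id)
    anno$af_AMR[i] <- v$af_amr
    anno$consequence[i] <- v$consequence
    anno$gene[i] <- v$gene
    anno$aa_sub[i] <- v$aa_sub
    anno$sift_pred[i] <- v$sift_pred
    anno$sift_score[i] <- v$sift_score
    anno$polyphen_pred[i] <- v$polyphen_pred
    anno$polyphen_score[i] <- v$polyphen_score
    anno$cadd_phred[i] <- v$cadd_phred
    anno$ncer[i] <- v$ncer
  }
  anno
}
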