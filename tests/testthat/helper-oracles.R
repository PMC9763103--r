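# Independent oracles and small fixture builders used across the suite.

# -- pedigree builders -------------------------------------------------------

# four-generation toy pedigree: two founder pairs, a married-in founder M1
# shared by two half-sib lines that rejoin at e1
toy_pedigree <- function() {
  ind <- data.frame(
    id     = c("Af", "Am", "Bf", "Bm", "M1", "c1", "c2", "d1", "d2", "e1"),
    father = c(NA, NA, NA, NA, NA, "Af", "Bf", "c1", "c2", "d1"),
    mother = c(NA, NA, NA, NA, NA, "Am", "Bm", "M1", "M1", "d2"),
    sex    = c("male", "female", "male", "female", "female",
               "male", "male", "male", "female", "male"),
    generation = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L),
    sampled = FALSE)
  new_pedigree(ind, founder_pairs = list(A = c("Af", "Am"), B = c("Bf", "Bm")))
}

# nuclear family: two founder couples, two full sibs
sib_pedigree <- function() {
  ind <- data.frame(
    id = c("f", "m", "s1", "s2"),
    father = c(NA, NA, "f", "f"),
    mother = c(NA, NA, "m", "m"),
    sex = c("male", "female", "male", "female"),
    generation = c(0L, 0L, 1L, 1L),
    sampled = c(FALSE, FALSE, TRUE, TRUE))
  new_pedigree(ind, founder_pairs = list(A = c("f", "m")))
}

# recursive ancestor enumeration, independent of the package's BFS
oracle_ancestors <- function(ped, id) {
  climb <- function(i) {
    out <- i
    fa <- ped$ind[i, "father"]; mo <- ped$ind[i, "mother"]
    if (!is.na(fa)) out <- c(out, climb(fa))
    if (!is.na(mo)) out <- c(out, climb(mo))
    unique(out)
  }
  climb(id)
}

oracle_founder_ancestry <- function(ped, id) {
  anc <- oracle_ancestors(ped, id)
  labs <- names(ped$founder_pairs)
  sort(labs[vapply(labs, function(l) any(ped$founder_pairs[[l]] %in% anc),
                   logical(1))])
}

# all-pairs shortest-path meiotic distance via explicit path enumeration
oracle_meiotic_distance <- function(ped, a, b) {
  da <- depths_oracle(ped, a)
  db <- depths_oracle(ped, b)
  common <- intersect(names(da), names(db))
  if (!length(common)) return(Inf)
  min(vapply(common, function(x) da[[x]] + db[[x]], numeric(1)))
}

depths_oracle <- function(ped, id) {
  res <- list()
  walk <- function(i, d) {
    if (is.null(res[[i]]) || res[[i]] > d) res[[i]] <<- d
    fa <- ped$ind[i, "father"]; mo <- ped$ind[i, "mother"]
    if (!is.na(fa)) walk(fa, d + 1)
    if (!is.na(mo)) walk(mo, d + 1)
  }
  walk(id, 0)
  res
}

# -- exact HWE oracle: direct factorial formula ------------------------------

oracle_hwe <- function(aa, ab, bb) {
  n <- aa + ab + bb
  n_minor <- min(2 * aa + ab, 2 * bb + ab)
  if (n_minor == 0) return(1)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  hs <- hs[(n_minor - hs) / 2 + hs <= n]
  logp <- vapply(hs, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lfactorial(n) - lfactorial(hom_minor) - lfactorial(h) -
      lfactorial(hom_major) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(ab, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# -- allele-assignment oracle: explicit diplotype enumeration ----------------

oracle_assign_allele <- function(carrier_dosage, carrier_copies,
                                 noncarrier_dosage) {
  ok <- !is.na(carrier_dosage)
  d <- carrier_dosage[ok]
  cc <- carrier_copies[ok]
  k <- length(d)
  achievable <- integer(0)
  if (k == 0) {
    achievable <- 0:1
  } else {
    orderings <- expand.grid(rep(list(0:1), k))
    for (g in seq_len(nrow(orderings))) {
      vals <- integer(0)
      good <- TRUE
      for (i in seq_len(k)) {
        al <- c(rep(1L, d[i]), rep(0L, 2L - d[i]))
        if (orderings[g, i] == 1) al <- rev(al)
        if (cc[i] == 2L) {
          if (al[1] != al[2]) { good <- FALSE; break }
          vals <- c(vals, al[1])
        } else vals <- c(vals, al[1])
      }
      if (good && length(unique(vals)) == 1L)
        achievable <- union(achievable, vals[1])
    }
  }
  if (length(achievable) == 0)
    return(list(allele = NA_integer_, status = "discordant"))
  if (length(achievable) == 1)
    return(list(allele = achievable, status = "assigned"))
  nc <- noncarrier_dosage[!is.na(noncarrier_dosage)]
  alt_absent <- all(nc == 0L)
  ref_absent <- all(nc == 2L)
  if (length(nc) && xor(alt_absent, ref_absent))
    return(list(allele = if (alt_absent) 1L else 0L, status = "assigned"))
  list(allele = NA_integer_, status = "unassigned")
}

# -- panel builders ----------------------------------------------------------

# phased panel over one chromosome from an explicit haplotype matrix
toy_panel <- function(haps, pos = NULL, chrom = "1") {
  m <- ncol(haps)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  mm <- marker_map(rep(chrom, m), pos, pos / 1e6, rep("A", m), rep("G", m))
  phased_panel(mm, haps, sprintf("S%02d", seq_len(nrow(haps) / 2)))
}

# small simulated study used by several tests (single clean haplotype)
small_study <- function(seed = 42, error_rate = 0, n_carriers = 3L) {
  cfg <- sim_config(chrom_lengths = c(`1` = 3e7), wgs_density = 80,
                    error_rate = error_rate, penetrance = 1, phenocopy = 0,
                    match_design = FALSE, seed = seed)
  specs <- list(clean = list(
    label = "B", chrom = "1", start_bp = 12e6, end_bp = 15.5e6, copy = 0L,
    variants = data.frame(
      pos_bp = 13.7e6, id = "rv1", consequence = "missense",
      gene = "G1", aa_sub = "S/L",
      sift_pred = "deleterious", sift_score = 0.01,
      polyphen_pred = "probably_damaging", polyphen_score = 0.99,
      cadd_phred = 25, ncer = NA, af_amr = 0.002)))
  simulate_study(cfg, planted_specs = specs, n_carriers = n_carriers,
                 contaminate_controls = FALSE)
}
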