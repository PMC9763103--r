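test_that("LOD contributions have the closed single-site forms", {
  # both copies carry the alt allele at f = 0.1: ratio -> 1/f as eps -> 0
  lod <- lod_score(1L, 1L, 0.1, eps = 1e-12)
  expect_equal(lod, 1, tolerance = 1e-6)
  # matching ref alleles: log10(1 / (1 - f))
  expect_equal(lod_score(0L, 0L, 0.2, eps = 1e-12), log10(1 / 0.8),
               tolerance = 1e-6)
  # mismatching site with the default error floor: direct evaluation
  eps <- 0.0025; f <- 0.3
  p_ibd <- f * (1 - eps) * eps + (1 - f) * eps * (1 - eps)
  expect_equal(lod_score(1L, 0L, f, eps = eps),
               log10(p_ibd / (f * (1 - f))))
  # degenerate frequency: site skipped with warning
  expect_warning(v <- lod_score(1L, 1L, 1, eps = eps), "frequency")
  expect_equal(v, 0)
})

test_that("LOD is additive over disjoint intervals and penalises mismatches", {
  set.seed(20)
  f <- runif(50, 0.05, 0.5)
  a <- rbinom(50, 1, f); b <- a
  b[c(10, 30)] <- 1L - b[c(10, 30)]
  total <- lod_score(a, b, f)
  per_site <- vapply(seq_len(50), function(i)
    lod_score(a[i], b[i], f[i]), numeric(1))
  expect_equal(total, sum(per_site), tolerance = 1e-9)
  expect_equal(total,
               lod_score(a, b, f, interval = c(1L, 25L)) +
                 lod_score(a, b, f, interval = c(26L, 50L)),
               tolerance = 1e-9)
  # appending a mismatching site strictly lowers the score
  expect_lt(lod_score(c(a, 1L), c(b, 0L), c(f, 0.3)), total)
})

test_that("a transmitted sib block is recovered as one segment", {
  cfg <- sim_config(chrom_lengths = c(`1` = 4e7), wgs_density = 100,
                    error_rate = 0, seed = 23)
  found <- 0
  for (s in 1:5) {
    cfg$seed <- 23 + s
    set.seed(cfg$seed)
    ped <- sib_pedigree()
    mm <- sim_marker_map(cfg)
    fh <- sim_founder_haplotypes(ped, mm, cfg)
    gd <- gene_drop(ped, fh, mm, cfg)
    # true shared regions between the sibs' paternal copies
    m1 <- gd$truth$mosaics[["s1"]][[1]][["1"]]
    m2 <- gd$truth$mosaics[["s2"]][[1]][["1"]]
    segs <- pairwise_ibd(gd$panel, ibd_params())
    segs <- segs[segs$hap_a == 0 & segs$hap_b == 0, ]
    # pick a true shared run > 3 Mb if one exists
    for (i in seq_len(nrow(m1))) {
      ov <- m2[m2$origin == m1$origin[i] &
                 m2$start_bp <= m1$end_bp[i] & m2$end_bp >= m1$start_bp[i], ]
      if (!nrow(ov)) next
      ts <- max(m1$start_bp[i], ov$start_bp[1])
      te <- min(m1$end_bp[i], ov$end_bp[nrow(ov)])
      if (te - ts < 3e6) next
      found <- found + 1
      hit <- segs[segs$start <= ts + (te - ts) * 0.05 &
                    segs$end >= te - (te - ts) * 0.05, ]
      expect_gte(nrow(hit), 1)  # one segment covering >= 95% of the block
    }
  }
  expect_gte(found, 1)
})

test_that("segments below the length threshold are suppressed", {
  set.seed(30)
  m <- 2000
  f <- runif(m, 0.3, 0.5)
  a <- rbinom(m, 1, f)
  b <- rbinom(m, 1, f)
  shared <- 501:589  # 0.89 Mb at 10 kb spacing
  b[shared] <- a[shared]
  h <- rbind(a, a, b, b)
  panel <- toy_panel(h)
  segs <- pairwise_ibd(panel, ibd_params())
  if (nrow(segs)) expect_true(all(segs$end - segs$start > 1e6))
  expect_false(any(segs$start > 4.9e6 & segs$end < 6.0e6))
})

test_that("unrelated haplotype panels yield essentially no segments", {
  bad <- 0
  for (s in 1:30) {
    set.seed(400 + s)
    m <- 2000
    f <- runif(m, 0.05, 0.5)
    h <- matrix(rbinom(12 * m, 1, rep(f, each = 12)), nrow = 12)
    segs <- pairwise_ibd(toy_panel(h), ibd_params())
    if (nrow(segs) > 0) bad <- bad + 1
  }
  expect_lte(bad / 30, 0.05)
})

test_that("no emitted segment violates the length or LOD thresholds", {
  st <- small_study(seed = 44, error_rate = 0.001)
  params <- ibd_params()
  segs <- pairwise_ibd(subset_panel(st$panel,
                                    markers = which(st$freqs > 0)), params)
  expect_true(all(segs$end - segs$start > params$min_length_bp))
  expect_true(all(segs$lod > params$min_lod))
  expect_true(all(segs$n_markers >= 2))
})

test_that("copy number counts cluster membership per individual", {
  cl <- list(members = data.frame(id = c("a", "a", "b"), hap = c(0, 1, 0)))
  expect_equal(ibd_copy_number("a", cl), 2)
  expect_equal(ibd_copy_number("b", cl), 1)
  expect_equal(ibd_copy_number("c", cl), 0)
})

test_that("kinship estimates follow total sharing", {
  none <- data.frame(id_a = character(0), hap_a = integer(0),
                     id_b = character(0), hap_b = integer(0),
                     chrom = character(0), start = integer(0),
                     end = integer(0), n_markers = integer(0),
                     lod = numeric(0))
  expect_equal(relatedness_degree(none, 1e8)$label, "unrelated")
  # full-genome IBD2: both copy pairs share everything
  full <- data.frame(id_a = "x", hap_a = c(0, 1), id_b = "y", hap_b = c(0, 1),
                     chrom = "1", start = 1, end = 1e8,
                     n_markers = 1000, lod = 100)
  rd <- relatedness_degree(full, 1e8)
  expect_equal(rd$kinship, 0.5)
  expect_equal(rd$label, "duplicate/MZ")
  # half-genome IBD1
  half <- full[1, ]; half$end <- 5e7
  expect_equal(relatedness_degree(half, 1e8)$kinship, 0.125)
})

test_that("simulated third cousins are recognised within one degree", {
  # two lines of three extra generations below a sibling pair; 8 meioses
  ind <- data.frame(
    id = c("gf", "gm", "s1", "s2",
           "u1", "u2", "u3", "v1", "v2", "v3",
           "w1", "w2", "w3", "x1", "x2", "x3"),
    father = c(NA, NA, "gf", "gf",
               "s1", "u1", "u2", NA, NA, NA,
               "s2", "w1", "w2", NA, NA, NA),
    mother = c(NA, NA, "gm", "gm",
               "v1", "v2", "v3", NA, NA, NA,
               "x1", "x2", "x3", NA, NA, NA),
    sex = c("male", "female", "male", "male",
            "male", "male", "male", "female", "female", "female",
            "male", "male", "male", "female", "female", "female"),
    generation = c(0, 0, 1, 1, 2, 3, 4, 0, 0, 0, 2, 3, 4, 0, 0, 0),
    sampled = c(rep(FALSE, 5), FALSE, TRUE, rep(FALSE, 4), FALSE, TRUE,
                rep(FALSE, 3)))
  ped <- new_pedigree(ind, founder_pairs = list(A = c("gf", "gm")))
  expect_equal(meiotic_distance(ped, "u3", "w3"), 8)  # 3rd cousins
  lens <- stats::setNames(rep(1e8, 18), as.character(1:18))
  cfg <- sim_config(chrom_lengths = lens, wgs_density = 10,
                    recomb_rate_cM_per_Mb = 1, error_rate = 0, seed = 1)
  degs <- c()
  for (s in 1:12) {
    cfg$seed <- 700 + s
    set.seed(cfg$seed)
    mm <- sim_marker_map(cfg)
    fh <- sim_founder_haplotypes(ped, mm, cfg)
    gd <- gene_drop(ped, fh, mm, cfg)
    segs <- pairwise_ibd(gd$panel, ibd_params())
    degs <- c(degs, relatedness_degree(segs, sum(lens))$degree)
  }
  truth_degree <- 7  # 3rd cousins
  expect_lte(abs(stats::median(degs) - truth_degree), 1)
})
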