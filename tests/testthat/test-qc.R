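test_that("exact HWE test handles canonical cases", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact_test(9, 2, 9), oracle_hwe(9, 2, 9), tolerance = 1e-12)
  # symmetry under swapping homozygote classes
  for (tab in list(c(3, 5, 1), c(0, 4, 7), c(12, 1, 2))) {
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 hwe_exact_test(tab[3], tab[2], tab[1]))
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("pairwise r-squared matches the correlation formula", {
  expect_equal(pairwise_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(pairwise_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)  # anticorrelation
  set.seed(10)
  for (k in 1:20) {
    a <- rbinom(30, 2, 0.4); b <- rbinom(30, 2, 0.4)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(pairwise_r2(a, b), cor(a, b)^2, tolerance = 1e-12)
  }
  expect_equal(pairwise_r2(rep(1, 5), c(0, 1, 2, 1, 0)), 0)  # zero variance
  expect_error(pairwise_r2(1:3, 1:4), "length")
})

test_that("LD pruning removes linked markers and is idempotent", {
  set.seed(11)
  n <- 40
  base <- matrix(rbinom(2 * n * 200, 1, 0.3), nrow = 2 * n)
  # marker 2 duplicates marker 1 at 1 kb distance
  base[, 2] <- base[, 1]
  pos <- c(100000L, 101000L, sort(sample(110000:2000000, 198)))
  panel <- toy_panel(base, pos = pos)
  th <- qc_thresholds()
  kept <- ld_prune(panel, th)
  expect_true(sum(c(1, 2) %in% kept) == 1)  # exactly one duplicate retained
  # brute-force audit: no retained within-window pair exceeds the threshold
  dos <- as_genotype_panel(panel)$geno
  for (i in kept) for (j in kept) {
    if (j <= i || pos[j] - pos[i] > th$ld_window_bp) next
    expect_lte(pairwise_r2(dos[, i], dos[, j]), th$max_r2)
  }
  # idempotence
  pruned <- subset_panel(panel, markers = kept)
  expect_equal(ld_prune(pruned, th), seq_along(kept))
})

test_that("LD pruning keeps independent markers and ignores labels", {
  set.seed(12)
  h <- matrix(rbinom(60 * 30, 1, 0.5), nrow = 60)
  panel <- toy_panel(h)
  expect_equal(ld_prune(panel), seq_len(30))
  relabelled <- panel
  relabelled$markers$id <- sprintf("other_%d", seq_len(30))
  expect_equal(ld_prune(relabelled), ld_prune(panel))
})

test_that("QC filters apply in the documented order with a telescoping report", {
  set.seed(13)
  n <- 20; m <- 120
  f <- runif(m, 0.2, 0.5)
  h <- matrix(rbinom(2 * n * m, 1, rep(f, each = 2 * n)), nrow = 2 * n)
  panel <- toy_panel(h, pos = sort(sample(1:5e6, m)))
  ped <- new_pedigree(data.frame(
    id = panel$samples, father = NA_character_, mother = NA_character_,
    sex = "unknown", generation = 0L, sampled = TRUE))
  clean <- apply_qc(panel, ped, qc_thresholds(), prune = FALSE)
  expect_equal(clean$report$n_markers_out, m)
  expect_equal(unlist(clean$report[c("individuals_removed",
                                     "missingness_removed", "hwe_removed",
                                     "maf_removed", "mendelian_removed")]),
               c(individuals_removed = 0, missingness_removed = 0,
                 hwe_removed = 0, maf_removed = 0, mendelian_removed = 0))
  expect_equal(clean$panel$haps, panel$haps)

  # plant failures: a rare marker, a missing-heavy marker, a missing-heavy
  # individual, and a Mendelian error in a parent-offspring pair
  h2 <- h
  h2[, 1] <- rbinom(2 * n, 1, 0.02)            # MAF ~0.02 <= 0.05
  h2[sample(2 * n, 2), 2] <- NA                # 5% site missingness
  h2[1:2, seq(3, m, 2)] <- NA                  # individual 1 misses half
  ped2 <- ped
  ped2$ind$father[2] <- panel$samples[3]       # sample 2 is child of sample 3
  h2[3:4, 5] <- c(1L, 1L)                      # child dosage 2
  h2[5:6, 5] <- c(0L, 0L)                      # parent dosage 0
  dirty <- apply_qc(toy_panel(h2, pos = panel$markers$pos_bp), ped2,
                    qc_thresholds(), prune = FALSE)
  expect_equal(dirty$report$individuals_removed, 1)
  expect_gte(dirty$report$missingness_removed, 1)
  expect_gte(dirty$report$maf_removed, 1)
  expect_gte(dirty$report$mendelian_removed, 1)  # marker 5 plus chance hits

  removed <- dirty$report$n_markers_in - dirty$report$n_markers_out
  expect_equal(removed,
               dirty$report$missingness_removed + dirty$report$hwe_removed +
                 dirty$report$maf_removed + dirty$report$mendelian_removed +
                 dirty$report$ld_pruned)
  # the MAF-failing and Mendelian-failing markers are gone
  expect_false(1 %in% dirty$retained)
  expect_false(5 %in% dirty$retained)
})

test_that("markers violating HWE at p < 0.001 are removed", {
  set.seed(14)
  n <- 50; m <- 30
  h <- matrix(rbinom(2 * n * m, 1, 0.4), nrow = 2 * n)
  # marker 1: all heterozygous - extreme excess
  h[seq(1, 2 * n, 2), 1] <- 0L
  h[seq(2, 2 * n, 2), 1] <- 1L
  panel <- toy_panel(h, pos = sort(sample(1:1e7, m)))
  ped <- new_pedigree(data.frame(
    id = panel$samples, father = NA_character_, mother = NA_character_,
    sex = "unknown", generation = 0L, sampled = TRUE))
  out <- apply_qc(panel, ped, qc_thresholds(), prune = FALSE)
  expect_false(1 %in% out$retained)
  expect_gte(out$report$hwe_removed, 1)
})
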