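test_that("backbone equals the planted alleles on clean data", {
  st <- small_study(seed = 71, error_rate = 0)
  res <- run_full(st)
  pl <- st$planted$clean
  mid <- mean(c(pl$start_bp, pl$end_bp))
  k <- which(vapply(res$candidates, function(c)
    c$chrom == pl$chrom && c$start <= mid && c$end >= mid, logical(1)))[1]
  rh <- res$risk_haplotypes[[k]]
  amap <- rh$allele_map
  # alleles at planted backbone markers match the planted founder haplotype
  in_pl <- match(st$panel$markers$pos_bp[pl$backbone_idx], amap$pos)
  ok <- !is.na(in_pl)
  expect_gt(sum(ok), 100)
  expect_equal(amap$allele[in_pl[ok]], unname(pl$backbone[ok]))
  expect_equal(rh$summary$n_discordant, 0L)
  # no site outside the candidate interval appears in the map
  expect_true(all(amap$pos >= rh$cluster$start & amap$pos <= rh$cluster$end))
  # fractions partition the sites
  s <- rh$summary
  expect_equal(s$n_backbone + s$n_genotype + s$n_unassigned + s$n_discordant,
               s$n_sites)
})

test_that("backbone disagreement errors strictly and defers on request", {
  hap <- rbinom(100, 1, 0.5)
  h2 <- hap; h2[40] <- 1L - h2[40]
  haps <- rbind(hap, hap, h2, hap, hap, hap)
  panel <- toy_panel(haps, pos = seq(10000, by = 10000, length.out = 100))
  cl <- list(chrom = "1", start = 1e5, end = 9e5,
             members = data.frame(id = c("S01", "S02", "S03"), hap = c(0, 0, 0)),
             carriers = c("S01", "S02", "S03"))
  expect_error(build_backbone(cl, panel), "disagree")
  bb <- build_backbone(cl, panel, on_disagreement = "defer")
  expect_true(is.na(bb$allele[match(40, bb$idx)]))
  expect_equal(sum(is.na(bb$allele)), 1)
  # single member copy: backbone is that copy verbatim
  cl1 <- cl; cl1$members <- cl1$members[1, ]; cl1$carriers <- "S01"
  bb1 <- build_backbone(cl1, panel)
  expect_equal(bb1$allele, unname(hap[bb1$idx]))
})

test_that("allele assignment follows the carrier/non-carrier contrast rules", {
  # all carriers homozygous alt
  expect_equal(assign_allele(c(2L, 2L, 2L), c(1L, 1L, 1L), c(0L, 1L)),
               list(allele = 1L, status = "assigned"))
  # all carriers het, alt absent from non-carriers, ref present
  expect_equal(assign_allele(c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L)),
               list(allele = 1L, status = "assigned"))
  # all carriers het, both alleles seen in non-carriers: uninformative
  expect_equal(assign_allele(c(1L, 1L), c(1L, 1L), c(1L, 0L))$status,
               "unassigned")
  # an IBD2 carrier must be homozygous: het IBD2 carrier is discordant
  expect_equal(assign_allele(c(1L), c(2L), integer(0))$status, "discordant")
  # missing carrier genotypes are non-constraining
  expect_equal(assign_allele(c(NA, 2L), c(1L, 1L), c(0L)),
               list(allele = 1L, status = "assigned"))
  expect_error(assign_allele(c(1L), c(3L), c(0L)), "copy numbers")
})

test_that("assignment is monotone in non-carrier information", {
  set.seed(72)
  for (rep in 1:200) {
    k <- sample(1:3, 1)
    cd <- sample(c(0:2, NA), k, replace = TRUE)
    cc <- sample(1:2, k, replace = TRUE)
    nc <- sample(c(0:2, NA), 3, replace = TRUE)
    before <- assign_allele(cd, cc, nc[1:2])
    after <- assign_allele(cd, cc, nc)
    if (before$status == "assigned" && after$status == "assigned")
      expect_equal(after$allele, before$allele)
    if (before$status == "discordant") expect_equal(after$status, "discordant")
  }
})

test_that("fine-mapping recovers planted variants and flags error sites", {
  st <- small_study(seed = 73, error_rate = 0)
  res <- run_full(st)
  pl <- st$planted$clean
  mid <- mean(c(pl$start_bp, pl$end_bp))
  truth <- unique(planted_carriers(st$truth, pl)$id)
  k <- which(vapply(res$candidates, function(c)
    c$chrom == pl$chrom && c$start <= mid && c$end >= mid &&
      setequal(c$carriers, truth), logical(1)))[1]
  rh <- res$risk_haplotypes[[k]]
  v <- rh$allele_map[rh$allele_map$id == "rv1", ]
  expect_equal(nrow(v), 1)
  expect_equal(v$allele, 1L)
  # a pedigree-enriched rare variant may enter the phased backbone (its
  # in-sample MAF exceeds the QC floor) or be genotype-assigned
  expect_true(v$source %in% c("backbone", "genotype"))
  hs <- res$hap_variants[[k]]
  expect_true("rv1" %in% hs$id)

  # with haplotype errors the discordant fraction stays near expectation
  st2 <- small_study(seed = 74, error_rate = 0.002)
  res2 <- run_full(st2)
  truth2 <- unique(planted_carriers(st2$truth, st2$planted$clean)$id)
  k2 <- which(vapply(res2$candidates, function(c)
    c$chrom == pl$chrom && c$start <= mid && c$end >= mid &&
      setequal(c$carriers, truth2), logical(1)))[1]
  s2 <- res2$risk_haplotypes[[k2]]$summary
  frac <- s2$n_discordant / s2$n_sites
  expect_lte(frac, 3 * 0.002 * (2 * 19))  # generous binomial envelope
})

test_that("haplotype-specific variants are private to the carrier set", {
  st <- small_study(seed = 75, error_rate = 0)
  res <- run_full(st)
  truth <- planted_carriers(st$truth, st$planted$clean)
  for (k in seq_along(res$candidates)) {
    hs <- res$hap_variants[[k]]
    if (!nrow(hs)) next
    noncarriers <- setdiff(st$wgs$samples, res$risk_haplotypes[[k]]$carriers$id)
    cols <- match(paste(hs$chrom, hs$pos),
                  paste(st$wgs$markers$chrom, st$wgs$markers$pos_bp))
    gn <- st$wgs$geno[match(noncarriers, st$wgs$samples), cols, drop = FALSE]
    expect_true(all(colSums(gn > 0, na.rm = TRUE) == 0))
  }
})
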