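test_that("simulated pedigree matches the study design", {
  cfg <- sim_config(seed = 1)
  ped <- simulate_pedigree(cfg)
  samples <- ped$ind$id[ped$ind$sampled]
  expect_length(samples, 19)
  # founders at generation 0; everyone else post-dates both parents
  expect_silent(founderscan:::validate_pedigree(ped))
  # every sampled individual descends from at least one labelled pair,
  # and the generated ancestry equals its recipe
  recipes <- attr(ped, "recipes")
  for (id in samples)
    expect_equal(founder_ancestry(ped, id), sort(recipes[[id]]))
  # at least three sampled individuals share a founder pair
  tab <- table(unlist(lapply(samples, function(id) founder_ancestry(ped, id))))
  expect_gte(max(tab), 3)
  # sampled individuals sit in the last two generations, far apart
  gen <- ped$ind$generation[ped$ind$sampled]
  expect_true(all(gen >= cfg$n_generations - 2))
  d <- vapply(combn(samples, 2, simplify = FALSE),
              function(p) meiotic_distance(ped, p[1], p[2]), numeric(1))
  expect_gte(min(d), cfg$min_meioses)
})

test_that("pedigree simulation is deterministic and rejects impossible sizes", {
  p1 <- simulate_pedigree(sim_config(seed = 5))
  p2 <- simulate_pedigree(sim_config(seed = 5))
  expect_identical(p1$ind, p2$ind)
  expect_error(simulate_pedigree(sim_config(n_generations = 1)),
               "n_generations")
})

test_that("17 of 19 sampled are affected under the default design", {
  st <- simulate_study(sim_config(seed = 1))
  samples <- st$pedigree$ind$id[st$pedigree$ind$sampled]
  expect_length(samples, 19)
  expect_equal(sum(is_affected(st$pedigree, samples)), 17)
})

test_that("gene drop in the no-crossover limit transmits parents verbatim", {
  ped <- sib_pedigree()
  # vanishing map length: crossover count is Poisson(~1e-8)
  cfg <- sim_config(chrom_lengths = c(`1` = 1e7), wgs_density = 50,
                    recomb_rate_cM_per_Mb = 1e-6, error_rate = 0, seed = 3)
  set.seed(3)
  mm <- sim_marker_map(cfg)
  fh <- sim_founder_haplotypes(ped, mm, cfg)
  gd <- gene_drop(ped, fh, mm, cfg)
  for (sib in c("s1", "s2")) {
    for (copy in 0:1) {
      hap <- gd$panel$haps[2 * match(sib, gd$panel$samples) - 1 + copy, ]
      parent <- if (copy == 0) "f" else "m"
      pf <- fh$haps[paste0(parent, ".0"), ]
      pm <- fh$haps[paste0(parent, ".1"), ]
      expect_true(identical(unname(hap), unname(pf)) ||
                    identical(unname(hap), unname(pm)))
      # the truth mosaic is a single full-chromosome interval
      mo <- gd$truth$mosaics[[sib]][[copy + 1]][["1"]]
      expect_equal(nrow(mo), 1)
      expect_equal(c(mo$start_bp, mo$end_bp), c(1, 1e7))
    }
  }
})

test_that("truth mosaics tile each chromosome without overlap", {
  st <- small_study(seed = 9, error_rate = 0)
  for (id in utils::head(st$panel$samples, 4)) {
    for (copy in 0:1) {
      mo <- st$truth$mosaics[[id]][[copy + 1]][["1"]]
      expect_equal(mo$start_bp[1], 1)
      expect_equal(mo$end_bp[nrow(mo)], unname(st$config$chrom_lengths["1"]))
      if (nrow(mo) > 1)
        expect_equal(mo$start_bp[-1], mo$end_bp[-nrow(mo)] + 1)
    }
  }
})

test_that("crossover count per meiosis is Poisson with the map length mean", {
  # one couple with many children on a 100 cM chromosome; crossovers are
  # observed as origin switches in the transmitted mosaics
  n_kids <- 1000
  ind <- data.frame(
    id = c("f", "m", sprintf("k%04d", seq_len(n_kids))),
    father = c(NA, NA, rep("f", n_kids)),
    mother = c(NA, NA, rep("m", n_kids)),
    sex = c("male", "female", rep("unknown", n_kids)),
    generation = c(0L, 0L, rep(1L, n_kids)),
    sampled = c(FALSE, FALSE, rep(TRUE, n_kids)))
  ped <- new_pedigree(ind, founder_pairs = list(A = c("f", "m")))
  cfg <- sim_config(chrom_lengths = c(`1` = 1e8), wgs_density = 20,
                    recomb_rate_cM_per_Mb = 1, error_rate = 0, seed = 21)
  set.seed(21)
  mm <- sim_marker_map(cfg)
  fh <- sim_founder_haplotypes(ped, mm, cfg)
  gd <- gene_drop(ped, fh, mm, cfg)
  switches <- unlist(lapply(gd$truth$mosaics, function(copies)
    vapply(copies, function(ch) nrow(ch[["1"]]) - 1L, integer(1))))
  expect_length(switches, 2 * n_kids)
  expect_lt(abs(mean(switches) - 1.0), 0.07)
})

test_that("planted haplotypes embed exclusive rare alleles", {
  st <- small_study(seed = 12)
  pl <- st$planted$clean
  expect_equal(pl$end_bp - pl$start_bp, 3.5e6)
  vi <- pl$variant_idx
  # the alt allele occurs only on transmitted copies of the planted founder
  carriers <- planted_carriers(st$truth, pl)
  for (i in seq_along(st$panel$samples)) {
    id <- st$panel$samples[i]
    for (copy in 0:1) {
      has_alt <- st$panel$haps[2 * i - 1 + copy, vi] == 1L
      is_carrier <- any(carriers$id == id & carriers$copy == copy)
      if (is_carrier) expect_true(all(has_alt))
      else expect_false(any(has_alt))
    }
  }
  expect_error(
    plant_risk_haplotype(
      list(haps = matrix(0L, 2, 2), ids = c("x.0", "x.1")),
      st$panel$markers,
      list(label = "B", founder_id = "x", copy = 0, chrom = "7",
           start_bp = 1, end_bp = 2e6,
           variants = data.frame(pos_bp = 1e6, id = "v"))),
    "outside the marker map")
})

test_that("penetrance/phenocopy model drives phenotypes", {
  st <- small_study(seed = 4)  # penetrance 1, phenocopy 0
  carriers <- unique(planted_carriers(st$truth, st$planted$clean)$id)
  samples <- st$pedigree$ind$id[st$pedigree$ind$sampled]
  expect_setequal(samples[is_affected(st$pedigree, samples)], carriers)
  # stochastic penetrance: carrier affected fraction approaches 0.8
  cfg <- sim_config(penetrance = 0.8, phenocopy = 0, match_design = FALSE,
                    seed = 1)
  ped <- simulate_pedigree(cfg)
  samples <- ped$ind$id[ped$ind$sampled]
  carriers <- samples[1:10]
  set.seed(99)
  frac <- replicate(200, {
    p2 <- assign_phenotypes(ped, carriers, cfg)
    mean(is_affected(p2, carriers))
  })
  expect_lt(abs(mean(frac) - 0.8), 0.08)
})

test_that("phenotype assignment is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 31)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$pedigree$diagnosis, st2$pedigree$diagnosis)
  expect_identical(st1$panel$haps, st2$panel$haps)
  expect_identical(st1$controls[[1]]$geno, st2$controls[[1]]$geno)
})

test_that("control cohorts match the two-cohort design and exclude planted alleles", {
  st <- simulate_study(sim_config(seed = 2))
  expect_equal(vapply(st$controls, function(p) length(p$samples), integer(1)),
               c(cohort1 = 49L, cohort2 = 42L))
  # planted embedded variants are absent from the array subset entirely
  vpos <- unlist(lapply(st$planted, `[[`, "variant_idx"))
  expect_false(any(vpos %in% st$array_idx))
  # zero-size cohort yields an empty panel
  empty <- make_controls(st$panel$markers, st$freqs, st$array_idx,
                         n_controls = 0L)
  expect_length(empty[[1]]$samples, 0)
  expect_error(make_controls(st$panel$markers, st$freqs, integer(0)),
               "empty")
})

test_that("fixture tables transcribe the published records", {
  fx <- load_fixture_tables()
  expect_equal(nrow(fx$haplotypes), 11)
  expect_equal(fx$variants$ncer[fx$variants$rsid == "rs562279749"], 97.26)
  h92 <- fx$haplotypes[fx$haplotypes$hap_id == "9.2", ]
  expect_setequal(h92$carrier_ids[[1]], c("7", "13", "8"))
  expect_setequal(fx$carriers$id[fx$carriers$`hap_9.2`], c("7", "13", "8"))
  expect_equal(nrow(fx$variants), 5)
  expect_equal(sum(fx$haplotypes$length_discrepant), 2)
})
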