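mk_cluster <- function(start, end, carriers, chrom = "1", haps = NULL) {
  if (is.null(haps)) haps <- rep(0L, length(carriers))
  list(chrom = chrom, start = start, end = end,
       members = data.frame(id = carriers, hap = haps),
       carriers = sort(unique(carriers)), support = integer(0))
}

test_that("length filter is strict at 1 Mb", {
  cls <- list(mk_cluster(1e6, 1.8e6, c("a", "b", "c")),      # 0.8 Mb
              mk_cluster(1e6, 4.53e6, c("a", "b", "c")),     # 3.53 Mb
              mk_cluster(1e6, 2e6, c("a", "b", "c")))        # exactly 1.0 Mb
  kept <- filter_by_length(cls)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$end, 4.53e6)
})

test_that("founder-pair filter counts shared ancestry and records ties", {
  ped <- carrier_matrix_pedigree()
  # carriers 7 (A/B), 13 (B), 8 (A/B/C): main FP B with count 3
  cl <- mk_cluster(1e6, 5e6, c("7", "13", "8"))
  out <- filter_by_founder_pair(list(cl), ped)
  expect_length(out, 1)
  expect_equal(out[[1]]$main_fp, "B")
  expect_equal(out[[1]]$main_fp_count, 3L)
  # disjoint ancestries: removed
  cl2 <- mk_cluster(1e6, 5e6, c("10", "15", "17"))  # B, C, E
  expect_length(filter_by_founder_pair(list(cl2)[1], ped), 0)
  # tie: carriers {A/B},{A/B},{A-only via 7? use 6,7,19 -> A:3 B:3 C:2 D:1}
  cl3 <- mk_cluster(1e6, 5e6, c("6", "7", "19"))
  out3 <- filter_by_founder_pair(list(cl3), ped)
  expect_equal(out3[[1]]$main_fp, c("A", "B"))
})

test_that("control screen flags genotype-consistent controls", {
  set.seed(61)
  m <- 60
  backbone <- rbinom(m, 1, 0.5)
  haps <- rbind(backbone, backbone, backbone,
                rbinom(m, 1, 0.5), rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  panel <- toy_panel(haps, pos = seq(50000, by = 50000, length.out = m))
  cl <- mk_cluster(1, 3.2e6, c("S01", "S02", "S03"), haps = c(0, 0, 0))
  # clean controls: random genotypes are inconsistent somewhere
  geno <- matrix(rbinom(40 * m, 2, 0.4), nrow = 40)
  controls <- list(c1 = genotype_panel(panel$markers, geno,
                                       sprintf("C%02d", 1:40)))
  res <- screen_controls(cl, panel, controls)
  expect_equal(res$status, "absent")
  # one control given the backbone on one chromosome copy
  geno2 <- geno
  geno2[5, ] <- backbone + rbinom(m, 1, 0.4)
  controls2 <- list(c1 = genotype_panel(panel$markers, geno2,
                                        sprintf("C%02d", 1:40)))
  res2 <- screen_controls(cl, panel, controls2)
  expect_equal(res2$status, "present_in")
  expect_equal(res2$panel, "c1")
  # too few shared markers is an error, not a silent pass
  tiny <- subset_panel(panel, markers = 1:5)
  controls3 <- list(c1 = genotype_panel(tiny$markers, geno[, 1:5, drop = FALSE],
                                        sprintf("C%02d", 1:40)))
  expect_error(screen_controls(cl, panel, controls3), "not evaluable")
})

test_that("phenotype filter applies the affected predicate to all carriers", {
  ped <- carrier_matrix_pedigree()
  ped$diagnosis[["8"]] <- "OCD"                       # OCD-only: control
  ped$diagnosis[["13"]] <- c("CMVT", "ADHD_probable") # CMVT counts as affected
  all_ts <- mk_cluster(1e6, 5e6, c("6", "7", "19"))
  one_ocd <- mk_cluster(1e6, 5e6, c("7", "13", "8"))
  cmvt <- mk_cluster(1e6, 5e6, c("7", "13", "12"))
  kept <- filter_by_phenotype(list(all_ts, one_ocd, cmvt), ped)
  expect_length(kept, 2)
  expect_false(any(vapply(kept, function(cl) "8" %in% cl$carriers, logical(1))))
  # the probable/confirmed distinction is controllable
  ped$diagnosis[["12"]] <- "TS_probable"
  expect_length(filter_by_phenotype(list(cmvt), ped, confirmed_only = TRUE), 0)
  expect_length(filter_by_phenotype(list(cmvt), ped), 1)
})

test_that("refinement extends identical members to the chromosome ends", {
  set.seed(62)
  hap <- rbinom(300, 1, 0.5)
  haps <- rbind(hap, hap, hap, rbinom(300, 1, 0.5), hap, rbinom(300, 1, 0.5))
  panel <- toy_panel(haps, pos = seq(10000, by = 10000, length.out = 300))
  cl <- mk_cluster(1e6, 2e6, c("S01", "S02", "S03"), haps = c(0, 0, 0))
  rb <- refine_boundaries(cl, panel)
  expect_equal(rb$start, panel$markers$pos_bp[1])
  expect_equal(rb$end, panel$markers$pos_bp[300])
})

test_that("a single flanking error stops strict refinement at that site", {
  set.seed(63)
  hap <- rbinom(300, 1, 0.5)
  h2 <- hap; h2[230] <- 1L - h2[230]   # one error right of the interval
  haps <- rbind(hap, hap, h2, rbinom(300, 1, 0.5),
                hap, rbinom(300, 1, 0.5))
  panel <- toy_panel(haps, pos = seq(10000, by = 10000, length.out = 300))
  cl <- mk_cluster(1.0e6, 2.0e6, c("S01", "S02", "S03"), haps = c(0, 0, 0))
  rb0 <- refine_boundaries(cl, panel, max_mismatches = 0L)
  expect_equal(rb0$end, panel$markers$pos_bp[229])
  expect_equal(rb0$start, panel$markers$pos_bp[1])
  # with one crossing allowed the error is passed
  rb1 <- refine_boundaries(cl, panel, max_mismatches = 1L)
  expect_equal(rb1$end, panel$markers$pos_bp[300])
})

test_that("spurious clusters abort refinement", {
  set.seed(64)
  haps <- matrix(rbinom(6 * 200, 1, 0.5), nrow = 6)
  panel <- toy_panel(haps, pos = seq(10000, by = 10000, length.out = 200))
  cl <- mk_cluster(2e5, 1.8e6, c("S01", "S02", "S03"), haps = c(0, 0, 0))
  expect_error(refine_boundaries(cl, panel), "spurious")
})

test_that("refined boundaries recover the planted truth on clean data", {
  st <- small_study(seed = 65, error_rate = 0)
  qc <- apply_qc(st$panel, st$pedigree, qc_thresholds())
  segs <- pairwise_ibd(qc$panel, ibd_params())
  cl <- multi_ibd_clusters(segs[segs$chrom == "1", ])
  truth <- planted_carriers(st$truth, st$planted$clean)
  shared <- attr(truth, "shared")
  mid <- mean(c(st$planted$clean$start_bp, st$planted$clean$end_bp))
  hit <- Filter(function(c) c$start <= mid && c$end >= mid, cl)[[1]]
  rb <- refine_boundaries(hit, qc$panel_preprune, max_mismatches = 0L)
  expect_lt(abs(rb$start - shared[1]), 1e5)
  expect_lt(abs(rb$end - shared[2]), 1e5)
  # refinement never shrinks below the supporting segment intersection
  expect_lte(rb$start, hit$start)
  expect_gte(rb$end, hit$end)
})

test_that("the cascade keeps a clean planted haplotype and traces telescopes", {
  st <- small_study(seed = 66, error_rate = 0.001)
  res <- run_full(st)
  tr <- res$trace
  expect_equal(tr$stage, c("length", "founder_pair", "controls",
                           "phenotype", "refine"))
  expect_equal(tr$n_in[-1], tr$n_out[-length(tr$n_out)])
  truth <- planted_carriers(st$truth, st$planted$clean)
  mid <- mean(c(st$planted$clean$start_bp, st$planted$clean$end_bp))
  hit <- Filter(function(c) c$start <= mid && c$end >= mid &&
                  setequal(c$carriers, unique(truth$id)), res$candidates)
  expect_gte(length(hit), 1)
})

test_that("a haplotype spiked into controls is removed at the control stage", {
  cfg <- sim_config(penetrance = 1, phenocopy = 0, match_design = FALSE,
                    seed = 67)
  st <- simulate_study(cfg, contaminate_controls = TRUE)
  res <- run_full(st)
  contam <- st$planted$contaminated
  on_contaminated_hap <- Filter(function(cl) {
    cl$chrom == contam$chrom &&
      any(member_origins(st$truth, cl) == contam$founder_hap, na.rm = TRUE)
  }, res$candidates)
  expect_length(on_contaminated_hap, 0)
  ctrl_row <- res$trace[res$trace$stage == "controls", ]
  expect_gt(ctrl_row$n_in, ctrl_row$n_out)
})
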