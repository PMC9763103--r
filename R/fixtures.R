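# Published-study fixtures: the risk-haplotype summary table, the
# prioritized-variant table and the carrier matrix, transcribed verbatim
# into inst/extdata (with ambiguities and length discrepancies flagged in a
# note column rather than silently resolved).

#' Load the published fixture tables
#'
#' Returns the three study tables: the eleven putative risk haplotypes
#' (coordinates, printed lengths, carriers, founder-pair sets, diagnoses),
#' the five prioritized variants with full annotations, and the
#' seventeen-affected-individuals carrier matrix for the four
#' variant-bearing haplotypes. Two haplotype rows whose printed length
#' disagrees with end - start are flagged (`length_discrepant`), and
#' founder-pair entries that conflict between tables carry a note.
#'
#' @return list with `haplotypes`, `variants` and `carriers` data.frames.
#'   Parsed list-columns: `haplotypes$carrier_ids`, `haplotypes$fp_list`
#'   (one character vector per carrier), `haplotypes$diagnosis_list`,
#'   `carriers$fp` (founder-pair set per individual).
#' @export
load_fixture_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "founderscan",
                                  mustWork = TRUE)
  t1 <- utils::read.table(path("risk_haplotypes.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character")
  t1$start_bp <- as.integer(t1$start_bp)
  t1$end_bp <- as.integer(t1$end_bp)
  t1$length_mb_printed <- as.numeric(t1$length_mb_printed)
  t1$length_discrepant <- as.logical(t1$length_discrepant)
  t1$n_main_fp <- as.integer(t1$n_main_fp)
  t1$carrier_ids <- strsplit(t1$carriers, ",", fixed = TRUE)
  t1$fp_list <- lapply(strsplit(t1$fp_sets, ";", fixed = TRUE),
                       strsplit, split = "/", fixed = TRUE)
  t1$diagnosis_list <- lapply(strsplit(t1$diagnoses, ";", fixed = TRUE),
                              strsplit, split = ",", fixed = TRUE)

  t2 <- utils::read.table(path("prioritized_variants.tsv"), sep = "\t",
                          header = TRUE, na.strings = "NA",
                          colClasses = "character")
  num <- c("pos", "af_AMR", "max_af", "sift_score", "polyphen_score",
           "cadd_phred", "pli", "mis_z", "ncer")
  for (cc in num) t2[[cc]] <- as.numeric(t2[[cc]])
  t2$id <- t2$rsid

  t3 <- utils::read.table(path("carrier_matrix.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character",
                          check.names = FALSE)
  for (cc in grep("^hap_", names(t3), value = TRUE))
    t3[[cc]] <- as.integer(t3[[cc]]) == 1L
  t3$fp <- strsplit(t3$fp_set, "/", fixed = TRUE)

  list(haplotypes = t1, variants = t2, carriers = t3)
}

#' Summaries of the carrier matrix
#'
#' Reproduces the headline counts over the carrier matrix: how many
#' affected individuals carry at least one variant-bearing haplotype, how
#' many of those share ancestry with a given founder pair, how many
#' individuals descend from that pair in total, and who carries multiple
#' haplotypes.
#'
#' @param carriers the `carriers` data.frame from [load_fixture_tables()]
#'   (or any frame with `id`, `fp` list-column and `hap_*` logical columns).
#' @param fp founder-pair label of interest.
#' @return list with `carrier_ids`, `n_carriers`, `n_carriers_with_fp`,
#'   `n_fp_descendants`, `multi_carrier_ids`.
#' @export
carrier_matrix_summary <- function(carriers, fp = "B") {
  hap_cols <- grep("^hap_", names(carriers), value = TRUE)
  hap <- as.matrix(carriers[hap_cols])
  n_haps <- rowSums(hap)
  is_carrier <- n_haps > 0
  has_fp <- vapply(carriers$fp, function(s) fp %in% s, logical(1))
  list(carrier_ids = carriers$id[is_carrier],
       n_carriers = sum(is_carrier),
       n_carriers_with_fp = sum(is_carrier & has_fp),
       n_fp_descendants = sum(has_fp),
       multi_carrier_ids = carriers$id[n_haps > 1])
}

#' Minimal pedigree consistent with the carrier matrix
#'
#' Deterministically constructs a pedigree whose sampled individuals are
#' the carrier-matrix ids and whose founder-pair ancestries equal the
#' matrix's founder-pair sets: each individual gets its own descent tree in
#' which single-pair ancestries are direct founder-couple children and
#' multi-pair ancestries merge two sub-trees. Intended for ancestry-logic
#' checks, not for transmission realism.
#'
#' @param carriers the `carriers` data.frame from [load_fixture_tables()].
#' @return An `fs_pedigree` with all matrix individuals sampled and
#'   diagnosed TS.
#' @export
carrier_matrix_pedigree <- function(carriers = load_fixture_tables()$carriers) {
  labs <- sort(unique(unlist(carriers$fp)))
  rows <- list()
  fp <- list()
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
  counter <- 0L
  make_anc <- function(S, prefix, sex) {
    if (length(S) == 1L) {
      counter <<- counter + 1L
      add(sprintf("%s_a%d", prefix, counter), fp[[S]][1], fp[[S]][2], sex, 1L)
    } else {
      half <- seq_len(ceiling(length(S) / 2))
      p1 <- make_anc(S[half], prefix, "male")
      p2 <- make_anc(S[-half], prefix, "female")
      counter <<- counter + 1L
      gen <- max(rows[[p1]]$generation, rows[[p2]]$generation) + 1L
      add(sprintf("%s_a%d", prefix, counter), p1, p2, sex, gen)
    }
  }
  dx <- list()
  for (i in seq_len(nrow(carriers))) {
    id <- carriers$id[i]
    anc <- make_anc(carriers$fp[[i]], paste0("t", id), "male")
    gen <- rows[[anc]]$generation
    rows[[anc]]$id <- id
    rows[[anc]]$sampled <- TRUE
    names(rows)[match(anc, names(rows))] <- id
    dx[[id]] <- "TS"
  }
  new_pedigree(do.call(rbind, rows), founder_pairs = fp, diagnosis = dx)
}

#' Recompute haplotype lengths from printed coordinates
#'
#' Length in Mb is (end - start) / 1e6 rounded to the printed precision
#' (two decimals); rows where this disagrees with the printed length are
#' returned flagged, matching the fixture's `length_discrepant` column.
#'
#' @param haplotypes the `haplotypes` data.frame from
#'   [load_fixture_tables()].
#' @return The input with `length_mb_computed` and `length_matches` columns.
#' @export
check_haplotype_lengths <- function(haplotypes = load_fixture_tables()$haplotypes) {
  haplotypes$length_mb_computed <-
    round((haplotypes$end_bp - haplotypes$start_bp) / 1e6, 2)
  haplotypes$length_matches <-
    haplotypes$length_mb_computed == haplotypes$length_mb_printed
  haplotypes
}
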