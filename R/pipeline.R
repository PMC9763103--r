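#' Pipeline parameters
#'
#' One object bundling every stage's parameters; each default equals the
#' published threshold where one exists (QC cut-offs, segment length > 1 Mb,
#' LOD > 3, >= 3 haplotype copies per cluster, rarity/CADD/ncER cut-offs).
#'
#' @param qc an [qc_thresholds()] object.
#' @param ibd an [ibd_params()] object.
#' @param min_copies,window_bp multi-IBD clustering parameters.
#' @param min_length_bp,min_same_fp,max_mismatch_frac,confirmed_only
#'   haplotype-cascade parameters (see [filter_cascade()]).
#' @param max_mismatches boundary refinement: cap on isolated per-member
#'   mismatches crossed per flank (the density rule in
#'   [refine_boundaries()] does the actual boundary detection; the cap
#'   guards against pathological inputs).
#' @param prioritize an [prioritize_thresholds()] object.
#' @return list of class `fs_pipeline_params`.
#' @export
pipeline_params <- function(qc = qc_thresholds(), ibd = ibd_params(),
                            min_copies = 3L, window_bp = 250000L,
                            min_length_bp = 1e6, min_same_fp = 3L,
                            max_mismatch_frac = 0, confirmed_only = FALSE,
                            max_mismatches = 20L,
                            prioritize = prioritize_thresholds()) {
  structure(list(qc = qc, ibd = ibd, min_copies = as.integer(min_copies),
                 window_bp = as.integer(window_bp),
                 min_length_bp = min_length_bp,
                 min_same_fp = as.integer(min_same_fp),
                 max_mismatch_frac = max_mismatch_frac,
                 confirmed_only = confirmed_only,
                 max_mismatches = as.integer(max_mismatches),
                 prioritize = prioritize),
            class = "fs_pipeline_params")
}

#' Run the full IBD risk-haplotype pipeline
#'
#' Executes QC, pairwise IBD detection, multi-IBD clustering, the haplotype
#' filter cascade, fine-mapping and variant prioritization on a study (an
#' `fs_study` from [simulate_study()] or a directory written by
#' [run_simulation()]). Emits the filter trace, a risk-haplotype table, a
#' prioritized-variant table, a carrier matrix, and one structured log line
#' per stage with in/out counts.
#'
#' @param study an `fs_study` or a directory path.
#' @param params an [pipeline_params()] object.
#' @param verbose print stage logs as they happen.
#' @return list of class `fs_result`; see Details.
#' @export
run_full <- function(study, params = pipeline_params(), verbose = FALSE) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "fs_study"))
  log <- list()
  say <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    if (verbose) message(line)
    log[[length(log) + 1L]] <<- line
  }

  if (nrow(study$panel$markers) == 0 || !length(study$panel$samples))
    stop("qc stage: empty phased panel")
  qc <- apply_qc(study$panel, study$pedigree, params$qc)
  say("qc", "markers %d -> %d, samples %d -> %d",
      qc$report$n_markers_in, qc$report$n_markers_out,
      qc$report$n_samples_in, qc$report$n_samples_out)

  segments <- pairwise_ibd(qc$panel, params$ibd)
  say("ibd", "%d segments (> %.1f Mb, LOD > %.1f)", nrow(segments),
      params$ibd$min_length_bp / 1e6, params$ibd$min_lod)

  clusters <- list()
  for (ch in unique(segments$chrom)) {
    clusters <- c(clusters,
                  multi_ibd_clusters(segments[segments$chrom == ch, ],
                                     min_copies = params$min_copies,
                                     window_bp = params$window_bp))
  }
  say("cluster", "%d multi-IBD clusters (>= %d copies)", length(clusters),
      params$min_copies)

  casc <- filter_cascade(clusters, study$pedigree, qc$panel,
                         qc$panel_preprune, study$controls,
                         min_length_bp = params$min_length_bp,
                         min_same_fp = params$min_same_fp,
                         max_mismatch_frac = params$max_mismatch_frac,
                         confirmed_only = params$confirmed_only,
                         max_mismatches = params$max_mismatches)
  for (k in seq_len(nrow(casc$trace)))
    say("filter", "%s: %d -> %d", casc$trace$stage[k],
        casc$trace$n_in[k], casc$trace$n_out[k])

  risk <- lapply(casc$candidates, fine_map, wgs = study$wgs,
                 panel = qc$panel_preprune)
  variants <- lapply(risk, haplotype_specific_variants, wgs = study$wgs)
  say("finemap", "%d risk haplotypes, %s haplotype-specific variants",
      length(risk), paste(vapply(variants, nrow, integer(1)), collapse = "/"))

  prio <- list()
  for (k in seq_along(risk)) {
    ids <- variants[[k]]$id
    prio[[k]] <- if (length(ids))
      prioritize_variants(ids, study$annotations, params$prioritize)
    else list(report = NULL, audit = NULL)
  }
  n_pass <- sum(vapply(prio, function(p)
    if (is.null(p$report)) 0L else nrow(p$report), integer(1)))
  say("prioritize", "%d deleterious haplotype-specific variant(s)", n_pass)

  res <- list(qc = qc$report, segments = segments, clusters = clusters,
              trace = casc$trace, candidates = casc$candidates,
              risk_haplotypes = risk, hap_variants = variants,
              prioritized = prio,
              risk_table = risk_table(casc$candidates, study$pedigree),
              variant_table = variant_table(casc$candidates, prio),
              carrier_matrix = carrier_matrix(casc$candidates, study$pedigree),
              log = unlist(log))
  class(res) <- "fs_result"
  res
}

#' @export
print.fs_result <- function(x, ...) {
  cat("<fs_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

# Table-1-shaped summary of surviving risk haplotypes
risk_table <- function(candidates, ped) {
  if (!length(candidates))
    return(data.frame(hap_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      length_mb = numeric(0), carriers = character(0),
                      fp_sets = character(0), main_fp = character(0),
                      n_main_fp = integer(0), diagnoses = character(0)))
  idx_by_chrom <- stats::ave(seq_along(candidates),
                             vapply(candidates, `[[`, character(1), "chrom"),
                             FUN = seq_along)
  do.call(rbind, lapply(seq_along(candidates), function(k) {
    cl <- candidates[[k]]
    dx <- vapply(cl$carriers, function(id)
      paste(ped$diagnosis[[id]], collapse = ","), character(1))
    data.frame(
      hap_id = sprintf("%s.%d", cl$chrom, idx_by_chrom[k]),
      chrom = cl$chrom, start_bp = cl$start, end_bp = cl$end,
      length_mb = round((cl$end - cl$start) / 1e6, 2),
      carriers = paste(cl$carriers, collapse = ","),
      fp_sets = paste(vapply(cl$fp_sets, paste, character(1), collapse = "/"),
                      collapse = ";"),
      main_fp = paste(cl$main_fp, collapse = "/"),
      n_main_fp = cl$main_fp_count,
      diagnoses = paste(dx, collapse = ";"))
  }))
}

# Table-2-shaped prioritized-variant report across haplotypes
variant_table <- function(candidates, prio) {
  out <- NULL
  for (k in seq_along(prio)) {
    rep_k <- prio[[k]]$report
    if (is.null(rep_k) || !nrow(rep_k)) next
    rep_k$hap_chrom <- candidates[[k]]$chrom
    rep_k$hap_start <- candidates[[k]]$start
    rep_k$hap_end <- candidates[[k]]$end
    out <- rbind(out, rep_k)
  }
  if (is.null(out)) data.frame() else out
}

# Table-3-shaped carrier matrix: affected sampled individuals x candidates
carrier_matrix <- function(candidates, ped) {
  samples <- ped$ind$id[ped$ind$sampled]
  aff <- samples[is_affected(ped, samples)]
  m <- data.frame(id = aff,
                  fp_set = vapply(aff, function(id)
                    paste(founder_ancestry(ped, id), collapse = "/"),
                    character(1)))
  for (k in seq_along(candidates))
    m[[sprintf("hap_%d", k)]] <- aff %in% candidates[[k]]$carriers
  m
}

#' Write a synthetic study to disk
#'
#' Generates a synthetic dataset with [simulate_study()] and writes it in
#' the pipeline's exchange formats: phased pedigree VCF, two unphased
#' control VCFs, FAM plus side-car TSV, transmission-truth JSON,
#' annotation TSV and the configuration as YAML, plus a checksum manifest.
#' Re-running with the same configuration reproduces the files.
#'
#' @param config an [sim_config()] object.
#' @param dir output directory (created if needed).
#' @param ... passed to [simulate_study()].
#' @return The manifest data.frame (file, md5), invisibly; attribute
#'   `"study"` holds the in-memory study.
#' @export
run_simulation <- function(config = sim_config(), dir, ...) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  study <- simulate_study(config, ...)
  p <- function(f) file.path(dir, f)
  write_phased_vcf(study$panel, p("pedigree_phased.vcf.gz"))
  write_genotype_vcf(study$controls[[1]], p("controls_cohort1.vcf.gz"))
  write_genotype_vcf(study$controls[[2]], p("controls_cohort2.vcf.gz"))
  write_pedigree(study$pedigree, p("pedigree.fam"), p("pedigree_meta.tsv"))
  truth <- list(
    samples = study$truth$samples, hap_ids = study$truth$hap_ids,
    # name the two copies so JSON keeps the nesting as objects
    mosaics = lapply(study$truth$mosaics, stats::setNames,
                     c("copy0", "copy1")),
    planted = lapply(study$planted, function(pl)
      pl[c("label", "founder_hap", "chrom", "start_bp", "end_bp")]),
    carriers = study$carriers, array_idx = study$array_idx,
    freqs = study$freqs)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(study$annotations, p("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- unclass(config)
  cfg_out$chrom_lengths <- as.list(cfg_out$chrom_lengths)  # keep names in YAML
  yaml::write_yaml(cfg_out, p("config.yaml"))
  files <- c("pedigree_phased.vcf.gz", "controls_cohort1.vcf.gz",
             "controls_cohort2.vcf.gz", "pedigree.fam", "pedigree_meta.tsv",
             "truth.json", "annotations.tsv", "config.yaml")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(manifest, "study") <- study
  invisible(manifest)
}

#' Read a study directory back into memory
#'
#' Counterpart of [run_simulation()]: all writers round-trip with these
#' readers. The transmission-truth mosaics are restored from JSON.
#'
#' @param dir directory written by [run_simulation()].
#' @return An `fs_study`.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- yaml::read_yaml(p("config.yaml"))
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), NULL)])
  panel <- read_phased_vcf(p("pedigree_phased.vcf.gz"))
  controls <- list(cohort1 = read_genotype_vcf(p("controls_cohort1.vcf.gz")),
                   cohort2 = read_genotype_vcf(p("controls_cohort2.vcf.gz")))
  ped <- read_pedigree(p("pedigree.fam"), p("pedigree_meta.tsv"))
  tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  mosaics <- lapply(tr$mosaics, function(copies)
    lapply(unname(copies), function(chroms) lapply(chroms, as.data.frame)))
  truth <- structure(list(mosaics = mosaics, samples = tr$samples,
                          hap_ids = tr$hap_ids), class = "fs_truth")
  planted <- lapply(tr$planted, function(pl) pl)
  anno <- utils::read.table(p("annotations.tsv"), sep = "\t", header = TRUE,
                            na.strings = "NA")
  anno$chrom <- as.character(anno$chrom)
  structure(list(pedigree = ped, panel = panel,
                 wgs = as_genotype_panel(panel), controls = controls,
                 truth = truth, planted = planted, carriers = tr$carriers,
                 annotations = anno, array_idx = tr$array_idx,
                 freqs = tr$freqs, config = config),
            class = "fs_study")
}
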