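# File-format plumbing: VCF (via vcfR), segment/cluster TSV+BED, truth JSON.
# Genetic-map positions travel in the INFO field (CM=<pos_cM>) so panels
# round-trip through VCF without a companion map file.

fs_vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##source=founderscan",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position (cM)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
}

fs_fix_matrix <- function(markers) {
  cbind(CHROM = markers$chrom,
        POS = as.character(markers$pos_bp),
        ID = markers$id,
        REF = markers$ref,
        ALT = markers$alt,
        QUAL = ".",
        FILTER = "PASS",
        INFO = sprintf("CM=%.6f", markers$pos_cM))
}

#' Write / read a phased panel as VCF
#'
#' Phased genotypes are written with the `|` separator (`"0|1"`); the genetic
#' map position is carried in the INFO field (`CM=`). `write.vcf` emits a
#' bgzip-style gzipped file, so paths conventionally end in `.vcf.gz`.
#'
#' @param panel an `fs_phased`.
#' @param path output file path.
#' @return `read_phased_vcf` returns an `fs_phased`.
#' @export
write_phased_vcf <- function(panel, path) {
  n <- length(panel$samples)
  a0 <- t(panel$haps[seq(1, 2 * n, 2), , drop = FALSE])
  a1 <- t(panel$haps[seq(2, 2 * n, 2), , drop = FALSE])
  gt <- matrix(paste0(ifelse(is.na(a0), ".", a0), "|",
                      ifelse(is.na(a1), ".", a1)),
               nrow = nrow(a0))
  gt[is.na(a0) & is.na(a1)] <- ".|."
  colnames(gt) <- panel$samples
  write_vcfR(panel$markers, gt, path)
  invisible(panel)
}

#' @rdname write_phased_vcf
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  m <- markers_from_vcfR(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("VCF contains unphased genotypes; phase the data or simulate phased")
  sp <- strsplit(as.vector(gt), "|", fixed = TRUE)
  a0 <- suppressWarnings(as.integer(vapply(sp, `[`, character(1), 1)))
  a1 <- suppressWarnings(as.integer(vapply(sp, `[`, character(1), 2)))
  haps <- matrix(NA_integer_, nrow = 2 * length(samples), ncol = nrow(m))
  for (j in seq_along(samples)) {
    idx <- (j - 1) * nrow(m) + seq_len(nrow(m))
    haps[2 * j - 1, ] <- a0[idx]
    haps[2 * j, ] <- a1[idx]
  }
  phased_panel(m, haps, samples)
}

#' Write / read a genotype panel as VCF
#'
#' Unphased dosages are encoded as `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param panel an `fs_geno`.
#' @param path output file path.
#' @return `read_genotype_vcf` returns an `fs_geno`.
#' @export
write_genotype_vcf <- function(panel, path) {
  codes <- c("0/0", "0/1", "1/1")
  g <- t(panel$geno)
  gt <- matrix(ifelse(is.na(g), "./.", codes[g + 1L]), nrow = nrow(g))
  colnames(gt) <- panel$samples
  write_vcfR(panel$markers, gt, path)
  invisible(panel)
}

#' @rdname write_genotype_vcf
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  m <- markers_from_vcfR(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  for (j in seq_len(ncol(gt))) dos[j, ] <- unname(lut[gt[, j]])
  genotype_panel(m, dos, colnames(gt))
}

write_vcfR <- function(markers, gt, path) {
  v <- methods::new(structure("vcfR", package = "vcfR"),
                    meta = fs_vcf_header(),
                    fix = fs_fix_matrix(markers),
                    gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

markers_from_vcfR <- function(v) {
  fix <- v@fix
  cm <- as.numeric(sub("^.*CM=([-0-9.eE+]+).*$", "\\1", fix[, "INFO"]))
  if (anyNA(cm)) cm <- as.numeric(fix[, "POS"]) / 1e6  # fall back: 1 cM/Mb
  marker_map(fix[, "CHROM"], as.integer(fix[, "POS"]), cm,
             fix[, "REF"], fix[, "ALT"], fix[, "ID"])
}

#' Write IBD segments as TSV or BED
#'
#' The TSV keeps the native 1-based inclusive coordinates with columns
#' `id_a, hap_a, id_b, hap_b, chrom, start, end, n_markers, lod`. The BED
#' writer converts to BED's 0-based half-open convention
#' (`start-1`, `end`).
#'
#' @param segments segment data.frame from [pairwise_ibd()].
#' @param path output path.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(segments)
}

#' @rdname write_segments_tsv
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,  # 1-based inclusive -> 0-based half-open
                    end = segments$end,
                    name = sprintf("%s.%d|%s.%d", segments$id_a, segments$hap_a,
                                   segments$id_b, segments$hap_b),
                    score = round(segments$lod, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(segments)
}

#' Write multi-IBD clusters as TSV
#'
#' One row per cluster: id, interval, copy count, comma-joined carriers and
#' IBD2 carriers.
#'
#' @param clusters list of clusters from [multi_ibd_clusters()].
#' @param path output path.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    ibd2 <- names(which(table(cl$members$id) == 2L))
    data.frame(cluster_id = i, chrom = cl$chrom, start = cl$start, end = cl$end,
               n_copies = nrow(cl$members),
               carriers = paste(sort(unique(cl$members$id)), collapse = ","),
               ibd2_carriers = if (length(ibd2)) paste(sort(ibd2), collapse = ",") else ".")
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
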