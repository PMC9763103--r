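# Fine-mapping: reconstruct the full allele sequence of a risk haplotype.
# The backbone comes from the phased marker data (member copies are mutually
# identical after refinement); remaining WGS sites are assigned from the
# genotype contrast between carriers (with their IBD copy numbers) and
# non-carriers, and sites that admit no consistent allele are reported as
# discordant rather than dropped.

#' Build the phased backbone of a risk haplotype
#'
#' For every phased marker inside the candidate interval, the allele carried
#' by the member haplotype copies is assigned. Member copies are expected to
#' be mutually identical after boundary refinement; a disagreeing marker
#' either raises an error (`on_disagreement = "error"`, the strict
#' contract) or is deferred to genotype-based assignment
#' (`on_disagreement = "defer"`, used by [fine_map()] because isolated
#' haplotype errors are expected at a nonzero error rate).
#'
#' @param cluster refined cluster (members and interval known).
#' @param panel full phased panel.
#' @param on_disagreement `"error"` or `"defer"`.
#' @return data.frame with `idx` (marker index into `panel$markers`) and
#'   `allele` (0/1; `NA` for deferred sites when `"defer"`).
#' @export
build_backbone <- function(cluster, panel,
                           on_disagreement = c("error", "defer")) {
  on_disagreement <- match.arg(on_disagreement)
  m <- panel$markers
  idx <- which(m$chrom == cluster$chrom & m$pos_bp >= cluster$start &
                 m$pos_bp <= cluster$end)
  rows <- 2L * match(cluster$members$id, panel$samples) - 1L + cluster$members$hap
  H <- panel$haps[rows, idx, drop = FALSE]
  ones <- colSums(H == 1L, na.rm = TRUE)
  zeros <- colSums(H == 0L, na.rm = TRUE)
  allele <- ifelse(ones > 0L & zeros == 0L, 1L,
                   ifelse(zeros > 0L & ones == 0L, 0L, NA_integer_))
  disagree <- ones > 0L & zeros > 0L
  if (any(disagree) && on_disagreement == "error")
    stop("member haplotypes disagree at ", sum(disagree),
         " backbone marker(s); refinement contract violated")
  data.frame(idx = idx, allele = allele)
}

#' Assign a haplotype allele at one site from genotype contrasts
#'
#' An allele x is *consistent* when every carrier's dosage of x is at least
#' its haplotype copy number (an IBD2 carrier must be homozygous for x);
#' carriers with missing genotypes are non-constraining. If exactly one
#' allele is consistent it is assigned. If both are consistent, the allele
#' absent from every non-carrier genotype is assigned when exactly one such
#' allele exists; otherwise the site is unassigned (uninformative). If no
#' allele is consistent the site is discordant (possible genotyping error)
#' and left unassigned with a reason code.
#'
#' @param carrier_dosage integer alt dosages of the carriers (`{0,1,2,NA}`).
#' @param carrier_copies copy number in `{1, 2}` per carrier.
#' @param noncarrier_dosage integer alt dosages of the non-carriers.
#' @return list with `allele` (0, 1 or `NA`) and `status` (one of
#'   `"assigned"`, `"unassigned"`, `"discordant"`).
#' @export
assign_allele <- function(carrier_dosage, carrier_copies, noncarrier_dosage) {
  if (length(carrier_dosage) != length(carrier_copies))
    stop("carrier dosage/copy-number length mismatch")
  if (any(!carrier_copies %in% c(1L, 2L)))
    stop("carrier copy numbers must be 1 or 2")
  ok <- !is.na(carrier_dosage)
  d <- carrier_dosage[ok]
  cc <- carrier_copies[ok]
  alt_ok <- all(d >= cc)            # dosage(alt) = d
  ref_ok <- all((2L - d) >= cc)     # dosage(ref) = 2 - d
  if (!alt_ok && !ref_ok)
    return(list(allele = NA_integer_, status = "discordant"))
  if (xor(alt_ok, ref_ok))
    return(list(allele = if (alt_ok) 1L else 0L, status = "assigned"))
  nc <- noncarrier_dosage[!is.na(noncarrier_dosage)]
  alt_absent <- all(nc == 0L)
  ref_absent <- all(nc == 2L)
  if (length(nc) && xor(alt_absent, ref_absent))
    return(list(allele = if (alt_absent) 1L else 0L, status = "assigned"))
  list(allele = NA_integer_, status = "unassigned")
}

#' Fine-map a risk haplotype
#'
#' Backbone first (phased markers in the interval), then genotype-based
#' assignment via [assign_allele()] for every remaining WGS site in the
#' interval. Carrier copy numbers are taken from the cluster membership
#' (IBD2 carriers contribute both copies). Reports assigned / unassigned /
#' discordant counts and the backbone fraction.
#'
#' @param cluster refined cluster.
#' @param wgs an `fs_geno` panel over all WGS sites (pedigree samples).
#' @param panel full phased panel (backbone source).
#' @return list of class `fs_risk_haplotype`: `cluster`, `allele_map`
#'   (data.frame `chrom, pos, ref, alt, allele, source` with source in
#'   backbone/genotype/unassigned/discordant), `carriers` (data.frame
#'   `id, copies`), and `summary` counts.
#' @export
fine_map <- function(cluster, wgs, panel) {
  m <- wgs$markers
  idx <- which(m$chrom == cluster$chrom & m$pos_bp >= cluster$start &
                 m$pos_bp <= cluster$end)
  if (!length(idx)) stop("candidate interval contains no WGS sites")
  bb <- build_backbone(cluster, panel, on_disagreement = "defer")
  bb_pos <- panel$markers$pos_bp[bb$idx]
  bb_allele <- stats::setNames(bb$allele, bb_pos)

  carriers <- data.frame(id = unique(cluster$members$id))
  carriers$copies <- vapply(carriers$id, function(id)
    sum(cluster$members$id == id), integer(1))
  noncarriers <- setdiff(wgs$samples, carriers$id)
  gc <- wgs$geno[match(carriers$id, wgs$samples), idx, drop = FALSE]
  gn <- wgs$geno[match(noncarriers, wgs$samples), idx, drop = FALSE]

  allele <- rep(NA_integer_, length(idx))
  source <- rep("unassigned", length(idx))
  pos <- m$pos_bp[idx]
  from_bb <- match(pos, bb_pos)
  has_bb <- !is.na(from_bb) & !is.na(bb_allele[from_bb])
  allele[has_bb] <- bb_allele[from_bb[has_bb]]
  source[has_bb] <- "backbone"
  for (k in which(!has_bb)) {
    res <- assign_allele(gc[, k], carriers$copies, gn[, k])
    allele[k] <- res$allele
    source[k] <- if (res$status == "assigned") "genotype" else res$status
  }
  amap <- data.frame(chrom = cluster$chrom, pos = pos,
                     ref = m$ref[idx], alt = m$alt[idx], id = m$id[idx],
                     allele = allele, source = source)
  counts <- table(factor(source, levels = c("backbone", "genotype",
                                            "unassigned", "discordant")))
  structure(list(cluster = cluster, allele_map = amap, carriers = carriers,
                 summary = list(n_sites = length(idx),
                                n_backbone = unname(counts["backbone"]),
                                n_genotype = unname(counts["genotype"]),
                                n_unassigned = unname(counts["unassigned"]),
                                n_discordant = unname(counts["discordant"]),
                                backbone_fraction =
                                  unname(counts["backbone"]) / length(idx))),
            class = "fs_risk_haplotype")
}

#' @export
print.fs_risk_haplotype <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fs_risk_haplotype> %s:%d-%d | %d carriers | %d sites (%d backbone, %d genotype, %d unassigned, %d discordant)\n",
    x$cluster$chrom, x$cluster$start, x$cluster$end, nrow(x$carriers),
    s$n_sites, s$n_backbone, s$n_genotype, s$n_unassigned, s$n_discordant))
  invisible(x)
}

#' Haplotype-specific variants
#'
#' Variants on the fine-mapped haplotype whose assigned allele is the
#' alternate allele and whose alternate allele has dosage 0 in every
#' sampled pedigree individual outside the carrier set.
#'
#' @param rh an `fs_risk_haplotype` from [fine_map()].
#' @param wgs the `fs_geno` pedigree panel.
#' @return Subset of the allele map (assigned alt sites private to the
#'   carriers).
#' @export
haplotype_specific_variants <- function(rh, wgs) {
  amap <- rh$allele_map
  cand <- which(!is.na(amap$allele) & amap$allele == 1L)
  if (!length(cand)) return(amap[integer(0), ])
  noncarriers <- setdiff(wgs$samples, rh$carriers$id)
  col <- match(paste(amap$chrom[cand], amap$pos[cand]),
               paste(wgs$markers$chrom, wgs$markers$pos_bp))
  gn <- wgs$geno[match(noncarriers, wgs$samples), col, drop = FALSE]
  private <- colSums(gn > 0L, na.rm = TRUE) == 0L
  amap[cand[private], ]
}
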