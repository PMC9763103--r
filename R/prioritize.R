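#' Variant prioritization thresholds
#'
#' Rarity and deleteriousness cut-offs for the haplotype-specific variant
#' filter: common variants (reference-population MAF > 0.01) are excluded,
#' coding variants require a protein-impact consequence plus SIFT
#' deleterious, PolyPhen damaging and CADD phred > 20, non-coding variants
#' require CADD > 10 and an ncER percentile > 95. All inequalities are
#' strict.
#'
#' @param rare_max_af,ultra_rare_max_af rarity class boundaries.
#' @param coding_min_cadd,noncoding_min_cadd CADD phred thresholds.
#' @param min_ncer ncER percentile threshold.
#' @param reference_population population whose AF drives rarity.
#' @param strict_polyphen accept only "probably damaging" (the narrower
#'   reading); default also accepts "possibly damaging", which matches the
#'   published pass set.
#' @param cadd_or_predictors for coding variants, accept CADD *or* the
#'   SIFT/PolyPhen predictors instead of requiring all (conjunction is the
#'   default).
#' @return list of class `fs_prioritize_thresholds`.
#' @export
prioritize_thresholds <- function(rare_max_af = 0.01,
                                  ultra_rare_max_af = 0.001,
                                  coding_min_cadd = 20,
                                  noncoding_min_cadd = 10,
                                  min_ncer = 95,
                                  reference_population = "AMR",
                                  strict_polyphen = FALSE,
                                  cadd_or_predictors = FALSE) {
  if (ultra_rare_max_af > rare_max_af)
    stop("ultra_rare_max_af must not exceed rare_max_af")
  if (any(c(coding_min_cadd, noncoding_min_cadd, min_ncer) < 0))
    stop("thresholds must be >= 0")
  structure(list(rare_max_af = rare_max_af,
                 ultra_rare_max_af = ultra_rare_max_af,
                 coding_min_cadd = coding_min_cadd,
                 noncoding_min_cadd = noncoding_min_cadd,
                 min_ncer = min_ncer,
                 reference_population = reference_population,
                 strict_polyphen = isTRUE(strict_polyphen),
                 cadd_or_predictors = isTRUE(cadd_or_predictors)),
            class = "fs_prioritize_thresholds")
}

coding_consequences <- function() c("missense", "frameshift", "nonsense", "splice_site")

#' Rarity classification
#'
#' Ultra-rare below 0.001, rare in \[0.001, 0.01), common otherwise
#' (boundaries excluded from the rarer class). A missing AF is treated as
#' the rarest class - absence from the reference database - with a warning
#' flag in the attribute `"af_missing"`.
#'
#' @param af allele frequency in the reference population (vectorised).
#' @param thresholds an [prioritize_thresholds()] object.
#' @return Character vector in `{"ultra_rare", "rare", "common"}`.
#' @export
classify_rarity <- function(af, thresholds = prioritize_thresholds()) {
  out <- ifelse(is.na(af), "ultra_rare",
                ifelse(af < thresholds$ultra_rare_max_af, "ultra_rare",
                       ifelse(af < thresholds$rare_max_af, "rare", "common")))
  attr(out, "af_missing") <- is.na(af)
  out
}

#' Coding deleteriousness filter
#'
#' Pass requires a protein-impact consequence (frameshift, nonsense,
#' splice-site or missense), SIFT deleterious (including low-confidence
#' deleterious), PolyPhen probably or possibly damaging, and CADD phred
#' above the coding threshold. Missing sub-annotations fail with a reason.
#'
#' @param anno one annotation row (list or 1-row data.frame) with fields
#'   `consequence`, `sift_pred`, `polyphen_pred`, `cadd_phred`.
#' @param thresholds an [prioritize_thresholds()] object.
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
coding_filter <- function(anno, thresholds = prioritize_thresholds()) {
  reasons <- character(0)
  if (!isTRUE(anno$consequence %in% coding_consequences()))
    reasons <- c(reasons, "consequence")
  sift_ok <- isTRUE(anno$sift_pred %in%
                      c("deleterious", "deleterious_low_confidence"))
  pp_accept <- if (thresholds$strict_polyphen) "probably_damaging" else
    c("probably_damaging", "possibly_damaging")
  pp_ok <- isTRUE(anno$polyphen_pred %in% pp_accept)
  cadd_ok <- isTRUE(!is.na(anno$cadd_phred) &&
                      anno$cadd_phred > thresholds$coding_min_cadd)
  if (thresholds$cadd_or_predictors) {
    if (!(cadd_ok || (sift_ok && pp_ok)))
      reasons <- c(reasons, "cadd_or_predictors")
  } else {
    if (!sift_ok) reasons <- c(reasons, "sift")
    if (!pp_ok) reasons <- c(reasons, "polyphen")
    if (!cadd_ok) reasons <- c(reasons, "cadd")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Non-coding deleteriousness filter
#'
#' Pass requires a non-coding consequence, CADD phred above the non-coding
#' threshold and an ncER percentile above the ncER threshold. A missing
#' ncER (unstable assembly conversion) fails with reason "unliftable".
#'
#' @inheritParams coding_filter
#' @return list with `pass` and `reasons`.
#' @export
noncoding_filter <- function(anno, thresholds = prioritize_thresholds()) {
  reasons <- character(0)
  if (isTRUE(anno$consequence %in% coding_consequences()))
    reasons <- c(reasons, "consequence")
  if (!isTRUE(!is.na(anno$cadd_phred) &&
                anno$cadd_phred > thresholds$noncoding_min_cadd))
    reasons <- c(reasons, "cadd")
  if (is.null(anno$ncer) || is.na(anno$ncer))
    reasons <- c(reasons, "unliftable")
  else if (!(anno$ncer > thresholds$min_ncer))
    reasons <- c(reasons, "ncer")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Highest population allele frequency
#'
#' Returns the population with the maximal AF among the per-population map;
#' ties go to the lexicographically first population, with all tied
#' populations reported.
#'
#' @param af_by_population named numeric vector of allele frequencies.
#' @return list with `population`, `af` and `tied` (all argmax populations).
#' @export
max_population_af <- function(af_by_population) {
  af <- af_by_population[!is.na(af_by_population)]
  if (!length(af)) stop("af_by_population is empty")
  mx <- max(af)
  tied <- sort(names(af)[af == mx])
  list(population = tied[1], af = unname(mx), tied = tied)
}

#' Prioritize haplotype-specific variants
#'
#' Drops common variants, routes protein-impact consequences through the
#' coding branch and everything else through the non-coding branch, and
#' returns one report row per passing variant (rarity class, branch, all
#' scores, maximal population AF) plus a full audit of failures with
#' reasons. Every variant is routed to exactly one branch.
#'
#' @param variant_ids character ids of haplotype-specific variants.
#' @param annotations annotation data.frame (one row per variant id; columns
#'   `id`, `af_<POP>` columns, `consequence`, `gene`, `aa_sub`, `sift_pred`,
#'   `sift_score`, `polyphen_pred`, `polyphen_score`, `cadd_phred`, `ncer`).
#' @param thresholds an [prioritize_thresholds()] object.
#' @return list with `report` (passing rows) and `audit` (all rows with
#'   `pass`, `branch`, `rarity`, `reasons`).
#' @export
prioritize_variants <- function(variant_ids, annotations,
                                thresholds = prioritize_thresholds()) {
  rows <- match(variant_ids, annotations$id)
  if (anyNA(rows))
    stop("unannotated variant(s): ",
         paste(variant_ids[is.na(rows)], collapse = ", "))
  ann <- annotations[rows, , drop = FALSE]
  af_cols <- grep("^af_", names(ann), value = TRUE)
  ref_col <- paste0("af_", thresholds$reference_population)
  if (!ref_col %in% af_cols)
    stop("annotations lack the reference population column ", ref_col)
  audit <- NULL
  for (k in seq_len(nrow(ann))) {
    a <- as.list(ann[k, ])
    rarity <- classify_rarity(a[[ref_col]], thresholds)
    if (rarity == "common") {
      branch <- "none"; pass <- FALSE; reasons <- "common"
    } else if (a$consequence %in% coding_consequences()) {
      branch <- "coding"
      res <- coding_filter(a, thresholds)
      pass <- res$pass; reasons <- res$reasons
    } else {
      branch <- "noncoding"
      res <- noncoding_filter(a, thresholds)
      pass <- res$pass; reasons <- res$reasons
    }
    afs <- unlist(a[af_cols])
    names(afs) <- sub("^af_", "", af_cols)
    mx <- max_population_af(afs)
    audit <- rbind(audit, data.frame(
      id = a$id, rarity = as.character(rarity), branch = branch, pass = pass,
      reasons = paste(reasons, collapse = ","),
      gene = if (is.null(a$gene)) NA_character_ else a$gene,
      consequence = a$consequence,
      af_ref = a[[ref_col]], max_af = mx$af, max_af_pop = mx$population,
      sift_pred = a$sift_pred, polyphen_pred = a$polyphen_pred,
      cadd_phred = a$cadd_phred, ncer = a$ncer))
  }
  list(report = audit[audit$pass, , drop = FALSE], audit = audit)
}
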