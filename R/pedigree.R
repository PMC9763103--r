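#' Construct a pedigree
#'
#' A pedigree is a directed ancestry graph over individuals, together with the
#' labelled founder pairs (couples with no recorded ancestors) from which the
#' study descends. Founders (both parents unknown) sit at generation 0; every
#' non-founder's generation exceeds both parents' generations.
#'
#' @param individuals data.frame with columns `id`, `father`, `mother`
#'   (character; `NA` for unknown), `sex` (`"male"`, `"female"` or
#'   `"unknown"`), `generation` (integer >= 0) and `sampled` (logical: has
#'   genotype data).
#' @param founder_pairs named list mapping a pair label (e.g. `"A"`..`"F"`) to
#'   a character vector `c(father_id, mother_id)`.
#' @param diagnosis named list mapping individual id to a character vector of
#'   diagnosis labels (subset of [diagnosis_levels()]); individuals absent
#'   from the list are taken as undiagnosed/unaffected.
#' @return An object of class `fs_pedigree`.
#' @export
new_pedigree <- function(individuals, founder_pairs = list(), diagnosis = list()) {
  stopifnot(is.data.frame(individuals))
  req <- c("id", "father", "mother", "sex", "generation", "sampled")
  missing_cols <- setdiff(req, names(individuals))
  if (length(missing_cols))
    stop("pedigree individuals lack columns: ", paste(missing_cols, collapse = ", "))
  ind <- individuals[, req]
  ind$id <- as.character(ind$id)
  ind$father <- as.character(ind$father)
  ind$mother <- as.character(ind$mother)
  if (anyDuplicated(ind$id))
    stop("duplicated individual ids in pedigree")
  rownames(ind) <- ind$id
  ped <- structure(
    list(ind = ind, founder_pairs = founder_pairs, diagnosis = diagnosis),
    class = "fs_pedigree"
  )
  validate_pedigree(ped)
  ped
}

#' @export
print.fs_pedigree <- function(x, ...) {
  cat(sprintf(
    "<fs_pedigree> %d individuals (%d sampled), %d generations, %d founder pairs\n",
    nrow(x$ind), sum(x$ind$sampled), max(x$ind$generation) + 1L,
    length(x$founder_pairs)))
  invisible(x)
}

validate_pedigree <- function(ped) {
  ind <- ped$ind
  parents <- c(ind$father, ind$mother)
  parents <- parents[!is.na(parents)]
  unknown <- setdiff(parents, ind$id)
  if (length(unknown))
    stop("pedigree references unknown parent id(s): ",
         paste(unique(unknown), collapse = ", "))
  is_founder <- is.na(ind$father) & is.na(ind$mother)
  if (any(ind$generation[is_founder] != 0))
    stop("founders must have generation 0")
  nf <- which(!is_founder)
  for (i in nf) {
    g <- ind$generation[i]
    for (p in c(ind$father[i], ind$mother[i])) {
      if (!is.na(p) && g <= ind[p, "generation"])
        stop("individual ", ind$id[i], " does not post-date parent ", p)
    }
  }
  for (lab in names(ped$founder_pairs)) {
    fp <- ped$founder_pairs[[lab]]
    if (length(fp) != 2 || !all(fp %in% ind$id))
      stop("founder pair ", lab, " must name two pedigree members")
    if (!all(is_founder[match(fp, ind$id)]))
      stop("founder pair ", lab, " contains a non-founder")
  }
  # generation ordering above guarantees acyclicity
  invisible(ped)
}

ped_check_ids <- function(ped, ids) {
  bad <- setdiff(ids, ped$ind$id)
  if (length(bad))
    stop("unknown individual id(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' All ancestors of an individual
#'
#' Breadth-first walk up the ancestry graph; the individual itself is included.
#'
#' @param ped an `fs_pedigree`.
#' @param id individual id.
#' @return Character vector of ids (self plus all ancestors).
#' @export
ancestors <- function(ped, id) {
  ped_check_ids(ped, id)
  ind <- ped$ind
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    pp <- c(ind[frontier, "father"], ind[frontier, "mother"])
    frontier <- setdiff(unique(pp[!is.na(pp)]), seen)
  }
  seen
}

#' Founder-pair ancestry of an individual
#'
#' Returns the labels of the founder pairs from which an individual descends,
#' i.e. the pairs with at least one member reachable by walking up the
#' ancestry graph. A founder belonging to pair X has ancestry `{X}`.
#'
#' @inheritParams ancestors
#' @return Character vector of founder-pair labels (sorted).
#' @export
founder_ancestry <- function(ped, id) {
  anc <- ancestors(ped, id)
  labs <- names(ped$founder_pairs)
  hit <- vapply(labs, function(l) any(ped$founder_pairs[[l]] %in% anc), logical(1))
  sort(labs[hit])
}

#' Meiotic distance between two individuals
#'
#' Minimum, over common ancestors, of the number of meioses from each
#' individual up to that ancestor. Parent-child pairs are at distance 1, full
#' siblings at 2. `Inf` when the pair has no common ancestor.
#'
#' @inheritParams ancestors
#' @param id1,id2 individual ids.
#' @return Non-negative number of meiotic steps (possibly `Inf`).
#' @export
meiotic_distance <- function(ped, id1, id2) {
  ped_check_ids(ped, c(id1, id2))
  d1 <- ancestor_depths(ped, id1)
  d2 <- ancestor_depths(ped, id2)
  common <- intersect(names(d1), names(d2))
  if (!length(common)) return(Inf)
  min(d1[common] + d2[common])
}

# named vector: ancestor id -> minimum number of meioses up from `id`
ancestor_depths <- function(ped, id) {
  ind <- ped$ind
  depth <- stats::setNames(0L, id)
  frontier <- id
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    pp <- unique(c(ind[frontier, "father"], ind[frontier, "mother"]))
    pp <- setdiff(pp[!is.na(pp)], names(depth))
    if (length(pp)) depth[pp] <- d
    frontier <- pp
  }
  depth
}

#' Diagnosis vocabulary
#'
#' Tic-spectrum and co-morbid labels used in the carrier tables. `TS` is
#' Tourette syndrome, `CMVT` chronic motor-or-vocal tic disorder; `_probable`
#' suffixes mark probable diagnoses.
#'
#' @return Character vector of recognised diagnosis labels.
#' @export
diagnosis_levels <- function() {
  c("TS", "TS_probable", "CMVT", "CMVT_probable", "OCD", "OCD_probable",
    "ADHD", "ADHD_probable", "unaffected")
}

#' Affected predicate
#'
#' Affected status is defined as a confirmed or probable tic-spectrum
#' diagnosis (TS or CMVT); OCD-only or ADHD-only individuals count as
#' controls.
#'
#' @inheritParams ancestors
#' @param id individual id (vectorised).
#' @return Logical vector.
#' @export
is_affected <- function(ped, id) {
  ped_check_ids(ped, id)
  aff <- c("TS", "TS_probable", "CMVT", "CMVT_probable")
  vapply(id, function(i) {
    dx <- ped$diagnosis[[i]]
    !is.null(dx) && length(intersect(dx, aff)) > 0
  }, logical(1))
}

#' Read / write a pedigree as FAM plus side-car TSV
#'
#' The FAM dialect is the 6-column PLINK layout (family, id, father, mother,
#' sex, phenotype; `0` encodes unknown). Founder-pair labels, generations,
#' sampling flags and diagnosis sets do not fit in FAM and travel in a
#' side-car TSV with columns `id`, `generation`, `sampled`, `founder_pair`
#' (label if the individual is a member of a founder pair with role suffix
#' `:father`/`:mother`, else `.`) and `diagnosis` (comma-joined labels or
#' `.`).
#'
#' @param ped an `fs_pedigree`.
#' @param fam path to the FAM file.
#' @param sidecar path to the side-car TSV.
#' @param family family id written to column 1.
#' @return `write_pedigree` returns the input invisibly; `read_pedigree`
#'   returns an `fs_pedigree`.
#' @export
write_pedigree <- function(ped, fam, sidecar, family = "FAM1") {
  ind <- ped$ind
  sex_code <- c(male = 1L, female = 2L, unknown = 0L)[ind$sex]
  phe <- ifelse(is_affected(ped, ind$id), 2L, 1L)
  fam_df <- data.frame(family, ind$id,
                       ifelse(is.na(ind$father), "0", ind$father),
                       ifelse(is.na(ind$mother), "0", ind$mother),
                       sex_code, phe)
  utils::write.table(fam_df, fam, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fp <- rep(".", nrow(ind))
  for (lab in names(ped$founder_pairs)) {
    pair <- ped$founder_pairs[[lab]]
    fp[match(pair[1], ind$id)] <- paste0(lab, ":father")
    fp[match(pair[2], ind$id)] <- paste0(lab, ":mother")
  }
  dx <- vapply(ind$id, function(i) {
    d <- ped$diagnosis[[i]]
    if (is.null(d) || !length(d)) "." else paste(d, collapse = ",")
  }, character(1))
  sc <- data.frame(id = ind$id, generation = ind$generation,
                   sampled = ind$sampled, founder_pair = fp, diagnosis = dx)
  utils::write.table(sc, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ped)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(fam, sidecar) {
  f <- utils::read.table(fam, sep = "\t", header = FALSE,
                         colClasses = "character")
  names(f) <- c("family", "id", "father", "mother", "sex", "phenotype")
  sc <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                          colClasses = c(id = "character"))
  sc <- sc[match(f$id, sc$id), ]
  sex <- c(`1` = "male", `2` = "female", `0` = "unknown")[f$sex]
  ind <- data.frame(
    id = f$id,
    father = ifelse(f$father == "0", NA_character_, f$father),
    mother = ifelse(f$mother == "0", NA_character_, f$mother),
    sex = unname(sex),
    generation = as.integer(sc$generation),
    sampled = as.logical(sc$sampled)
  )
  fp <- list()
  has_fp <- sc$founder_pair != "."
  for (i in which(has_fp)) {
    parts <- strsplit(sc$founder_pair[i], ":", fixed = TRUE)[[1]]
    lab <- parts[1]; role <- parts[2]
    if (is.null(fp[[lab]])) fp[[lab]] <- c(father = NA_character_, mother = NA_character_)
    fp[[lab]][[role]] <- sc$id[i]
  }
  fp <- lapply(fp, unname)
  dx <- list()
  for (i in seq_len(nrow(sc))) {
    if (sc$diagnosis[i] != ".")
      dx[[sc$id[i]]] <- strsplit(sc$diagnosis[i], ",", fixed = TRUE)[[1]]
  }
  new_pedigree(ind, founder_pairs = fp, diagnosis = dx)
}
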