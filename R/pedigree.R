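#' Read a pedigree file
#'
#' Tab-separated columns `id`, `sire`, `dam` and optionally `sex`; `0`, `NA`
#' or an empty field denotes an unknown parent. Every named parent must
#' itself be listed, and no sample may be its own ancestor.
#'
#' @param path path to the pedigree TSV (with header).
#' @return an object of class `pedigree`: data.frame with columns `id`,
#'   `sire`, `dam` (NA = unknown), `sex` (possibly NA).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    la_stop("pedigree file must have columns id, sire, dam",
            "liftann_pedigree_error")
  }
  clean <- function(x) ifelse(is.na(x) | x %in% c("0", "", "NA"), NA, x)
  ped <- data.frame(id = df$id, sire = clean(df$sire), dam = clean(df$dam),
                    sex = if ("sex" %in% names(df)) df$sex else NA_character_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) {
    la_stop(sprintf("duplicate pedigree id '%s'",
                    ped$id[duplicated(ped$id)][1]), "liftann_pedigree_error")
  }
  parents <- stats::na.omit(c(ped$sire, ped$dam))
  missing <- setdiff(parents, ped$id)
  if (length(missing)) {
    la_stop(sprintf("pedigree references unknown parent '%s'", missing[1]),
            "liftann_pedigree_error")
  }
  # cycle check: walk ancestors of every sample
  parent_of <- function(id) stats::na.omit(
    c(ped$sire[ped$id == id], ped$dam[ped$id == id]))
  for (s in ped$id) {
    seen <- character(); frontier <- parent_of(s)
    while (length(frontier)) {
      if (s %in% frontier) {
        la_stop(sprintf("pedigree cycle involving '%s'", s),
                "liftann_pedigree_error")
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Mendelian-consistency check of a cohort against a pedigree
#'
#' For every variant and every offspring with at least one genotyped parent,
#' tests biparental transmission: a fully-called trio is consistent iff the
#' child's two alleles can be partitioned so that one is carried by the sire
#' and the other by the dam; with a single genotyped parent (duo) the call is
#' consistent iff the child shares at least one allele with that parent or
#' the child is heterozygous. Any missing genotype in a trio/duo skips that
#' family for that variant. Only autosomal biallelic records should be
#' supplied; the check itself is genotype-only.
#'
#' @param vt a [variant_table] with genotypes.
#' @param ped a `pedigree` from [read_pedigree()].
#' @param max_violation_rate mark variants whose violation rate (violations /
#'   families checked) exceeds this threshold (default 0: any violation
#'   marks; nothing is removed).
#' @return list with `per_variant` (data.frame: `n_checked`, `n_violations`,
#'   `rate`, `flagged`) and `families` (data.frame describing the trios/duos
#'   used: child, sire, dam).
#' @export
mendel_check <- function(vt, ped, max_violation_rate = 0) {
  fams <- ped[!is.na(ped$sire) | !is.na(ped$dam), c("id", "sire", "dam")]
  names(fams)[1] <- "child"
  n <- n_variants(vt)
  nv <- integer(n); nc <- integer(n)
  idx <- function(id) match(id, vt$samples)
  for (f in seq_len(nrow(fams))) {
    ci <- idx(fams$child[f])
    pi1 <- if (!is.na(fams$sire[f])) idx(fams$sire[f]) else NA_integer_
    pi2 <- if (!is.na(fams$dam[f])) idx(fams$dam[f]) else NA_integer_
    if (is.na(ci)) next
    c1 <- vt$gt1[, ci]; c2 <- vt$gt2[, ci]
    child_ok <- !is.na(c1) & !is.na(c2)
    s1 <- if (!is.na(pi1)) vt$gt1[, pi1] else rep(NA_integer_, n)
    s2 <- if (!is.na(pi1)) vt$gt2[, pi1] else rep(NA_integer_, n)
    d1 <- if (!is.na(pi2)) vt$gt1[, pi2] else rep(NA_integer_, n)
    d2 <- if (!is.na(pi2)) vt$gt2[, pi2] else rep(NA_integer_, n)
    sire_ok <- !is.na(s1) & !is.na(s2)
    dam_ok <- !is.na(d1) & !is.na(d2)
    trio <- child_ok & sire_ok & dam_ok
    duo_s <- child_ok & sire_ok & !dam_ok
    duo_d <- child_ok & !sire_ok & dam_ok
    has <- function(a, b, al) (a == al) | (b == al)
    trio_cons <- (has(s1, s2, c1) & has(d1, d2, c2)) |
                 (has(s1, s2, c2) & has(d1, d2, c1))
    duo_cons_s <- (c1 != c2) | has(s1, s2, c1) | has(s1, s2, c2)
    duo_cons_d <- (c1 != c2) | has(d1, d2, c1) | has(d1, d2, c2)
    nc <- nc + as.integer(trio | duo_s | duo_d)
    nv <- nv + as.integer((trio & !trio_cons) |
                          (duo_s & !duo_cons_s) | (duo_d & !duo_cons_d))
  }
  rate <- ifelse(nc > 0, nv / nc, 0)
  list(per_variant = data.frame(
         n_checked = nc, n_violations = nv, rate = rate,
         flagged = nv > 0 & rate > max_violation_rate),
       families = fams)
}

#' Consistency of one fully-called trio genotype combination
#'
#' Exposed helper implementing the biparental transmission rule on allele
#' pairs; used for spot checks and enumeration tests.
#'
#' @param sire,dam,child integer vectors of length 2 of allele indices.
#' @return TRUE iff the child's alleles can be partitioned between the
#'   parents.
#' @export
trio_consistent <- function(sire, dam, child) {
  (child[1] %in% sire && child[2] %in% dam) ||
    (child[2] %in% sire && child[1] %in% dam)
}
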