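#' Per-variant allele frequencies and genotype-class counts
#'
#' Frequencies are computed over fully-called diploid genotypes only: a call
#' with either allele missing is treated as missing. `AF` is the alternate
#' allele count over called alleles, `MAF = min(AF, 1 - AF)`. A variant with
#' no called genotype keeps `AF = NA` and is flagged undefined rather than
#' dropped.
#'
#' @param vt a [variant_table] with genotypes.
#' @return data.frame with columns `ac` (alt allele count), `an` (called
#'   alleles), `af`, `maf`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_missing`.
#' @export
allele_frequency <- function(vt) {
  called <- !is.na(vt$gt1) & !is.na(vt$gt2)
  alt_n <- (vt$gt1 == 1L) + (vt$gt2 == 1L)
  alt_n[!called] <- NA_integer_
  ac <- rowSums(alt_n, na.rm = TRUE)
  an <- 2L * rowSums(called)
  af <- ifelse(an > 0, ac / an, NA_real_)
  data.frame(
    ac = ac, an = an, af = af, maf = pmin(af, 1 - af),
    n_hom_ref = rowSums(alt_n == 0L, na.rm = TRUE),
    n_het = rowSums(alt_n == 1L, na.rm = TRUE),
    n_hom_alt = rowSums(alt_n == 2L, na.rm = TRUE),
    n_missing = rowSums(!called))
}

#' Private-allele test
#'
#' A variant is private iff exactly one individual carries at least one
#' alternate allele (a single homozygous carrier is still one individual).
#' Carriers are scanned over fully-called genotypes, consistent with the
#' frequency computation, so a private variant always has an alternate
#' allele count of 1 or 2.
#'
#' @param vt a [variant_table] with genotypes.
#' @return logical vector per variant.
#' @export
is_private <- function(vt) {
  called <- !is.na(vt$gt1) & !is.na(vt$gt2)
  carrier <- called & (vt$gt1 == 1L | vt$gt2 == 1L)
  rowSums(carrier) == 1L
}

#' Variant type of normalized records
#'
#' @param vt a [variant_table] (normalized).
#' @return character vector: "SNV", "insertion", "deletion" or "MNV".
#' @export
variant_type <- function(vt) {
  lr <- nchar(vt$ref); la <- nchar(vt$alt)
  ifelse(lr == 1L & la == 1L, "SNV",
         ifelse(lr < la, "insertion",
                ifelse(lr > la, "deletion", "MNV")))
}

#' Derived allele frequency spectrum
#'
#' Bins the derived-allele frequency of every variant with a defined,
#' non-zero frequency into `n_bins` equal-width bins over (0, 1]. By default
#' the alternate allele is taken as derived (reference = ancestral); with
#' `polarization = "ancestral"` the ancestral allele is read from the INFO
#' key `aa_key` and variants whose ancestral allele is neither ref nor alt
#' (or absent) are excluded and counted.
#'
#' @param vt a [variant_table] with genotypes.
#' @param n_bins number of equal-width frequency bins (default 20).
#' @param polarization "alt" (default) or "ancestral".
#' @param aa_key INFO key holding the ancestral allele.
#' @return integer vector of bin counts (length `n_bins`) with attributes
#'   `breaks` and `n_excluded`.
#' @export
derived_afs <- function(vt, n_bins = 20L, polarization = c("alt", "ancestral"),
                        aa_key = "MG_AA") {
  polarization <- match.arg(polarization)
  af <- allele_frequency(vt)$af
  excluded <- 0L
  if (polarization == "ancestral") {
    aa <- info_get(vt, aa_key)
    derived <- ifelse(!is.na(aa) & aa == vt$ref, af,
                      ifelse(!is.na(aa) & aa == vt$alt, 1 - af, NA_real_))
    excluded <- sum(!is.na(af) & is.na(derived))
    af <- derived
  }
  f <- af[!is.na(af) & af > 0]
  bins <- tabulate(pmin(ceiling(f * n_bins), n_bins), nbins = n_bins)
  structure(bins, breaks = seq(0, 1, length.out = n_bins + 1),
            n_excluded = excluded)
}

#' Variants-of-interest rule
#'
#' A pure union: a variant is of interest iff it carries a pathogenic
#' clinical match (`MG_CLN_PATH`), or its predicted impact is HIGH
#' (`MG_IMPACT`), or any configured damaging-score field meets its cutoff.
#' Adding annotations can therefore never remove a variant from the list.
#'
#' @param vt an annotated [variant_table].
#' @param damaging optional list of rules, each a list with `key` (INFO key
#'   of a numeric score), `threshold`, and optional `direction` (">=",
#'   default, or "<=").
#' @return logical vector per variant.
#' @export
variants_of_interest <- function(vt, damaging = list()) {
  voi <- info_has(vt, "MG_CLN_PATH") |
    (!is.na(info_get(vt, "MG_IMPACT")) & info_get(vt, "MG_IMPACT") == "HIGH")
  for (rule in damaging) {
    v <- suppressWarnings(as.numeric(info_get(vt, rule$key)))
    dir <- rule$direction %||% ">="
    hit <- !is.na(v) & (if (dir == "<=") v <= rule$threshold
                        else v >= rule$threshold)
    voi <- voi | hit
  }
  voi
}

#' Region-category genome footprint
#'
#' Bases of the (unmasked) genome falling in each region category, computed
#' from the gene models by the same precedence as [classify_region()]:
#' coding, then utr, splice region, intron, non-coding gene, upstream,
#' downstream, remainder intergenic.
#'
#' @param genes gene models.
#' @param genome_length total non-masked genome length (bp) to apportion.
#' @param splice_width splice-region width used in classification.
#' @return named numeric vector of base counts summing to `genome_length`.
#' @export
region_genome_footprint <- function(genes, genome_length, splice_width = 3L) {
  gx <- build_gene_index(genes, splice_width)
  cov <- GenomicRanges::GRanges()
  out <- c(coding = 0, utr = 0, splice_region = 0, intron = 0,
           non_coding_gene = 0, upstream_gene = 0, downstream_gene = 0,
           intergenic = 0)
  take <- function(gr, cov) {
    if (length(gr) == 0) return(list(bp = 0, cov = cov))
    red <- GenomicRanges::reduce(gr)
    new <- GenomicRanges::setdiff(red, cov)
    list(bp = sum(BiocGenerics::width(new)),
         cov = GenomicRanges::reduce(c(cov, red)))
  }
  for (layer in list(c("coding", "cds"), c("utr", "exon"),
                     c("splice_region", "splice"), c("intron", "gene_coding"),
                     c("non_coding_gene", "gene_noncoding"),
                     c("upstream_gene", "upstream"),
                     c("downstream_gene", "downstream"))) {
    r <- take(gx[[layer[2]]], cov)
    out[layer[1]] <- r$bp
    cov <- r$cov
  }
  out["intergenic"] <- genome_length - sum(out)
  out
}

#' Summarize a variant catalog
#'
#' Aggregates the cohort-level statistics of an annotated, normalized
#' variant stream: totals by variant type, private-allele count, derived
#' allele frequency spectrum, region-category breakdown (with variant and
#' genome percentage pairs when gene models and a genome length are given),
#' Mendelian violations (when a pedigree is given) and the
#' variants-of-interest count.
#'
#' @param vt annotated, normalized [variant_table].
#' @param genes optional gene models for the region breakdown. When the
#'   records already carry `MG_CSQ`, the region is taken from it (coding
#'   subcategories lumped into `coding`); otherwise [classify_region()] runs.
#' @param ped optional `pedigree`.
#' @param n_bins AFS bin count.
#' @param genome_length optional non-masked genome length (bp) for the
#'   genome-percentage column.
#' @param damaging damaging-score rules passed to [variants_of_interest()].
#' @param polarization,aa_key AFS polarization, see [derived_afs()].
#' @return an object of class `catalog_summary`.
#' @export
summarize_catalog <- function(vt, genes = NULL, ped = NULL, n_bins = 20L,
                              genome_length = NULL, damaging = list(),
                              polarization = "alt", aa_key = "MG_AA") {
  n <- n_variants(vt)
  types <- variant_type(vt)
  n_by_type <- vapply(c("SNV", "insertion", "deletion", "MNV"),
                      function(t) sum(types == t), integer(1))
  freq <- allele_frequency(vt)
  afs <- derived_afs(vt, n_bins, polarization, aa_key)
  region_cats <- c("coding", "utr", "splice_region", "intron",
                   "non_coding_gene", "upstream_gene", "downstream_gene",
                   "intergenic")
  coding_cats <- c("frameshift", "stop_gained", "stop_lost", "start_lost",
                   "inframe_insertion", "inframe_deletion", "missense",
                   "synonymous")
  region <- NULL
  csq <- info_get(vt, "MG_CSQ")
  if (!all(is.na(csq))) {
    region <- ifelse(csq %in% coding_cats, "coding", csq)
  } else if (!is.null(genes)) {
    region <- classify_region(vt, genes)$category
  }
  region_counts <- if (!is.null(region)) {
    vapply(region_cats, function(r) sum(region == r, na.rm = TRUE), integer(1))
  } else NULL
  genome_pct <- if (!is.null(genes) && !is.null(genome_length)) {
    fp <- region_genome_footprint(genes, genome_length)
    100 * fp[region_cats] / genome_length
  } else NULL
  mendel <- if (!is.null(ped)) mendel_check(vt, ped) else NULL
  voi <- variants_of_interest(vt, damaging)
  structure(list(
    n_variants = n,
    n_by_type = n_by_type,
    pct_indel = if (n > 0)
      100 * (n_by_type[["insertion"]] + n_by_type[["deletion"]]) / n else 0,
    n_private = sum(is_private(vt)),
    afs = afs,
    region_counts = region_counts,
    region_pct = if (!is.null(region_counts) && n > 0)
      100 * region_counts / n else NULL,
    genome_pct = genome_pct,
    n_voi = sum(voi),
    voi = voi,
    n_mendel_violation = if (!is.null(mendel))
      sum(mendel$per_variant$n_violations > 0) else NA_integer_,
    per_variant = cbind(
      data.frame(chrom = vt$chrom, pos = vt$pos, ref = vt$ref, alt = vt$alt,
                 type = types, stringsAsFactors = FALSE),
      freq,
      data.frame(private = is_private(vt),
                 region = if (is.null(region)) rep(NA_character_, n) else region,
                 voi = voi))),
    class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("catalog_summary: %d variant(s)\n", x$n_variants))
  cat("  by type: ", paste(names(x$n_by_type), x$n_by_type, sep = "=",
                           collapse = ", "),
      sprintf(" (%.1f%% indel)\n", x$pct_indel))
  cat(sprintf("  private: %d (%.1f%%)\n", x$n_private,
              if (x$n_variants > 0) 100 * x$n_private / x$n_variants else 0))
  if (!is.null(x$region_counts)) {
    cat("  regions: ", paste(names(x$region_counts), x$region_counts,
                             sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  variants of interest: %d\n", x$n_voi))
  invisible(x)
}

#' Write a catalog summary as TSV and JSON
#'
#' @param summary a `catalog_summary`.
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>_per_variant.tsv`.
#' @return character vector of the paths written, invisibly.
#' @export
write_catalog_summary <- function(summary, prefix) {
  js <- summary[c("n_variants", "n_by_type", "pct_indel", "n_private",
                  "n_voi", "n_mendel_violation")]
  js$afs <- as.integer(summary$afs)
  js$region_counts <- as.list(summary$region_counts)
  js$region_pct <- as.list(summary$region_pct)
  js$genome_pct <- as.list(summary$genome_pct)
  jpath <- paste0(prefix, ".json")
  jsonlite::write_json(js, jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tpath <- paste0(prefix, "_per_variant.tsv")
  utils::write.table(summary$per_variant, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jpath, tpath))
}
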