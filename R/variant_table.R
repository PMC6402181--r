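#' Tabular container for decomposed, biallelic variant records
#'
#' A `variant_table` holds one row per decomposed variant: fixed VCF fields,
#' an open-ended per-record INFO store, and per-sample diploid genotypes as
#' two integer allele-index matrices (`0` = ref, `1` = alt, `NA` = missing).
#' Every record carries exactly one alternate allele; multi-allelic sites are
#' split on read (see [read_vcf()]). The table is tagged with the assembly its
#' coordinates refer to, so that records cannot silently cross between source
#' and target coordinate spaces.
#'
#' @param chrom character vector of contig names.
#' @param pos integer vector, 1-based position of the first ref base.
#' @param ref,alt uppercase ACGT allele strings; `ref != alt` rowwise.
#' @param id optional variant identifiers (`NA` for none).
#' @param qual optional numeric qualities.
#' @param filter filter field strings (`NA` = missing, "PASS", or
#'   semicolon-joined labels).
#' @param info list of named lists, one per record; values are character
#'   vectors or `TRUE` for flags. `NULL` means all-empty.
#' @param gt1,gt2 integer matrices (variants x samples) of first/second allele
#'   indices, or `NULL` when there are no samples.
#' @param samples character vector of sample names.
#' @param assembly assembly tag for the coordinate space of the records.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, id = NULL, qual = NULL,
                          filter = NULL, info = NULL, gt1 = NULL, gt2 = NULL,
                          samples = character(), assembly = "unknown") {
  n <- length(chrom)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  id <- if (is.null(id)) rep(NA_character_, n) else as.character(id)
  qual <- if (is.null(qual)) rep(NA_real_, n) else as.numeric(qual)
  filter <- if (is.null(filter)) rep(NA_character_, n) else as.character(filter)
  info <- if (is.null(info)) rep(list(list()), n) else info
  stopifnot(length(id) == n, length(qual) == n, length(filter) == n,
            length(info) == n)
  ns <- length(samples)
  if (is.null(gt1)) gt1 <- matrix(NA_integer_, n, ns)
  if (is.null(gt2)) gt2 <- matrix(NA_integer_, n, ns)
  storage.mode(gt1) <- "integer"
  storage.mode(gt2) <- "integer"
  stopifnot(nrow(gt1) == n, nrow(gt2) == n,
            ncol(gt1) == ns, ncol(gt2) == ns)
  if (n > 0) {
    bad <- which(!is_acgt(ref) | !is_acgt(alt))
    if (length(bad)) {
      la_stop(sprintf("non-ACGT allele at record %d (%s>%s)",
                      bad[1], ref[bad[1]], alt[bad[1]]),
              "liftann_parse_error")
    }
    same <- which(ref == alt)
    if (length(same)) {
      la_stop(sprintf("ref equals alt at record %d (%s:%d)",
                      same[1], chrom[same[1]], pos[same[1]]),
              "liftann_parse_error")
    }
    if (any(pos < 1L)) la_stop("position < 1", "liftann_parse_error")
  }
  structure(
    list(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
         qual = qual, filter = filter, info = info,
         gt1 = gt1, gt2 = gt2, samples = as.character(samples),
         assembly = assembly),
    class = "variant_table")
}

#' Number of variant records
#' @param x a `variant_table`.
#' @export
n_variants <- function(x) length(x$chrom)

#' Sample names of a variant table
#' @param x a `variant_table`.
#' @export
vt_samples <- function(x) x$samples

#' @export
length.variant_table <- function(x) n_variants(x)

#' Subset a variant table by record index
#' @param x a `variant_table`.
#' @param i integer or logical index over records.
#' @export
`[.variant_table` <- function(x, i) {
  variant_table(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], x$id[i], x$qual[i],
                x$filter[i], x$info[i],
                x$gt1[i, , drop = FALSE], x$gt2[i, , drop = FALSE],
                x$samples, x$assembly)
}

#' Row-bind variant tables
#'
#' All inputs must share the same sample list and assembly tag.
#' @param ... `variant_table` objects.
#' @export
vt_bind <- function(...) {
  vts <- list(...)
  vts <- vts[vapply(vts, n_variants, 1L) > 0 | seq_along(vts) == 1]
  base <- vts[[1]]
  for (v in vts[-1]) {
    if (!identical(v$samples, base$samples))
      la_stop("cannot bind variant tables with different samples",
              "liftann_config_error")
    if (!identical(v$assembly, base$assembly))
      la_stop(sprintf("cannot bind variant tables on assemblies '%s' and '%s'",
                      base$assembly, v$assembly), "liftann_config_error")
  }
  variant_table(
    unlist(lapply(vts, `[[`, "chrom")),
    unlist(lapply(vts, `[[`, "pos")),
    unlist(lapply(vts, `[[`, "ref")),
    unlist(lapply(vts, `[[`, "alt")),
    unlist(lapply(vts, `[[`, "id")),
    unlist(lapply(vts, `[[`, "qual")),
    unlist(lapply(vts, `[[`, "filter")),
    do.call(c, lapply(vts, `[[`, "info")),
    do.call(rbind, lapply(vts, `[[`, "gt1")),
    do.call(rbind, lapply(vts, `[[`, "gt2")),
    base$samples, base$assembly)
}

#' Sort a variant table by (chrom, pos, ref, alt)
#'
#' @param x a `variant_table`.
#' @param contig_order optional character vector fixing the contig order;
#'   defaults to the lexicographic order of the contigs present.
#' @export
vt_sort <- function(x, contig_order = NULL) {
  if (is.null(contig_order)) contig_order <- sort(unique(x$chrom))
  ci <- match(x$chrom, contig_order)
  if (anyNA(ci)) {
    la_stop(sprintf("contig '%s' absent from declared contig order",
                    x$chrom[which(is.na(ci))[1]]), "liftann_order_error")
  }
  x[order(ci, x$pos, x$ref, x$alt)]
}

#' Variant key strings "chrom:pos:ref:alt"
#' @param x a `variant_table`.
#' @export
vt_keys <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Get a scalar INFO value per record
#'
#' @param x a `variant_table`.
#' @param key INFO key.
#' @return character vector, `NA` where the key is absent; flags return "TRUE".
#' @export
info_get <- function(x, key) {
  vapply(x$info, function(ii) {
    v <- ii[[key]]
    if (is.null(v)) NA_character_ else paste(as.character(v), collapse = ",")
  }, character(1))
}

#' Test presence of an INFO key per record
#' @param x a `variant_table`.
#' @param key INFO key.
#' @export
info_has <- function(x, key) {
  vapply(x$info, function(ii) !is.null(ii[[key]]), logical(1))
}

#' Set an INFO key on a subset of records
#'
#' @param x a `variant_table`.
#' @param key INFO key.
#' @param values vector of values (recycled if scalar) or a list of values.
#' @param which integer/logical index of the records to touch (default all).
#' @export
info_set <- function(x, key, values, which = seq_len(n_variants(x))) {
  idx <- seq_len(n_variants(x))[which]
  if (!is.list(values)) values <- as.list(rep_len(values, length(idx)))
  stopifnot(length(values) == length(idx))
  for (j in seq_along(idx)) x$info[[idx[j]]][[key]] <- values[[j]]
  x
}

#' Drop an INFO key everywhere
#' @noRd
info_drop <- function(x, key) {
  x$info <- lapply(x$info, function(ii) { ii[[key]] <- NULL; ii })
  x
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d record(s), %d sample(s), assembly '%s'\n",
              n_variants(x), length(x$samples), x$assembly))
  if (n_variants(x) > 0) {
    show <- utils::head(as.data.frame(x), 6)
    print(show)
    if (n_variants(x) > 6) cat(sprintf("... and %d more\n", n_variants(x) - 6))
  }
  invisible(x)
}

#' @export
as.data.frame.variant_table <- function(x, ...) {
  data.frame(chrom = x$chrom, pos = x$pos, id = x$id, ref = x$ref,
             alt = x$alt, qual = x$qual, filter = x$filter,
             info = vapply(x$info, format_info_string, character(1)),
             stringsAsFactors = FALSE)
}
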