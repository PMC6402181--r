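# Generic annotation-join engine. Sources are keyed stores living in target
# coordinates: ALLELE_KEYED ((chrom,pos,ref,alt) -> values), POSITION_KEYED
# ((chrom,pos) -> values), INTERVAL (interval tree -> values). Matching
# values are written into INFO under the namespace MG_<NAME>_<FIELD>, so two
# sources can never collide unless they share a name (checked up front).

#' Load an annotation source
#'
#' Reads a TSV (with header), ClinVar-style VCF, or BED file into a keyed
#' annotation store. Allele-keyed records are re-normalized against the
#' target genome when one is supplied, so representation differences cannot
#' break allele-identity matching. Duplicate keys are collapsed with their
#' values concatenated. BED intervals (0-based half-open) are converted to
#' 1-based inclusive internally.
#'
#' @param path input file.
#' @param kind one of "ALLELE_KEYED", "POSITION_KEYED", "INTERVAL".
#' @param fields character vector of value column names to retain. For a VCF
#'   source these name INFO keys (e.g. CLNSIG); for BED the single field is
#'   taken from the name column.
#' @param name unique source label used as the INFO namespace.
#' @param genome optional target-assembly genome for re-normalization.
#' @return an object of class `annotation_source`.
#' @export
load_source <- function(path, kind, fields, name, genome = NULL) {
  kind <- match.arg(kind, c("ALLELE_KEYED", "POSITION_KEYED", "INTERVAL"))
  if (kind == "INTERVAL") {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    df <- data.frame(chrom = bed[[1]],
                     start = as.integer(bed[[2]]) + 1L,
                     end = as.integer(bed[[3]]),
                     stringsAsFactors = FALSE)
    if (any(df$start > df$end)) {
      la_stop(sprintf("interval source '%s': empty or negative interval", name),
              "liftann_schema_error")
    }
    df[[fields[1]]] <- if (ncol(bed) >= 4) as.character(bed[[4]]) else "1"
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    return(structure(list(name = name, kind = kind, fields = fields[1],
                          table = df, ranges = gr),
                     class = "annotation_source"))
  }
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vt <- suppressMessages(read_vcf(path))
    df <- data.frame(chrom = vt$chrom, pos = vt$pos, ref = vt$ref,
                     alt = vt$alt, stringsAsFactors = FALSE)
    for (f in fields) df[[f]] <- info_get(vt, f)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    missing_cols <- setdiff(fields, names(df))
    if (length(missing_cols)) {
      la_stop(sprintf("source '%s': field(s) %s absent from header of '%s'",
                      name, paste(missing_cols, collapse = ", "), path),
              "liftann_schema_error")
    }
    need <- if (kind == "ALLELE_KEYED") c("chrom", "pos", "ref", "alt")
            else c("chrom", "pos")
    if (!all(need %in% names(df))) {
      la_stop(sprintf("source '%s': key column(s) %s absent from header",
                      name, paste(setdiff(need, names(df)), collapse = ", ")),
              "liftann_schema_error")
    }
    df$pos <- as.integer(df$pos)
  }
  if (kind == "ALLELE_KEYED") {
    df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
    if (!is.null(genome)) {
      for (i in seq_len(nrow(df))) {
        nv <- normalize_one(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], genome)
        df$pos[i] <- nv$pos; df$ref[i] <- nv$ref; df$alt[i] <- nv$alt
      }
    }
    key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    key <- paste(df$chrom, df$pos, sep = ":")
  }
  # collapse duplicate keys, concatenating values per field
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    for (f in fields) {
      agg <- tapply(df[[f]], key, function(v) paste(v, collapse = ","))
      df[[f]][keep] <- as.character(agg[key[keep]])
    }
    df <- df[keep, , drop = FALSE]
    key <- key[keep]
  }
  structure(list(name = name, kind = kind, fields = fields,
                 table = df, key = key),
            class = "annotation_source")
}

#' @export
print.annotation_source <- function(x, ...) {
  cat(sprintf("annotation_source '%s' (%s): %d record(s), fields: %s\n",
              x$name, x$kind, nrow(x$table), paste(x$fields, collapse = ", ")))
  invisible(x)
}

#' Match variants against an allele-keyed source
#'
#' A variant matches a source row iff chrom, pos, ref and alt are all
#' identical after normalization; positional overlap with a different
#' alternate (or with the reference only) is not a match.
#'
#' @param vt target-coordinate [variant_table].
#' @param src an `annotation_source` of kind ALLELE_KEYED.
#' @return integer vector: row index into the source table per variant, `NA`
#'   for no match.
#' @export
match_allele_keyed <- function(vt, src) {
  stopifnot(src$kind == "ALLELE_KEYED")
  match(vt_keys(vt), src$key)
}

#' Canonicalize a clinical-significance string
#'
#' Case-insensitive; composite assertions are split on "/" and "," and each
#' token mapped onto the controlled vocabulary. Returns NA for strings with
#' no recognizable token.
#' @param sig character vector of raw significance strings.
#' @return list with `canonical` (character, tokens re-joined with "/") and
#'   `pathogenic` (logical: any token pathogenic or likely pathogenic).
#' @export
parse_significance <- function(sig) {
  vocab <- c("pathogenic", "likely pathogenic", "uncertain significance",
             "likely benign", "benign", "risk factor", "drug response",
             "association", "protective", "affects", "other", "not provided",
             "conflicting interpretations of pathogenicity")
  canonical <- character(length(sig)); pathogenic <- logical(length(sig))
  for (i in seq_along(sig)) {
    toks <- trimws(strsplit(tolower(gsub("_", " ", sig[i])), "[/,]")[[1]])
    toks <- toks[toks != ""]
    known <- toks[toks %in% vocab]
    canonical[i] <- if (length(known))
      paste(gsub(" ", "_", known), collapse = "/") else NA_character_
    pathogenic[i] <- any(known %in% c("pathogenic", "likely pathogenic"))
  }
  list(canonical = canonical, pathogenic = pathogenic)
}

#' Flag variants matching clinical assertions
#'
#' Writes `MG_CLN_SIG` (canonical significance), `MG_CLN_DN` (condition) and
#' `MG_CLN_GENE` for every variant identical in position and allele to an
#' assertion, and sets the flag `MG_CLN_PATH` iff any significance token is
#' pathogenic or likely pathogenic. Unrecognized significance strings are
#' recorded verbatim under `MG_CLN_SIG_RAW` with a warning and never set the
#' pathogenic flag.
#'
#' @param vt target-coordinate [variant_table].
#' @param assertions `annotation_source` (ALLELE_KEYED) whose fields include
#'   `significance` and optionally `condition` and `gene`.
#' @return the annotated [variant_table].
#' @export
flag_clinical <- function(vt, assertions) {
  hit <- match_allele_keyed(vt, assertions)
  idx <- which(!is.na(hit))
  if (!length(idx)) return(vt)
  rows <- hit[idx]
  sig_raw <- assertions$table$significance[rows]
  parsed <- parse_significance(sig_raw)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (is.na(parsed$canonical[j])) {
      warning(sprintf("unrecognized clinical significance '%s' at %s",
                      sig_raw[j], vt_keys(vt)[i]))
      vt$info[[i]][["MG_CLN_SIG_RAW"]] <- sig_raw[j]
    } else {
      vt$info[[i]][["MG_CLN_SIG"]] <- parsed$canonical[j]
      if (parsed$pathogenic[j]) vt$info[[i]][["MG_CLN_PATH"]] <- TRUE
    }
    if (!is.null(assertions$table$condition))
      vt$info[[i]][["MG_CLN_DN"]] <- gsub("[;= ]", "_",
                                          assertions$table$condition[rows[j]])
    if (!is.null(assertions$table$gene))
      vt$info[[i]][["MG_CLN_GENE"]] <- assertions$table$gene[rows[j]]
  }
  vt
}

#' Annotate variants against an ordered list of sources
#'
#' For each source, matching values are written under
#' `MG_<SOURCENAME>_<FIELD>`; absent matches write nothing. Namespaces are
#' checked for collisions before any record is touched. Annotation never
#' alters coordinates, alleles or genotypes, and the result is independent of
#' source order and record order.
#'
#' @param vt target-coordinate [variant_table] (lift status LIFTED or
#'   ALLELE_SWAP).
#' @param sources list of `annotation_source` objects.
#' @return the annotated [variant_table].
#' @export
annotate_variants <- function(vt, sources) {
  keys <- unlist(lapply(sources, function(s)
    paste0("MG_", toupper(s$name), "_", toupper(s$fields))))
  if (anyDuplicated(keys)) {
    la_stop(sprintf("INFO key collision across annotation sources: %s",
                    keys[duplicated(keys)][1]), "liftann_config_error")
  }
  nm <- vapply(sources, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    la_stop("annotation source names must be unique", "liftann_config_error")
  }
  # canonical processing order: result must not depend on how the source
  # list happened to be ordered
  sources <- sources[order(nm)]
  for (src in sources) {
    prefix <- paste0("MG_", toupper(src$name), "_")
    if (src$kind == "ALLELE_KEYED") {
      hit <- match_allele_keyed(vt, src)
      for (i in which(!is.na(hit))) {
        for (f in src$fields)
          vt$info[[i]][[paste0(prefix, toupper(f))]] <- src$table[[f]][hit[i]]
      }
    } else if (src$kind == "POSITION_KEYED") {
      hit <- match(paste(vt$chrom, vt$pos, sep = ":"), src$key)
      for (i in which(!is.na(hit))) {
        for (f in src$fields)
          vt$info[[i]][[paste0(prefix, toupper(f))]] <- src$table[[f]][hit[i]]
      }
    } else {  # INTERVAL: any overlap of the ref span suffices
      q <- GenomicRanges::GRanges(
        vt$chrom, IRanges::IRanges(vt$pos, vt$pos + nchar(vt$ref) - 1L))
      ov <- GenomicRanges::findOverlaps(q, src$ranges)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      f <- src$fields[1]
      for (i in unique(qh)) {
        vals <- unique(src$table[[f]][sh[qh == i]])
        vt$info[[i]][[paste0(prefix, toupper(f))]] <- vals
      }
    }
  }
  vt
}
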