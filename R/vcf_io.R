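# VCF text conventions: INFO stored per record as a named list; flags are
# TRUE, everything else character vectors (comma-joined on write).

#' @noRd
parse_info_string <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) out[[p]] <- TRUE
    else out[[substr(p, 1, eq - 1)]] <-
        strsplit(substr(p, eq + 1, nchar(p)), ",", fixed = TRUE)[[1]]
  }
  out
}

#' @noRd
format_info_string <- function(ii) {
  if (length(ii) == 0) return(".")
  paste(vapply(names(ii), function(k) {
    v <- ii[[k]]
    if (isTRUE(v)) k else paste0(k, "=", paste(as.character(v), collapse = ","))
  }, character(1)), collapse = ";")
}

#' @noRd
parse_gt_field <- function(gt) {
  # "0/1", "1|1", ".", "./." -> c(a1, a2); haploid calls get NA second allele
  if (is.na(gt)) return(c(NA_integer_, NA_integer_))
  gt <- strsplit(gt, ":", fixed = TRUE)[[1]][1]
  al <- strsplit(gt, "[/|]")[[1]]
  al <- ifelse(al == ".", NA, al)
  a <- suppressWarnings(as.integer(al))
  c(a[1], if (length(a) >= 2) a[2] else NA_integer_)
}

#' Read a VCF file into a decomposed variant table
#'
#' Parses a VCF 4.2 file (optionally gzipped), decomposing every
#' multi-allelic site into one biallelic record per alternate allele.
#' Genotype indices are remapped per decomposed record: the kept alternate
#' becomes 1, the reference stays 0, and any *other* alternate becomes
#' missing, so that no reference observation is fabricated. Symbolic
#' alternates (`<DEL>`, breakends), spanning-deletion `*` alleles and alleles
#' containing `N` are skipped; the number of skipped alternates is attached as
#' attribute `skipped` and reported with a message.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param assembly assembly tag to stamp on the records; default is the
#'   header's `##assembly=` value, or "unknown".
#' @return a [variant_table]; attribute `skipped` counts excluded alternates.
#' @export
read_vcf <- function(path, assembly = NULL) {
  lines_head <- readLines(path, n = 1L)
  if (length(lines_head) == 0 || !startsWith(lines_head[1], "##fileformat=VCF")) {
    la_stop(sprintf("malformed VCF header at line 1 of '%s': missing ##fileformat",
                    path), "liftann_parse_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  n_header <- length(meta) + 1L  # meta lines plus the #CHROM line
  if (is.null(assembly)) {
    am <- grep("^##assembly=", meta, value = TRUE)
    assembly <- if (length(am)) sub("^##assembly=", "", am[1]) else "unknown"
  }
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(structure(variant_table(character(), integer(), character(),
                                   character(), assembly = assembly,
                                   samples = vcf_sample_names(v)),
                     skipped = 0L))
  }
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  dec <- which(chrom[-1] == chrom[-length(chrom)] & diff(pos) < 0)
  if (length(dec)) {
    la_stop(sprintf("non-monotonic positions within contig '%s' at line %d",
                    chrom[dec[1] + 1], n_header + dec[1] + 1L),
            "liftann_parse_error")
  }
  samples <- vcf_sample_names(v)
  ns <- length(samples)
  gt_raw <- if (ns > 0) v@gt[, -1, drop = FALSE] else NULL

  out_chrom <- character(); out_pos <- integer(); out_id <- character()
  out_ref <- character(); out_alt <- character(); out_qual <- numeric()
  out_filter <- character(); out_info <- list()
  g1 <- list(); g2 <- list()
  skipped <- 0L

  for (r in seq_len(nrow(fix))) {
    ref <- toupper(fix[r, "REF"])
    alts <- toupper(strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]])
    if (grepl("[^ACGT]", ref)) { skipped <- skipped + length(alts); next }
    gts <- if (ns > 0) {
      m <- vapply(gt_raw[r, ], parse_gt_field, integer(2))
      m  # 2 x ns
    } else matrix(integer(0), 2, 0)
    info_parsed <- parse_info_string(fix[r, "INFO"])
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (grepl("[<>\\[\\]*]", alt) || grepl("[^ACGT]", alt)) {
        skipped <- skipped + 1L
        next
      }
      remap <- function(a) ifelse(is.na(a), NA_integer_,
                                  ifelse(a == 0L, 0L,
                                         ifelse(a == k, 1L, NA_integer_)))
      out_chrom <- c(out_chrom, fix[r, "CHROM"])
      out_pos <- c(out_pos, pos[r])
      out_id <- c(out_id, fix[r, "ID"])
      out_ref <- c(out_ref, ref)
      out_alt <- c(out_alt, alt)
      out_qual <- c(out_qual, suppressWarnings(as.numeric(fix[r, "QUAL"])))
      out_filter <- c(out_filter, fix[r, "FILTER"])
      out_info <- c(out_info, list(info_parsed))
      g1 <- c(g1, list(remap(gts[1, ])))
      g2 <- c(g2, list(remap(gts[2, ])))
    }
  }
  if (skipped > 0) {
    message(sprintf("read_vcf: skipped %d symbolic/N-containing alternate allele(s)",
                    skipped))
  }
  vt <- variant_table(out_chrom, out_pos, out_ref, out_alt, out_id, out_qual,
                      out_filter, out_info,
                      do.call(rbind, g1) %||% NULL,
                      do.call(rbind, g2) %||% NULL,
                      samples = samples, assembly = assembly)
  structure(vt, skipped = skipped)
}

#' @noRd
vcf_sample_names <- function(v) {
  if (is.null(v@gt) || ncol(v@gt) <= 1) character() else colnames(v@gt)[-1]
}

#' @noRd
format_gt_matrix <- function(vt) {
  n <- n_variants(vt)
  a1 <- ifelse(is.na(vt$gt1), ".", as.character(vt$gt1))
  a2 <- ifelse(is.na(vt$gt2), ".", as.character(vt$gt2))
  matrix(paste0(a1, "/", a2), n, length(vt$samples))
}

#' Write a variant table as a VCF 4.2 file
#'
#' Every INFO key present in the records is declared in the header: keys
#' listed in `header_meta$info` keep their declared Number/Type/Description,
#' any other key is declared as unbounded String (flags as Flag). Input must
#' be coordinate-sorted under the declared contig order.
#'
#' @param vt a [variant_table].
#' @param path output path; a `.gz` suffix gzips the file.
#' @param header_meta optional list with elements `contigs` (named integer
#'   vector of contig lengths, fixing the contig order), `info` (data.frame
#'   with columns id, number, type, description), and `extra` (character
#'   vector of additional `##` lines).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, header_meta = list()) {
  contigs <- header_meta$contigs
  contig_order <- if (!is.null(contigs)) names(contigs) else unique(vt$chrom)
  ci <- match(vt$chrom, contig_order)
  if (anyNA(ci)) {
    la_stop(sprintf("contig '%s' not in declared contig order",
                    vt$chrom[which(is.na(ci))[1]]), "liftann_order_error")
  }
  if (n_variants(vt) > 1) {
    bad <- which(diff(ci) < 0 | (diff(ci) == 0 & diff(vt$pos) < 0))
    if (length(bad)) {
      i <- bad[1]
      la_stop(sprintf("unsorted records: %s:%d followed by %s:%d",
                      vt$chrom[i], vt$pos[i], vt$chrom[i + 1], vt$pos[i + 1]),
              "liftann_order_error")
    }
  }
  # header
  h <- "##fileformat=VCFv4.2"
  if (!identical(vt$assembly, "unknown"))
    h <- c(h, paste0("##assembly=", vt$assembly))
  if (!is.null(contigs)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)))
  } else {
    h <- c(h, sprintf("##contig=<ID=%s>", contig_order))
  }
  declared <- header_meta$info
  used_keys <- unique(unlist(lapply(vt$info, names)))
  info_lines <- character()
  seen <- character()
  if (!is.null(declared)) {
    for (r in seq_len(nrow(declared))) {
      info_lines <- c(info_lines,
        sprintf('##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
                declared$id[r], declared$number[r], declared$type[r],
                declared$description[r]))
    }
    seen <- declared$id
  }
  for (k in setdiff(used_keys, seen)) {
    is_flag <- all(vapply(vt$info, function(ii)
      is.null(ii[[k]]) || isTRUE(ii[[k]]), logical(1)))
    info_lines <- c(info_lines, if (is_flag)
      sprintf('##INFO=<ID=%s,Number=0,Type=Flag,Description="Annotation %s">', k, k)
    else
      sprintf('##INFO=<ID=%s,Number=.,Type=String,Description="Annotation %s">', k, k))
  }
  h <- c(h, info_lines, header_meta$extra)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(vt$samples) > 0) {
    h <- c(h, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    cols <- c(cols, "FORMAT", vt$samples)
  }
  h <- c(h, paste(cols, collapse = "\t"))
  # body
  body <- character(0)
  if (n_variants(vt) > 0) {
    fields <- cbind(
      vt$chrom, as.character(vt$pos),
      ifelse(is.na(vt$id), ".", vt$id), vt$ref, vt$alt,
      ifelse(is.na(vt$qual), ".", as.character(vt$qual)),
      ifelse(is.na(vt$filter), ".", vt$filter),
      vapply(vt$info, format_info_string, character(1)))
    if (length(vt$samples) > 0) {
      fields <- cbind(fields, "GT", format_gt_matrix(vt))
    }
    body <- apply(fields, 1, paste, collapse = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(h, body), con)
  invisible(path)
}
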