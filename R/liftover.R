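#' Lift variants from source to target coordinates
#'
#' Maps every record of a normalized source-assembly [variant_table] through
#' a chain set onto the target assembly and reconciles alleles with the
#' target reference:
#'
#' * every base of the ref span (plus the following base for insertions) must
#'   map through one chain with consecutive offsets, else `SPANS_GAP`;
#' * on a minus-strand chain, ref and alt are reverse-complemented, the
#'   target position is the leftmost lifted base, and the transform records
#'   `REVCOMP`;
#' * the target reference is fetched and compared: equal to the lifted ref
#'   gives `LIFTED`; equal to the lifted alt gives `ALLELE_SWAP` with ref and
#'   alt exchanged (transform gains `SWAP`); neither gives `REF_MISMATCH`,
#'   which is not annotation-eligible;
#' * lifted indels are re-normalized against the target genome so that
#'   allele-identity matching is well-defined after strand flips.
#'
#' Records with status `LIFTED`/`ALLELE_SWAP` are returned in target
#' coordinates carrying provenance INFO (`MG_LIFT_STATUS`, `MG_TRANSFORM`,
#' `MG_TGT_LOCUS`) plus the original coordinates (`MG_ORIG`) used later by
#' [back_translate()]. All other records are returned unchanged in source
#' coordinates with their status in `MG_LIFT_STATUS`.
#'
#' @param vt normalized source-assembly [variant_table].
#' @param chains a `chain_set` from [parse_chain()].
#' @param target_genome [Biostrings::DNAStringSet] of the target assembly.
#' @param target_assembly assembly tag for the lifted records.
#' @return list with elements `lifted` (variant_table, target coordinates),
#'   `unlifted` (variant_table, source coordinates) and `results` (data.frame
#'   with one row per input: `status`, `target_chrom`, `target_pos`,
#'   `target_strand`, `transform`, and the original coordinates).
#' @export
lift_variants <- function(vt, chains, target_genome, target_assembly = "target") {
  n <- n_variants(vt)
  res <- data.frame(status = character(n), target_chrom = NA_character_,
                    target_pos = NA_integer_, target_strand = NA_character_,
                    transform = "NONE",
                    orig_chrom = vt$chrom, orig_pos = vt$pos,
                    orig_ref = vt$ref, orig_alt = vt$alt,
                    new_ref = NA_character_, new_alt = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- lift_one(vt$chrom[i], vt$pos[i], vt$ref[i], vt$alt[i],
                  chains, target_genome)
    res$status[i] <- r$status
    if (r$status %in% c("LIFTED", "ALLELE_SWAP")) {
      res$target_chrom[i] <- r$tgt_chrom
      res$target_pos[i] <- r$tgt_pos
      res$target_strand[i] <- r$tgt_strand
      res$transform[i] <- r$transform
      res$new_ref[i] <- r$ref
      res$new_alt[i] <- r$alt
    }
  }
  ok <- res$status %in% c("LIFTED", "ALLELE_SWAP")
  lifted <- vt[ok]
  if (any(ok)) {
    lifted$chrom <- res$target_chrom[ok]
    lifted$pos <- res$target_pos[ok]
    lifted$ref <- res$new_ref[ok]
    lifted$alt <- res$new_alt[ok]
    lifted$assembly <- target_assembly
    oi <- which(ok)
    for (j in seq_along(oi)) {
      i <- oi[j]
      lifted$info[[j]][["MG_LIFT_STATUS"]] <- res$status[i]
      lifted$info[[j]][["MG_TRANSFORM"]] <- res$transform[i]
      lifted$info[[j]][["MG_TGT_LOCUS"]] <- paste(
        res$target_chrom[i], res$target_pos[i], res$target_strand[i], sep = ":")
      lifted$info[[j]][["MG_ORIG"]] <- paste(
        res$orig_chrom[i], res$orig_pos[i], res$orig_ref[i], res$orig_alt[i],
        sep = ":")
    }
  } else {
    lifted$assembly <- target_assembly
  }
  unlifted <- vt[!ok]
  unlifted <- info_set(unlifted, "MG_LIFT_STATUS", res$status[!ok])
  list(lifted = lifted, unlifted = unlifted, results = res)
}

#' @noRd
lift_one <- function(chrom, pos, ref, alt, chains, target_genome) {
  span <- nchar(ref)
  # for insertions, require the base after the anchor to map as well, so the
  # insertion point itself is inside one contiguous block
  extra <- if (nchar(alt) > nchar(ref)) 1L else 0L
  pos0 <- (pos - 1L):(pos - 1L + span - 1L + extra)
  maps <- lapply(pos0, function(p) map_point(chains, chrom, p))
  st <- vapply(maps, `[[`, "", "status")
  if (any(st == "AMBIGUOUS_MULTIMAP")) return(list(status = "AMBIGUOUS_MULTIMAP"))
  if (all(st == "NO_CHAIN")) return(list(status = "NO_CHAIN"))
  if (any(st != "LIFTED")) return(list(status = "SPANS_GAP"))
  cid <- vapply(maps, `[[`, "", "chain_id")
  tchrom <- vapply(maps, `[[`, "", "tgt_chrom")
  tstrand <- vapply(maps, `[[`, "", "tgt_strand")
  tpos <- vapply(maps, function(m) as.integer(m$tgt_pos0), integer(1))
  if (length(unique(cid)) > 1 || length(unique(tchrom)) > 1 ||
      length(unique(tstrand)) > 1) {
    return(list(status = "SPANS_GAP"))
  }
  step <- if (tstrand[1] == "+") 1L else -1L
  if (length(tpos) > 1 && !all(diff(tpos) == step)) {
    return(list(status = "SPANS_GAP"))
  }
  strand <- tstrand[1]
  ref_tpos <- tpos[seq_len(span)]  # target positions of the ref span only
  transform <- "NONE"
  new_ref <- ref; new_alt <- alt
  if (strand == "-") {
    new_ref <- revcomp(ref)
    new_alt <- revcomp(alt)
    transform <- "REVCOMP"
  }
  tgt_pos <- min(ref_tpos) + 1L  # leftmost lifted base, 1-based
  tseq_ref <- genome_seq(target_genome, tchrom[1], tgt_pos,
                         tgt_pos + nchar(new_ref) - 1L)
  status <- NULL
  if (tseq_ref == new_ref) {
    status <- "LIFTED"
  } else {
    tlen <- length(target_genome[[tchrom[1]]])
    if (tgt_pos + nchar(new_alt) - 1L <= tlen) {
      tseq_alt <- genome_seq(target_genome, tchrom[1], tgt_pos,
                             tgt_pos + nchar(new_alt) - 1L)
      if (tseq_alt == new_alt) {
        status <- "ALLELE_SWAP"
        tmp <- new_ref; new_ref <- new_alt; new_alt <- tmp
        transform <- if (transform == "REVCOMP") "REVCOMP_AND_SWAP" else "SWAP"
      }
    }
    if (is.null(status)) return(list(status = "REF_MISMATCH"))
  }
  norm <- normalize_one(tchrom[1], tgt_pos, new_ref, new_alt, target_genome)
  list(status = status, tgt_chrom = tchrom[1], tgt_pos = norm$pos,
       tgt_strand = strand, transform = transform,
       ref = norm$ref, alt = norm$alt)
}

#' Translate annotated records back to their original coordinates
#'
#' Restores the source-assembly locus and alleles carried in `MG_ORIG` at
#' lift time, retaining every annotation gathered in target space plus the
#' provenance keys (`MG_TGT_LOCUS`, `MG_TRANSFORM`, `MG_LIFT_STATUS`).
#' Back-translation uses the carried coordinates, never a reverse chain pass,
#' so it is lossless by construction.
#'
#' @param vt a target-coordinate [variant_table] produced by [lift_variants()].
#' @param assembly assembly tag to restore on the output records.
#' @return a source-coordinate [variant_table].
#' @export
back_translate <- function(vt, assembly = "source") {
  orig <- info_get(vt, "MG_ORIG")
  if (anyNA(orig)) {
    la_stop(sprintf("record %d lacks original coordinates (MG_ORIG)",
                    which(is.na(orig))[1]), "liftann_internal_error")
  }
  parts <- strsplit(orig, ":", fixed = TRUE)
  vt$chrom <- vapply(parts, `[[`, "", 1)
  vt$pos <- as.integer(vapply(parts, `[[`, "", 2))
  vt$ref <- vapply(parts, `[[`, "", 3)
  vt$alt <- vapply(parts, `[[`, "", 4)
  vt$assembly <- assembly
  info_drop(vt, "MG_ORIG")
}

#' Merge back-translated and unliftable variant streams
#'
#' Combines the two source-coordinate streams into a single sorted stream.
#' Unlifted records carry their lift status in `MG_LIFT_STATUS` and no
#' target-space annotations. The output record count is the sum of the input
#' counts; a duplicate (chrom, pos, ref, alt) across the streams is an error.
#'
#' @param lifted_annotated back-translated, annotated [variant_table].
#' @param unlifted [variant_table] of records that could not be lifted.
#' @param contig_order optional contig order for sorting.
#' @return sorted merged [variant_table].
#' @export
merge_streams <- function(lifted_annotated, unlifted, contig_order = NULL) {
  merged <- vt_bind(lifted_annotated, unlifted)
  keys <- vt_keys(merged)
  if (anyDuplicated(keys)) {
    la_stop(sprintf("duplicate variant across streams: %s",
                    keys[duplicated(keys)][1]), "liftann_duplicate_error")
  }
  vt_sort(merged, contig_order)
}
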