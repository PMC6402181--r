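#' Normalize variants against a reference genome
#'
#' Applies the standard parsimony/left-alignment procedure to every record:
#' shared trailing bases are trimmed, shared leading bases are trimmed down to
#' a single anchor base for indels, and indels are left-shifted through
#' repeats as far as the genome allows (classic left-alignment: whenever ref
#' and alt end in the same base it is dropped and, if either allele empties,
#' the preceding genome base is prepended to both). SNVs pass through
#' unchanged and the whole operation is idempotent. After normalization, ref
#' and alt share no common suffix and share a leading base only when one of
#' them has length 1 (an anchored indel).
#'
#' @param vt a [variant_table] whose coordinates refer to `genome`.
#' @param genome a [Biostrings::DNAStringSet] for the same assembly.
#' @return the normalized [variant_table].
#' @export
normalize_variants <- function(vt, genome) {
  n <- n_variants(vt)
  for (i in seq_len(n)) {
    nv <- normalize_one(vt$chrom[i], vt$pos[i], vt$ref[i], vt$alt[i], genome)
    vt$pos[i] <- nv$pos; vt$ref[i] <- nv$ref; vt$alt[i] <- nv$alt
  }
  vt
}

#' @noRd
normalize_one <- function(chrom, pos, ref, alt, genome) {
  found <- genome_seq(genome, chrom, pos, pos + nchar(ref) - 1L)
  if (found != ref) {
    la_stop(sprintf("reference mismatch at %s:%d: expected '%s', genome has '%s'",
                    chrom, pos, ref, found), "liftann_ref_mismatch",
            chrom = chrom, pos = pos, expected = ref, found = found)
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
      b <- r[length(r)]
      r <- r[-length(r)]; a <- a[-length(a)]
      if (length(r) == 0 || length(a) == 0) {
        if (pos == 1L) {  # cannot shift past the contig start; undo last trim
          r <- c(r, b); a <- c(a, b)
          break
        }
        pos <- pos - 1L
        base <- genome_seq(genome, chrom, pos, pos)
        r <- c(base, r); a <- c(base, a)
      }
    } else if (length(r) >= 2 && length(a) >= 2 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1L
    } else break
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}
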