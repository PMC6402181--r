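#' Consequence categories and their impact tiers
#'
#' Fixed category-to-impact table used across the package, mirroring the
#' conventional HIGH/MODERATE/LOW/MODIFIER severity scheme. The element
#' order doubles as the tie-break order when several categories share an
#' impact tier.
#' @export
CONSEQUENCE_IMPACT <- c(
  frameshift = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
  start_lost = "HIGH",
  inframe_insertion = "MODERATE", inframe_deletion = "MODERATE",
  missense = "MODERATE",
  synonymous = "LOW", splice_region = "LOW",
  intron = "MODIFIER", utr = "MODIFIER", upstream_gene = "MODIFIER",
  downstream_gene = "MODIFIER", intergenic = "MODIFIER",
  non_coding_gene = "MODIFIER")

#' Impact tier of a consequence category
#' @param category one of the names of [CONSEQUENCE_IMPACT].
#' @return "HIGH", "MODERATE", "LOW" or "MODIFIER".
#' @export
impact_tier <- function(category) {
  out <- unname(CONSEQUENCE_IMPACT[category])
  if (anyNA(out)) {
    stop(sprintf("unknown consequence category '%s'",
                 category[which(is.na(out))[1]]))
  }
  out
}

#' @noRd
severity_rank <- function(category) match(category, names(CONSEQUENCE_IMPACT))

# distance (bp) defining the up/downstream windows around gene bounds
GENE_FLANK_BP <- 5000L

#' Build overlap indexes over a set of gene models
#'
#' @param genes list from [read_gene_models()].
#' @param splice_width intronic bases adjacent to each exon/intron boundary
#'   classified as splice region (0 disables).
#' @return list of GRanges indexes used by [classify_region()] and
#'   [call_consequences()].
#' @export
build_gene_index <- function(genes, splice_width = 3L) {
  gr0 <- function() GenomicRanges::GRanges()
  mk <- function(chrom, start, end, ...) {
    keep <- start <= end
    GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(start[keep], end[keep]),
                           ...)
  }
  cds_c <- character(); cds_s <- integer(); cds_e <- integer()
  cds_gene <- character(); cds_tx <- character()
  ex_c <- character(); ex_s <- integer(); ex_e <- integer(); ex_gene <- character()
  sp_c <- character(); sp_s <- integer(); sp_e <- integer(); sp_gene <- character()
  for (g in genes) {
    for (tx in g$transcripts) {
      if (nrow(tx$cds) > 0) {
        cds_c <- c(cds_c, rep(g$chrom, nrow(tx$cds)))
        cds_s <- c(cds_s, tx$cds$start); cds_e <- c(cds_e, tx$cds$end)
        cds_gene <- c(cds_gene, rep(g$gene_id, nrow(tx$cds)))
        cds_tx <- c(cds_tx, rep(tx$transcript_id, nrow(tx$cds)))
      }
      if (!g$non_coding && nrow(tx$exons) > 0) {
        ex_c <- c(ex_c, rep(g$chrom, nrow(tx$exons)))
        ex_s <- c(ex_s, tx$exons$start); ex_e <- c(ex_e, tx$exons$end)
        ex_gene <- c(ex_gene, rep(g$gene_id, nrow(tx$exons)))
      }
      if (splice_width > 0 && nrow(tx$exons) > 1) {
        ex <- tx$exons[order(tx$exons$start), ]
        for (j in seq_len(nrow(ex) - 1)) {
          i_start <- ex$end[j] + 1L; i_end <- ex$start[j + 1] - 1L
          if (i_start > i_end) next
          w <- min(splice_width, i_end - i_start + 1L)
          sp_c <- c(sp_c, g$chrom, g$chrom)
          sp_s <- c(sp_s, i_start, i_end - w + 1L)
          sp_e <- c(sp_e, i_start + w - 1L, i_end)
          sp_gene <- c(sp_gene, g$gene_id, g$gene_id)
        }
      }
    }
  }
  coding <- !vapply(genes, `[[`, TRUE, "non_coding")
  gchrom <- vapply(genes, `[[`, "", "chrom")
  gstart <- vapply(genes, function(g) as.integer(g$start), 1L)
  gend <- vapply(genes, function(g) as.integer(g$end), 1L)
  gstrand <- vapply(genes, `[[`, "", "strand")
  gid <- vapply(genes, `[[`, "", "gene_id")
  up_s <- ifelse(gstrand == "-", gend + 1L, pmax(1L, gstart - GENE_FLANK_BP))
  up_e <- ifelse(gstrand == "-", gend + GENE_FLANK_BP, gstart - 1L)
  dn_s <- ifelse(gstrand == "-", pmax(1L, gstart - GENE_FLANK_BP), gend + 1L)
  dn_e <- ifelse(gstrand == "-", gstart - 1L, gend + GENE_FLANK_BP)
  list(
    genes = genes,
    cds = if (length(cds_c)) mk(cds_c, cds_s, cds_e, gene = cds_gene,
                                tx = cds_tx) else gr0(),
    exon = if (length(ex_c)) mk(ex_c, ex_s, ex_e, gene = ex_gene) else gr0(),
    splice = if (length(sp_c)) mk(sp_c, sp_s, sp_e, gene = sp_gene) else gr0(),
    gene_coding = mk(gchrom[coding], gstart[coding], gend[coding],
                     gene = gid[coding]),
    gene_noncoding = mk(gchrom[!coding], gstart[!coding], gend[!coding],
                        gene = gid[!coding]),
    upstream = mk(gchrom, up_s, up_e, gene = gid),
    downstream = mk(gchrom, dn_s, dn_e, gene = gid))
}

#' Classify the gene-region context of each variant
#'
#' Assigns exactly one region category per variant: inside CDS is `coding`
#' (resolved into a specific consequence by [call_consequences()]); in an
#' exon but not CDS is `utr`; within `splice_width` intronic bases of an
#' exon/intron boundary is `splice_region`; otherwise inside a coding gene is
#' `intron`; inside a gene without CDS is `non_coding_gene`; within 5000 bp
#' of a gene's transcription start (strand-aware) is `upstream_gene`, within
#' 5000 bp of its end `downstream_gene`; everything else `intergenic`. A
#' variant hitting several genes takes the most severe category under the
#' precedence just listed.
#'
#' @param vt source-coordinate [variant_table].
#' @param genes gene models from [read_gene_models()], or a prebuilt index
#'   from [build_gene_index()].
#' @return list with `category` and `gene` (character vectors per variant).
#' @export
classify_region <- function(vt, genes) {
  gx <- if (is.list(genes) && !is.null(genes$cds)) genes else build_gene_index(genes)
  n <- n_variants(vt)
  q <- GenomicRanges::GRanges(
    vt$chrom, IRanges::IRanges(vt$pos, vt$pos + nchar(vt$ref) - 1L))
  category <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  layers <- list(
    list(gr = gx$downstream, cat = "downstream_gene"),
    list(gr = gx$upstream, cat = "upstream_gene"),
    list(gr = gx$gene_noncoding, cat = "non_coding_gene"),
    list(gr = gx$gene_coding, cat = "intron"),
    list(gr = gx$splice, cat = "splice_region"),
    list(gr = gx$exon, cat = "utr"),
    list(gr = gx$cds, cat = "coding"))
  for (layer in layers) {  # least to most severe; later layers overwrite
    if (length(layer$gr) == 0) next
    ov <- GenomicRanges::findOverlaps(q, layer$gr)
    qh <- S4Vectors::queryHits(ov)
    if (!length(qh)) next
    category[qh] <- layer$cat
    gene[qh] <- S4Vectors::mcols(layer$gr)$gene[S4Vectors::subjectHits(ov)]
  }
  list(category = category, gene = gene)
}

#' Build the coding-sequence context of a transcript
#'
#' Concatenates the CDS intervals in ascending genomic order, reverse
#' complementing for minus-strand transcripts, and records the genomic
#' coordinate map. An incomplete CDS (length not divisible by 3) keeps its
#' usable frame; the trailing partial codon is ignored.
#' @noRd
make_tx_context <- function(tx, genome, chrom) {
  cds <- tx$cds[order(tx$cds$start), , drop = FALSE]
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  fwd <- paste(vapply(seq_len(nrow(cds)), function(j)
    genome_seq(genome, chrom, cds$start[j], cds$end[j]), character(1)),
    collapse = "")
  total <- nchar(fwd)
  seq <- if (tx$strand == "-") revcomp(fwd) else fwd
  # genomic position -> 1-based forward-CDS offset
  offsets <- cumsum(c(0L, cds$end - cds$start + 1L))
  list(tx = tx, chrom = chrom, cds = cds, seq = seq, total = total,
       usable = (total %/% 3L) * 3L, offsets = offsets,
       complete = total %% 3L == 0L)
}

#' @noRd
cds_coord <- function(ctx, gpos) {
  for (j in seq_len(nrow(ctx$cds))) {
    if (gpos >= ctx$cds$start[j] && gpos <= ctx$cds$end[j]) {
      fwd <- ctx$offsets[j] + (gpos - ctx$cds$start[j]) + 1L
      return(as.integer(if (ctx$tx$strand == "-") ctx$total - fwd + 1L
                        else fwd))
    }
  }
  NA_integer_
}

#' @noRd
codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' @noRd
aa3 <- function(codon) {
  aa <- codon_aa(codon)
  if (aa == "*") "Ter" else unname(Biostrings::AMINO_ACID_CODE[aa])
}

#' Coding consequence of one variant on one transcript
#'
#' For an SNV the affected codon is recomputed under the standard genetic
#' code: a gained stop is `stop_gained`, a lost stop `stop_lost`, a changed
#' initiator codon `start_lost`, an amino-acid change `missense`, anything
#' else `synonymous`. An indel whose length change is not a multiple of 3 is
#' a `frameshift`, otherwise `inframe_insertion`/`inframe_deletion`.
#' Equal-length multi-base substitutions are resolved codon-by-codon.
#'
#' @param v list with `chrom`, `pos`, `ref`, `alt` (normalized, source
#'   coordinates; ref span must intersect the transcript's CDS).
#' @param tx a transcript from [read_gene_models()].
#' @param genome source-assembly genome.
#' @return list with `category`, `impact`, `transcript_id`, `hgvs_like`
#'   (NA for indels), `cds_complete`.
#' @export
coding_consequence <- function(v, tx, genome) {
  ctx <- make_tx_context(tx, genome, v$chrom)
  coding_consequence_ctx(v, ctx)
}

#' @noRd
coding_consequence_ctx <- function(v, ctx) {
  found <- genome_seq_ctx_check(ctx, v)
  lr <- nchar(v$ref); la <- nchar(v$alt)
  if (lr != la) {
    delta <- la - lr
    category <- if (delta %% 3L != 0L) "frameshift"
                else if (delta > 0L) "inframe_insertion" else "inframe_deletion"
    return(list(category = category, impact = impact_tier(category),
                transcript_id = ctx$tx$transcript_id, hgvs_like = NA_character_,
                cds_complete = ctx$complete))
  }
  # equal length: per-base codon comparison over the bases that lie in CDS
  minus <- ctx$tx$strand == "-"
  ref_c <- if (minus) revcomp(v$ref) else v$ref
  alt_c <- if (minus) revcomp(v$alt) else v$alt
  gpos_all <- v$pos:(v$pos + lr - 1L)
  cpos_all <- vapply(gpos_all, function(g) cds_coord(ctx, g), integer(1))
  if (minus) { gpos_all <- rev(gpos_all); cpos_all <- rev(cpos_all) }
  mut <- strsplit(ctx$seq, "")[[1]]
  alt_bases <- strsplit(alt_c, "")[[1]]
  touched <- integer()
  for (j in seq_len(lr)) {
    cp <- cpos_all[j]
    if (is.na(cp) || cp > ctx$usable) next
    mut[cp] <- alt_bases[j]
    touched <- c(touched, (cp - 1L) %/% 3L + 1L)
  }
  touched <- sort(unique(touched))
  touched <- touched[touched * 3L <= ctx$usable]
  if (!length(touched)) {
    # entire ref span lies in the unusable trailing partial codon
    return(list(category = "synonymous", impact = impact_tier("synonymous"),
                transcript_id = ctx$tx$transcript_id, hgvs_like = NA_character_,
                cds_complete = ctx$complete))
  }
  orig <- strsplit(ctx$seq, "")[[1]]
  cat_found <- "synonymous"; hgvs <- NA_character_
  first_change <- NULL
  for (ci in touched) {
    b <- (ci - 1L) * 3L
    rc <- paste(orig[(b + 1):(b + 3)], collapse = "")
    ac <- paste(mut[(b + 1):(b + 3)], collapse = "")
    if (rc == ac) next
    raa <- codon_aa(rc)
    aaa <- codon_aa(ac)
    this <- if (ci == 1L && rc == "ATG" && ac != "ATG") "start_lost"
            else if (raa != "*" && aaa == "*") "stop_gained"
            else if (raa == "*" && aaa != "*") "stop_lost"
            else if (raa != aaa) "missense"
            else "synonymous"
    if (is.null(first_change) && raa != aaa) first_change <- c(ci, rc, ac)
    if (severity_rank(this) < severity_rank(cat_found)) cat_found <- this
    if (is.na(hgvs)) {
      hgvs <- if (raa == aaa) sprintf("p.%s%d=", aa3(rc), ci)
              else sprintf("p.%s%d%s", aa3(rc), ci, aa3(ac))
    }
  }
  list(category = cat_found, impact = impact_tier(cat_found),
       transcript_id = ctx$tx$transcript_id, hgvs_like = hgvs,
       cds_complete = ctx$complete)
}

#' @noRd
genome_seq_ctx_check <- function(ctx, v) invisible(NULL)

#' Call the most severe consequence per variant
#'
#' Combines [classify_region()] with [coding_consequence()]: variants inside
#' CDS get their coding consequence on every overlapping transcript and keep
#' the most severe call (severity = impact tier, ties broken by the category
#' order of [CONSEQUENCE_IMPACT]); everything else keeps its region category.
#' Writes `MG_CSQ`, `MG_IMPACT`, `MG_GENE`, `MG_TX`, optional `MG_HGVS`, and
#' the `MG_CDS_INCOMPLETE` flag when the chosen transcript's CDS length is
#' not a multiple of 3.
#'
#' @param vt normalized source-coordinate [variant_table].
#' @param genes gene models from [read_gene_models()].
#' @param genome source-assembly genome.
#' @param splice_width intronic splice-region width in bp (default 3).
#' @return the annotated [variant_table].
#' @export
call_consequences <- function(vt, genes, genome, splice_width = 3L) {
  gx <- build_gene_index(genes, splice_width)
  reg <- classify_region(vt, gx)
  ctx_cache <- new.env(parent = emptyenv())
  q <- GenomicRanges::GRanges(
    vt$chrom, IRanges::IRanges(vt$pos, vt$pos + nchar(vt$ref) - 1L))
  ov <- GenomicRanges::findOverlaps(q, gx$cds)
  cds_hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  for (i in seq_len(n_variants(vt))) {
    category <- reg$category[i]
    gene_id <- reg$gene[i]
    tx_id <- NA_character_; hgvs <- NA_character_; incomplete <- FALSE
    if (category == "coding") {
      hits <- cds_hits[[as.character(i)]]
      pairs <- unique(data.frame(
        gene = S4Vectors::mcols(gx$cds)$gene[hits],
        tx = S4Vectors::mcols(gx$cds)$tx[hits], stringsAsFactors = FALSE))
      best <- NULL
      for (r in seq_len(nrow(pairs))) {
        g <- gx$genes[[pairs$gene[r]]]
        tx <- g$transcripts[[pairs$tx[r]]]
        ck <- paste(vt$chrom[i], pairs$tx[r])
        if (is.null(ctx_cache[[ck]])) {
          ctx_cache[[ck]] <- make_tx_context(tx, genome, vt$chrom[i])
        }
        cc <- coding_consequence_ctx(
          list(chrom = vt$chrom[i], pos = vt$pos[i], ref = vt$ref[i],
               alt = vt$alt[i]), ctx_cache[[ck]])
        if (is.null(best) ||
            severity_rank(cc$category) < severity_rank(best$category)) {
          best <- cc
          best$gene <- pairs$gene[r]
        }
      }
      category <- best$category
      gene_id <- best$gene
      tx_id <- best$transcript_id
      hgvs <- best$hgvs_like
      incomplete <- !best$cds_complete
    }
    vt$info[[i]][["MG_CSQ"]] <- category
    vt$info[[i]][["MG_IMPACT"]] <- impact_tier(category)
    if (!is.na(gene_id)) vt$info[[i]][["MG_GENE"]] <- gene_id
    if (!is.na(tx_id)) vt$info[[i]][["MG_TX"]] <- tx_id
    if (!is.na(hgvs)) vt$info[[i]][["MG_HGVS"]] <- hgvs
    if (incomplete) vt$info[[i]][["MG_CDS_INCOMPLETE"]] <- TRUE
  }
  vt
}
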