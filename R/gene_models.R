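#' Read GFF3 gene models
#'
#' Assembles the gene / mRNA / exon / CDS hierarchy of a GFF3 file into a
#' list of gene models. Coordinates stay 1-based inclusive as in the file;
#' exons are stored in ascending genomic order regardless of strand. Genes
#' without any CDS are retained and flagged non-coding. Transcripts whose
#' total CDS length is not divisible by 3 are flagged incomplete (consequence
#' calls then use the usable frame only).
#'
#' @param path path to a GFF3 file.
#' @return a list of gene models; each is a list with elements `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `non_coding`, and `transcripts` (each
#'   with `transcript_id`, `strand`, `exons`/`cds` data.frames of 1-based
#'   inclusive intervals, CDS with `phase`, and `cds_complete`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- lapply(md$Parent, as.character)

  gene_idx <- which(type == "gene")
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  tx_parent <- vapply(parents[tx_idx], function(p)
    if (length(p)) p[1] else NA_character_, character(1))
  tx_by_gene <- split(tx_idx, tx_parent)
  tx_ids <- ids[tx_idx]

  child_idx <- which(type %in% c("exon", "CDS"))
  for (ci in child_idx) {
    p <- parents[[ci]]
    if (type[ci] == "CDS" && (length(p) == 0 || !p[1] %in% tx_ids)) {
      la_stop(sprintf("CDS feature '%s' has no parent transcript",
                      ids[ci] %||% "<unnamed>"), "liftann_gff_error")
    }
  }
  child_parent <- vapply(parents[child_idx], function(p)
    if (length(p)) p[1] else NA_character_, character(1))
  children_by_tx <- split(child_idx, child_parent)

  genes <- vector("list", length(gene_idx))
  for (g in seq_along(gene_idx)) {
    gi <- gene_idx[g]
    gid <- ids[gi]
    txs <- list()
    for (ti in tx_by_gene[[gid]] %||% integer()) {
      tid <- ids[ti]
      kids <- children_by_tx[[tid]] %||% integer()
      ex <- kids[type[kids] == "exon"]
      cd <- kids[type[kids] == "CDS"]
      exons <- data.frame(start = BiocGenerics::start(gr)[ex],
                          end = BiocGenerics::end(gr)[ex])
      exons <- exons[order(exons$start), , drop = FALSE]
      cds <- data.frame(start = BiocGenerics::start(gr)[cd],
                        end = BiocGenerics::end(gr)[cd],
                        phase = as.integer(as.character(md$phase[cd])))
      cds <- cds[order(cds$start), , drop = FALSE]
      cds_len <- sum(cds$end - cds$start + 1L)
      txs[[tid]] <- list(
        transcript_id = tid,
        strand = as.character(BiocGenerics::strand(gr))[ti],
        exons = exons, cds = cds,
        cds_complete = nrow(cds) > 0 && cds_len %% 3L == 0L)
    }
    genes[[g]] <- list(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = as.character(BiocGenerics::strand(gr))[gi],
      start = BiocGenerics::start(gr)[gi],
      end = BiocGenerics::end(gr)[gi],
      non_coding = all(vapply(txs, function(t) nrow(t$cds) == 0, logical(1))) ||
        length(txs) == 0,
      transcripts = txs)
  }
  names(genes) <- ids[gene_idx]
  genes
}
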