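# a compact two-gene model set for region classification
region_genes <- function() {
  list(
    gp = list(gene_id = "gp", chrom = "chr1", strand = "+", start = 20000L,
              end = 30000L, non_coding = FALSE,
              transcripts = list(t1 = list(
                transcript_id = "t1", strand = "+",
                exons = data.frame(start = c(20000L, 25000L),
                                   end = c(21000L, 26000L)),
                cds = data.frame(start = 20500L, end = 20999L, phase = 0L),
                cds_complete = FALSE))),
    gm = list(gene_id = "gm", chrom = "chr1", strand = "-", start = 50000L,
              end = 60000L, non_coding = FALSE,
              transcripts = list(t2 = list(
                transcript_id = "t2", strand = "-",
                exons = data.frame(start = 50000L, end = 60000L),
                cds = data.frame(start = 55000L, end = 55299L, phase = 0L),
                cds_complete = TRUE))),
    nc = list(gene_id = "nc", chrom = "chr1", strand = "+", start = 80000L,
              end = 81000L, non_coding = TRUE,
              transcripts = list(t3 = list(
                transcript_id = "t3", strand = "+",
                exons = data.frame(start = 80000L, end = 81000L),
                cds = data.frame(start = integer(), end = integer(),
                                 phase = integer()),
                cds_complete = FALSE))))
}

test_that("region classification is strand-aware with 5000 bp flank windows", {
  genes <- region_genes()
  at <- function(pos) {
    vt <- variant_table("chr1", pos, "A", "G")
    classify_region(vt, genes)$category
  }
  expect_equal(at(30100L), "downstream_gene")  # 100 bp past plus-strand end
  expect_equal(at(35000L), "downstream_gene")  # boundary: exactly 5000 bp
  expect_equal(at(35001L), "intergenic")       # beyond the window
  expect_equal(at(15000L), "upstream_gene")    # exactly 5000 bp upstream
  expect_equal(at(14999L), "intergenic")       # 5001 bp upstream
  # minus-strand gene: 100 bp before its genomic start is DOWNstream
  expect_equal(at(49900L), "downstream_gene")
  expect_equal(at(60100L), "upstream_gene")
  expect_equal(at(20750L), "coding")
  expect_equal(at(20200L), "utr")       # exon, not CDS
  expect_equal(at(23000L), "intron")
  expect_equal(at(21002L), "splice_region")  # 2 bp into the intron
  expect_equal(at(80500L), "non_coding_gene")
})

test_that("region categories partition every variant exactly once", {
  genes <- region_genes()
  set.seed(3)
  vt <- variant_table(rep("chr1", 300), sample(1:100000, 300),
                      rep("A", 300), rep("G", 300))
  cat <- classify_region(vt, genes)$category
  expect_false(anyNA(cat))
  expect_equal(sum(table(cat)), 300L)
  expect_true(all(cat %in% names(CONSEQUENCE_IMPACT)
                  | cat %in% c("coding")))
})

test_that("coding consequences on a toy CDS match hand-derived calls", {
  # CDS ATG TGG TAA (Met-Trp-Stop) planted at 11..19
  s <- paste0("AAAAAAAAAA", "ATGTGGTAA", "AAAAAAAAAA")
  g <- toy_genome(chr1 = s)
  tx <- list(transcript_id = "t", strand = "+",
             exons = data.frame(start = 11L, end = 19L),
             cds = data.frame(start = 11L, end = 19L, phase = 0L),
             cds_complete = TRUE)
  cc <- function(pos, ref, alt)
    coding_consequence(list(chrom = "chr1", pos = pos, ref = ref, alt = alt),
                       tx, g)
  # TGG -> TGA: stop gained at codon 2
  out <- cc(16L, "G", "A")
  expect_equal(out$category, "stop_gained")
  expect_equal(out$hgvs_like, "p.Trp2Ter")
  expect_equal(out$impact, "HIGH")
  # TAA -> TAG: synonymous stop
  expect_equal(cc(19L, "A", "G")$category, "synonymous")
  # TAA -> CAA: stop lost
  expect_equal(cc(17L, "T", "C")$category, "stop_lost")
  # ATG -> CTG: start lost
  expect_equal(cc(11L, "A", "C")$category, "start_lost")
  # TGG -> AGG: missense Trp -> Arg
  out <- cc(14L, "T", "A")
  expect_equal(out$category, "missense")
  expect_equal(out$hgvs_like, "p.Trp2Arg")
  # 1 bp insertion inside codon 2: frameshift
  expect_equal(cc(14L, "T", "TA")$category, "frameshift")
  # 3 bp deletion removing exactly codon 2: inframe deletion
  expect_equal(cc(13L, "GTGG", "G")$category, "inframe_deletion")
  expect_equal(impact_tier("inframe_deletion"), "MODERATE")
})

test_that("every SNV in a toy CDS matches the translate-and-diff oracle", {
  toy <- make_toy_gene_genome(seed = 42, n_codons = 40)
  bases <- c("A", "C", "G", "T")
  cds_positions <- unlist(lapply(seq_len(nrow(toy$cds)), function(j)
    toy$cds$start[j]:toy$cds$end[j]))
  for (pos in cds_positions) {
    ref <- substr(toy$seq, pos, pos)
    for (alt in setdiff(bases, ref)) {
      got <- coding_consequence(
        list(chrom = "chr1", pos = pos, ref = ref, alt = alt),
        toy$tx, toy$genome)$category
      want <- oracle_csq(toy$seq, toy$cds, "+", pos, ref, alt)
      expect_equal(got, want,
                   label = sprintf("SNV %d %s>%s got %s", pos, ref, alt, got))
    }
  }
})

test_that("minus-strand transcripts call identically at mirrored positions", {
  toy <- make_toy_gene_genome(seed = 99, n_codons = 30)
  L <- nchar(toy$seq)
  seq2 <- rc(toy$seq)
  g2 <- toy_genome(chr1 = seq2)
  cds2 <- data.frame(start = rev(L - toy$cds$end + 1L),
                     end = rev(L - toy$cds$start + 1L),
                     phase = toy$cds$phase)
  tx2 <- list(transcript_id = "t2", strand = "-",
              exons = cds2[, c("start", "end")], cds = cds2,
              cds_complete = TRUE)
  bases <- c("A", "C", "G", "T")
  cds_positions <- unlist(lapply(seq_len(nrow(toy$cds)), function(j)
    toy$cds$start[j]:toy$cds$end[j]))
  for (pos in cds_positions[seq(1, length(cds_positions), by = 3)]) {
    ref <- substr(toy$seq, pos, pos)
    for (alt in setdiff(bases, ref)) {
      plus <- coding_consequence(
        list(chrom = "chr1", pos = pos, ref = ref, alt = alt),
        toy$tx, toy$genome)$category
      minus <- coding_consequence(
        list(chrom = "chr1", pos = L - pos + 1L, ref = rc(ref),
             alt = rc(alt)), tx2, g2)$category
      expect_equal(minus, plus,
                   label = sprintf("mirrored SNV at %d (%s>%s)", pos, ref, alt))
    }
  }
})

test_that("impact tiers follow the fixed category table", {
  expect_equal(impact_tier("frameshift"), "HIGH")
  expect_equal(impact_tier("stop_gained"), "HIGH")
  expect_equal(impact_tier("missense"), "MODERATE")
  expect_equal(impact_tier("synonymous"), "LOW")
  expect_equal(impact_tier("splice_region"), "LOW")
  expect_equal(impact_tier("intergenic"), "MODIFIER")
  expect_error(impact_tier("nonsense_mediated_decay"), "unknown")
})

test_that("call_consequences reports the most severe call with gene context", {
  toy <- make_toy_gene_genome(seed = 7, n_codons = 20)
  genes <- list(toygene = list(
    gene_id = "toygene", chrom = "chr1", strand = "+",
    start = min(toy$cds$start) - 50L, end = max(toy$cds$end) + 50L,
    non_coding = FALSE, transcripts = list(toy.t1 = toy$tx)))
  pos <- toy$cds$start[1] + 4L
  ref <- substr(toy$seq, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  b1 <- substr(toy$seq, 1, 1)
  vt <- variant_table(c("chr1", "chr1"), c(pos, 1L), c(ref, b1),
                      c(alt, setdiff(c("A", "C", "G", "T"), b1)[1]))
  out <- call_consequences(vt, genes, toy$genome)
  expect_equal(info_get(out, "MG_GENE")[1], "toygene")
  expect_equal(info_get(out, "MG_TX")[1], "toy.t1")
  # position 1 sits inside the 5000 bp upstream window of the toy gene
  expect_equal(info_get(out, "MG_CSQ")[2], "upstream_gene")
  expect_equal(info_get(out, "MG_IMPACT")[2], "MODIFIER")
  expect_equal(info_get(out, "MG_CSQ")[1],
               oracle_csq(toy$seq, toy$cds, "+", pos, ref, alt))
})
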