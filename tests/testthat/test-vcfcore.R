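test_that("a simple VCF line parses to the identical record", {
  path <- write_toy_vcf("chr1 100 . A G 50 PASS DP=7")
  vt <- read_vcf(path)
  expect_equal(n_variants(vt), 1L)
  expect_equal(vt$chrom, "chr1")
  expect_equal(vt$pos, 100L)
  expect_equal(vt$ref, "A")
  expect_equal(vt$alt, "G")
  expect_equal(vt$qual, 50)
  expect_equal(vt$filter, "PASS")
  expect_equal(vt$info[[1]]$DP, "7")
})

test_that("multi-allelic decomposition remaps all nine diploid index pairs", {
  pairs <- expand.grid(a1 = 0:2, a2 = 0:2)
  gts <- sprintf("%d/%d", pairs$a1, pairs$a2)
  samples <- sprintf("s%02d", seq_along(gts))
  path <- write_toy_vcf(
    paste(c("chr1 200 . A G,T . . .", "GT", gts), collapse = " "),
    samples = samples)
  vt <- read_vcf(path)
  expect_equal(n_variants(vt), 2L)
  expect_equal(vt$alt, c("G", "T"))
  # hand-enumerated remapping: kept alt -> 1, ref -> 0, other alt -> missing
  remap <- function(a, k) ifelse(a == 0, 0L, ifelse(a == k, 1L, NA_integer_))
  for (k in 1:2) {
    expect_equal(unname(vt$gt1[k, ]), remap(pairs$a1, k))
    expect_equal(unname(vt$gt2[k, ]), remap(pairs$a2, k))
  }
  # conservation: alt-index observations across decomposed records equal the
  # per-allele counts of the joint record
  joint <- c(pairs$a1, pairs$a2)
  for (k in 1:2) {
    expect_equal(sum(c(vt$gt1[k, ], vt$gt2[k, ]) == 1L, na.rm = TRUE),
                 sum(joint == k))
  }
})

test_that("symbolic and N-containing alternates are skipped and counted", {
  path <- write_toy_vcf(c("chr1 100 . A <DEL> . . .",
                          "chr1 200 . A G . . .",
                          "chr1 300 . A GN,T . . ."))
  expect_message(vt <- read_vcf(path), "skipped 2")
  expect_equal(attr(vt, "skipped"), 2L)
  expect_equal(vt$pos, c(200L, 300L))
  expect_equal(vt$alt, c("G", "T"))
})

test_that("malformed headers and non-monotonic positions are parse errors", {
  bad <- write_lines_tmp(c("chr1\t100\t.\tA\tG\t.\t.\t."), ".vcf")
  expect_error(read_vcf(bad), "fileformat", class = "liftann_parse_error")
  path <- write_toy_vcf(c("chr1 300 . A G . . .", "chr1 100 . T C . . ."))
  expect_error(read_vcf(path), "line", class = "liftann_parse_error")
})

test_that("write/read roundtrip is a fixpoint on sorted, normalized records", {
  set.seed(9)
  n <- 50
  pos <- sort(sample(1000:9000, n))
  refs <- sample(c("A", "C", "G", "T"), n, TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  vt <- variant_table(
    chrom = rep("chr1", n), pos = pos,
    ref = refs,
    alt = alts, id = sprintf("v%02d", 1:n),
    qual = sample(c(NA, 10, 55.5), n, TRUE),
    filter = sample(c(NA, "PASS", "lowq"), n, TRUE),
    gt1 = matrix(sample(c(NA, 0L, 1L), 2 * n, TRUE), n, 2),
    gt2 = matrix(sample(c(NA, 0L, 1L), 2 * n, TRUE), n, 2),
    samples = c("s1", "s2"), assembly = "toy")
  vt <- info_set(vt, "MG_TAG", sprintf("x%d", seq_len(n)))
  vt <- info_set(vt, "MG_FLAG", TRUE, which = seq(1, n, by = 5))
  p1 <- tempfile(fileext = ".vcf")
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(vt, p1, header_meta = list(contigs = c(chr1 = 10000L)))
  back <- read_vcf(p1)
  expect_equal(back$pos, vt$pos)
  expect_equal(back$ref, vt$ref)
  expect_equal(back$alt, vt$alt)
  expect_equal(back$qual, vt$qual)
  expect_equal(back$gt1, vt$gt1, ignore_attr = TRUE)
  expect_equal(back$gt2, vt$gt2, ignore_attr = TRUE)
  write_vcf(back, p2, header_meta = list(contigs = c(chr1 = 10000L)))
  expect_identical(readLines(p1), readLines(p2))
})

test_that("unsorted input to write_vcf names the offending pair", {
  vt <- variant_table(c("chr1", "chr1"), c(200L, 100L), c("A", "C"),
                      c("G", "T"))
  expect_error(write_vcf(vt, tempfile(fileext = ".vcf")),
               "chr1:200 followed by chr1:100",
               class = "liftann_order_error")
  expect_error(vt_sort(vt, contig_order = "chrX"),
               class = "liftann_order_error")
  expect_equal(vt_sort(vt)$pos, c(100L, 200L))
})

test_that("header-only VCFs round-trip and declare all INFO keys used", {
  empty <- variant_table(character(), integer(), character(), character())
  p <- tempfile(fileext = ".vcf")
  write_vcf(empty, p, header_meta = list(contigs = c(chr1 = 100L)))
  expect_equal(n_variants(read_vcf(p)), 0L)
  one <- variant_table("chr1", 10L, "A", "G",
                       info = list(list(K1 = "a", K2 = "b", K3 = TRUE)))
  write_vcf(one, p, header_meta = list(contigs = c(chr1 = 100L)))
  lines <- readLines(p)
  expect_length(grep("^##INFO", lines), 3L)
  expect_true(any(grepl("ID=K3,Number=0,Type=Flag", lines)))
})

test_that("normalization trims shared bases and is idempotent", {
  g <- toy_genome(chr1 = "GGGGGGGGGATCGGGGGG")
  # shared suffix: AT>GT at the A (pos 10)
  nv <- liftann:::normalize_one("chr1", 10L, "AT", "GT", g)
  expect_equal(nv, list(pos = 10L, ref = "A", alt = "G"))
  # SNV unchanged, idempotent
  vt <- variant_table("chr1", 10L, "A", "C", assembly = "toy")
  n1 <- normalize_variants(vt, g)
  n2 <- normalize_variants(n1, g)
  expect_equal(n1$pos, 10L)
  expect_identical(n1[seq_len(1)]$ref, n2$ref)
  expect_identical(n1$pos, n2$pos)
})

test_that("indels left-align through repeats, verified by brute force", {
  g <- toy_genome(chr1 = "GGGCACACACATGG")
  s <- as.character(g[[1]])
  apply_del <- function(pos, ref, alt) {
    paste0(substr(s, 1, pos - 1), alt, substr(s, pos + nchar(ref), nchar(s)))
  }
  # rightmost placement of a 2 bp CA deletion
  nv <- liftann:::normalize_one("chr1", 9L, "ACA", "A", g)
  edited <- apply_del(9, "ACA", "A")
  # brute force: every anchored 2 bp deletion placement giving the same
  # edited sequence; expected normalized position is the leftmost
  placements <- Filter(function(p) {
    apply_del(p, substr(s, p, p + 2), substr(s, p, p)) == edited
  }, 1:(nchar(s) - 2))
  expect_equal(nv$pos, min(unlist(placements)))
  expect_equal(apply_del(nv$pos, nv$ref, nv$alt), edited)
  # idempotence on the result
  expect_equal(liftann:::normalize_one("chr1", nv$pos, nv$ref, nv$alt, g), nv)
})

test_that("normalization preserves the mutated sequence on random toys", {
  set.seed(11)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "A", "C"), 60, TRUE), collapse = "")
    g <- toy_genome(chr1 = s)
    pos <- sample(5:40, 1)
    w <- sample(1:4, 1)
    if (runif(1) < 0.5) {
      ref <- substr(s, pos, pos + w); alt <- substr(s, pos, pos)
    } else {
      ref <- substr(s, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), w, TRUE),
                               collapse = ""))
    }
    if (ref == alt) next
    nv <- liftann:::normalize_one("chr1", pos, ref, alt, g)
    ed1 <- paste0(substr(s, 1, pos - 1), alt,
                  substr(s, pos + nchar(ref), nchar(s)))
    ed2 <- paste0(substr(s, 1, nv$pos - 1), nv$alt,
                  substr(s, nv$pos + nchar(nv$ref), nchar(s)))
    expect_identical(ed1, ed2)
  }
})

test_that("a reference/genome disagreement is a reference-integrity error", {
  g <- toy_genome(chr1 = "AAAA")
  err <- tryCatch(liftann:::normalize_one("chr1", 2L, "C", "G", g),
                  liftann_ref_mismatch = identity)
  expect_s3_class(err, "liftann_ref_mismatch")
  expect_equal(err$expected, "C")
  expect_equal(err$found, "A")
  expect_equal(err$pos, 2L)
})

test_that("GFF3 gene models assemble the gene/mRNA/exon/CDS hierarchy", {
  gff <- write_lines_tmp(c("##gff-version 3", gsub(" ", "\t", c(
    "chr1 t gene 100 500 . + . ID=g1",
    "chr1 t mRNA 100 500 . + . ID=t1;Parent=g1",
    "chr1 t exon 100 200 . + . Parent=t1",
    "chr1 t exon 300 400 . + . Parent=t1",
    "chr1 t CDS 150 154 . + 0 ID=c1;Parent=t1",
    "chr1 t CDS 300 306 . + 1 ID=c2;Parent=t1",
    "chr1 t gene 700 900 . - . ID=g2",
    "chr1 t mRNA 700 900 . - . ID=t2;Parent=g2",
    "chr1 t exon 800 850 . - . Parent=t2",
    "chr1 t exon 700 750 . - . Parent=t2"))), ".gff3")
  gm <- read_gene_models(gff)
  expect_named(gm, c("g1", "g2"))
  tx <- gm$g1$transcripts$t1
  expect_equal(nrow(tx$exons), 2L)
  # CDS lengths 5 + 7 = 12, divisible by 3
  expect_equal(sum(tx$cds$end - tx$cds$start + 1L), 12L)
  expect_true(tx$cds_complete)
  expect_false(gm$g1$non_coding)
  # minus-strand gene: exons in ascending genomic order, strand recorded
  t2 <- gm$g2$transcripts$t2
  expect_equal(t2$strand, "-")
  expect_equal(t2$exons$start, c(700L, 800L))
  expect_true(gm$g2$non_coding)
})

test_that("a CDS without a parent transcript is a structural error", {
  gff <- write_lines_tmp(c("##gff-version 3", gsub(" ", "\t", c(
    "chr1 t gene 100 500 . + . ID=g1",
    "chr1 t CDS 150 160 . + 0 ID=orphan;Parent=nosuch"))), ".gff3")
  expect_error(read_gene_models(gff), "orphan", class = "liftann_gff_error")
})
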