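# Small in-code fixtures and independent oracles shared across tests.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_genome <- function(...) Biostrings::DNAStringSet(c(...))

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

write_toy_vcf <- function(body, samples = character(),
                          contigs = c(chr1 = 10000L)) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                 as.integer(contigs)),
         '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
         paste(cols, collapse = "\t"))
  write_lines_tmp(c(h, gsub(" ", "\t", body)), ".vcf")
}

# chain description -> chain file lines (the tests build chains from plain
# block tables so the same tables can drive the independent per-base walk)
chain_lines <- function(ch) {
  n <- nrow(ch$blocks)
  c(sprintf("chain %d %s %d %s %d %d %s %d %s %d %d %s",
            ch$score %||0% 1000, ch$src_name, ch$src_size,
            ch$src_strand %||0% "+", ch$src_start, ch$src_end,
            ch$tgt_name, ch$tgt_size, ch$tgt_strand %||0% "+",
            ch$tgt_start, ch$tgt_end, ch$chain_id %||0% "1"),
    if (n > 1) sprintf("%d %d %d", ch$blocks$size[-n], ch$blocks$dt[-n],
                       ch$blocks$dq[-n]),
    as.character(ch$blocks$size[n]), "")
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

write_chain_tmp <- function(...) {
  write_lines_tmp(unlist(lapply(list(...), chain_lines)), ".chain")
}

# independent oracle: exhaustive per-base walk of a chain's blocks, one base
# at a time, yielding forward-strand source -> (tgt fwd pos, strand)
walk_chain <- function(ch) {
  out <- list()
  s <- ch$src_start; t <- ch$tgt_start
  for (b in seq_len(nrow(ch$blocks))) {
    for (k in seq_len(ch$blocks$size[b]) - 1L) {
      src_rel <- s + k
      src_fwd <- if ((ch$src_strand %||0% "+") == "+") src_rel
                 else ch$src_size - 1L - src_rel
      tgt_rel <- t + k
      tgt_fwd <- if ((ch$tgt_strand %||0% "+") == "+") tgt_rel
                 else ch$tgt_size - 1L - tgt_rel
      out[[as.character(src_fwd)]] <- c(tgt_fwd, (ch$tgt_strand %||0% "+") == "-")
    }
    s <- s + ch$blocks$size[b] + ch$blocks$dt[b]
    t <- t + ch$blocks$size[b] + ch$blocks$dq[b]
  }
  out
}

# independent oracle: consequence of an equal-length substitution by direct
# genome mutation, CDS re-extraction and full translation diff
oracle_csq <- function(genome_str, cds_df, strand, pos, ref, alt) {
  stopifnot(substr(genome_str, pos, pos + nchar(ref) - 1L) == ref)
  mut <- paste0(substr(genome_str, 1, pos - 1L), alt,
                substr(genome_str, pos + nchar(ref), nchar(genome_str)))
  get_cds <- function(s) {
    fwd <- paste(vapply(seq_len(nrow(cds_df)), function(j)
      substr(s, cds_df$start[j], cds_df$end[j]), character(1)), collapse = "")
    if (strand == "-") rc(fwd) else fwd
  }
  tr <- function(s) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE)), "")[[1]]
  cds_ref <- get_cds(genome_str); cds_alt <- get_cds(mut)
  aa_ref <- tr(cds_ref); aa_alt <- tr(cds_alt)
  changed <- which(aa_ref != aa_alt)
  if (substr(cds_ref, 1, 3) == "ATG" && substr(cds_alt, 1, 3) != "ATG")
    return("start_lost")
  if (length(changed) == 0) return("synonymous")
  if (any(aa_alt[changed] == "*")) return("stop_gained")
  if (any(aa_ref[changed] == "*")) return("stop_lost")
  "missense"
}

# independent oracle: Mendelian trio consistency by explicit enumeration of
# both allele partitions
enum_trio <- function(s1, s2, d1, d2, c1, c2) {
  ((c1 == s1 || c1 == s2) && (c2 == d1 || c2 == d2)) ||
    ((c2 == s1 || c2 == s2) && (c1 == d1 || c1 == d2))
}

# a small single-gene toy genome for consequence tests: one plus-strand gene
# with a two-exon CDS planted into a random background
make_toy_gene_genome <- function(seed = 42L, n_codons = 40L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  bg <- function(n) paste(sample(bases, n, TRUE), collapse = "")
  safe <- setdiff(as.vector(outer(as.vector(outer(bases, bases, paste0)),
                                  bases, paste0)),
                  c("TAA", "TAG", "TGA", "ATG"))
  coding <- paste0("ATG", paste(sample(safe, n_codons - 2, TRUE),
                                collapse = ""), "TAA")
  len1 <- (n_codons * 3) %/% 2
  cds <- data.frame(start = c(101L, 301L),
                    end = c(100L + len1, 300L + n_codons * 3L - len1),
                    phase = c(0L, (3L - len1 %% 3L) %% 3L))
  g <- paste0(bg(100), substr(coding, 1, len1), bg(200 - len1),
              substr(coding, len1 + 1, n_codons * 3), bg(100))
  tx <- list(transcript_id = "toy.t1", strand = "+",
             exons = data.frame(start = cds$start, end = cds$end),
             cds = cds, cds_complete = TRUE)
  list(genome = toy_genome(chr1 = g), seq = g, cds = cds, tx = tx,
       coding = coding)
}
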