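# Deterministic synthetic fixture generator. A fixture bundle contains a
# source genome, a target genome derived from it by an explicit edit script
# (deletions, insertions, inversions), a chain file encoding exactly that
# script, a multi-sample cohort VCF with genotypes drawn from a frequency
# law over a founders-plus-trios pedigree, planted gene models, clinical /
# score / interval annotation tables, and a machine-readable truth file. The
# truth bookkeeping (expected lift status, matches, consequences, Mendelian
# verdicts) is derived from the edit script and planted tables by direct
# arithmetic, independent of the chain parser and liftover engine it is used
# to test.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

#' @noRd
rand_cds <- function(n_codons) {
  all_codons <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
    c("A", "C", "G", "T"), paste0)), c("A", "C", "G", "T"), paste0))
  safe <- setdiff(all_codons, c(STOP_CODONS, "ATG"))
  paste0("ATG", paste(sample(safe, n_codons - 2, TRUE), collapse = ""), "TAA")
}

#' Specification of a synthetic fixture bundle
#'
#' The defaults emulate a small outbred cohort: 24 animals (16 founders, 8
#' trio offspring), 1000 biallelic variants with 12% indels (the indel share
#' reported for real short-variant catalogs), site frequencies drawn from a
#' neutral-like 1/f law, 2% missing genotypes, and an edit script containing
#' deletions, an insertion and an inversion so that every lift status occurs.
#' A second contig carries no chain at all.
#'
#' @param seed integer seed; the bundle is a pure function of the spec.
#' @param contig_len length of the main source contig (bp).
#' @param contig2_len length of the chain-less source contig (bp).
#' @param edits edit script for the main contig: list of
#'   `list(type = "deletion", start =, len =)`,
#'   `list(type = "insertion", at =, len =)` (target bases added after source
#'   position `at`), `list(type = "inversion", start =, len =)`. 1-based.
#' @param n_variants total variants; `frac_contig2` of them go to contig 2.
#' @param frac_contig2 fraction of variants on the chain-less contig.
#' @param indel_frac fraction of variants that are short indels (1-4 bp).
#' @param n_founders,n_children pedigree shape; children are offspring of
#'   founder pairs (2k-1, 2k).
#' @param freq_law "neutral" (density proportional to 1/f on (0.025, 0.95)),
#'   "uniform", or "grid" (multiples of 0.05).
#' @param genotype_mode "random" (binomial founder draws) or "deterministic"
#'   (founder allele counts fixed to `round(2 * n_founders * f)`).
#' @param missing_rate per-genotype missingness rate.
#' @param n_swap,n_mismatch lifted SNVs whose target base is edited so they
#'   come back as ALLELE_SWAP / REF_MISMATCH.
#' @param n_clinical,n_clinical_decoy clinical rows matching planted variants
#'   and same-position different-allele decoys.
#' @param n_scores position-keyed score rows at lifted variant positions.
#' @param n_mendel_violations planted transmission violations.
#' @param damaging_threshold score cutoff written into the bundle config.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, contig_len = 20000L, contig2_len = 5000L,
                         edits = list(
                           list(type = "deletion", start = 3001L, len = 200L),
                           list(type = "insertion", at = 6000L, len = 150L),
                           list(type = "inversion", start = 9001L, len = 600L),
                           list(type = "deletion", start = 14001L, len = 120L)),
                         n_variants = 1000L, frac_contig2 = 0.1,
                         indel_frac = 0.12,
                         n_founders = 16L, n_children = 8L,
                         freq_law = "neutral", genotype_mode = "random",
                         missing_rate = 0.02,
                         n_swap = 8L, n_mismatch = 8L,
                         n_clinical = 30L, n_clinical_decoy = 15L,
                         n_scores = 40L, n_mendel_violations = 5L,
                         damaging_threshold = 0.85) {
  spec <- as.list(environment())
  for (e in spec$edits) {
    hi <- if (e$type == "insertion") e$at else e$start + e$len - 1L
    if (hi > contig_len || (e$type != "insertion" && e$start < 1L)) {
      la_stop("edit script out of bounds for contig length", "liftann_spec_error")
    }
  }
  structure(spec, class = "fixture_spec")
}

#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# ---- planted gene models (fixed structure; sequence is seeded) -------------

#' @noRd
fixture_genes_def <- function(contig_len = .Machine$integer.max) {
  defs <- list(
    gplus = list(gene_id = "gplus", chrom = "mchr1", strand = "+",
                 start = 500L, end = 1500L,
                 exons = data.frame(start = c(600L, 1000L), end = c(899L, 1199L)),
                 cds = data.frame(start = c(700L, 1000L), end = c(899L, 1099L),
                                  phase = c(0L, 1L))),
    gminus = list(gene_id = "gminus", chrom = "mchr1", strand = "-",
                  start = 16000L, end = 17500L,
                  exons = data.frame(start = c(16100L, 16600L),
                                     end = c(16399L, 16899L)),
                  cds = data.frame(start = c(16151L, 16600L),
                                   end = c(16399L, 16749L),
                                   phase = c(0L, 0L))),
    gnc = list(gene_id = "gnc", chrom = "mchr1", strand = "+",
               start = 18200L, end = 18500L,
               exons = data.frame(start = 18250L, end = 18450L),
               cds = data.frame(start = integer(), end = integer(),
                                phase = integer())))
  # only genes that fit the main contig are planted
  Filter(function(g) g$end + 100L <= contig_len, defs)
}

#' @noRd
plant_genes <- function(seq1) {
  defs <- fixture_genes_def(nchar(seq1))
  s <- strsplit(seq1, "")[[1]]
  for (g in defs) {
    if (nrow(g$cds) == 0) next
    total <- sum(g$cds$end - g$cds$start + 1L)
    coding <- rand_cds(total %/% 3L)
    fwd <- if (g$strand == "-") revcomp(coding) else coding
    off <- 0L
    for (j in seq_len(nrow(g$cds))) {
      w <- g$cds$end[j] - g$cds$start[j] + 1L
      s[g$cds$start[j]:g$cds$end[j]] <-
        strsplit(substr(fwd, off + 1L, off + w), "")[[1]]
      off <- off + w
    }
  }
  paste(s, collapse = "")
}

#' @noRd
write_fixture_gff <- function(path, contig_len = .Machine$integer.max) {
  defs <- fixture_genes_def(contig_len)
  ln <- c("##gff-version 3")
  for (g in defs) {
    ln <- c(ln, sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$chrom, g$start, g$end, g$strand, g$gene_id))
    tid <- paste0(g$gene_id, ".t1")
    ln <- c(ln, sprintf("%s\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                        g$chrom, g$start, g$end, g$strand, tid, g$gene_id))
    for (j in seq_len(nrow(g$exons))) {
      ln <- c(ln, sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                          g$chrom, g$exons$start[j], g$exons$end[j],
                          g$strand, tid))
    }
    cds_rows <- seq_len(nrow(g$cds))
    if (g$strand == "-") cds_rows <- rev(cds_rows)
    for (j in cds_rows) {
      ln <- c(ln, sprintf("%s\tfixture\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                          g$chrom, g$cds$start[j], g$cds$end[j], g$strand,
                          g$cds$phase[j], g$gene_id, tid))
    }
  }
  writeLines(ln, path)
}

# ---- edit script machinery -------------------------------------------------

#' Apply an edit script to a source sequence
#'
#' Returns the target sequence, a segment map (source interval, forward
#' target start, strand) used for the generator's own coordinate arithmetic,
#' and the chain blocks encoding the script.
#' @noRd
apply_edit_script <- function(seq1, edits) {
  L <- nchar(seq1)
  ord <- order(vapply(edits, function(e)
    if (e$type == "insertion") e$at + 0.5 else as.numeric(e$start), 1))
  edits <- edits[ord]
  tgt <- character(); segs <- list()
  blocks <- data.frame(size = integer(), dt = integer(), dq = integer())
  inversions <- list()
  cur_src <- 1L   # next unconsumed source base (1-based)
  cur_tgt <- 1L   # next target base to be written (1-based)
  emit_match <- function(upto) {
    # copy source [cur_src, upto] to target
    if (upto >= cur_src) {
      w <- upto - cur_src + 1L
      tgt <<- c(tgt, substr(seq1, cur_src, upto))
      segs[[length(segs) + 1L]] <<- list(src_start = cur_src, src_end = upto,
                                         tgt_start = cur_tgt, strand = "+")
      cur_src <<- upto + 1L
      cur_tgt <<- cur_tgt + w
      w
    } else 0L
  }
  for (e in edits) {
    if (e$type == "deletion") {
      size <- emit_match(e$start - 1L)
      blocks <- rbind(blocks, data.frame(size = size, dt = e$len, dq = 0L))
      cur_src <- cur_src + e$len
    } else if (e$type == "insertion") {
      size <- emit_match(e$at)
      ins <- rand_dna(e$len)
      tgt <- c(tgt, ins)
      blocks <- rbind(blocks, data.frame(size = size, dt = 0L, dq = e$len))
      cur_tgt <- cur_tgt + e$len
    } else if (e$type == "inversion") {
      size <- emit_match(e$start - 1L)
      seg <- substr(seq1, e$start, e$start + e$len - 1L)
      tgt <- c(tgt, revcomp(seg))
      segs[[length(segs) + 1L]] <- list(src_start = e$start,
                                        src_end = e$start + e$len - 1L,
                                        tgt_start = cur_tgt, strand = "-")
      inversions[[length(inversions) + 1L]] <- list(
        src_start = e$start, src_end = e$start + e$len - 1L,
        tgt_start = cur_tgt)
      blocks <- rbind(blocks, data.frame(size = size, dt = e$len, dq = e$len))
      cur_src <- cur_src + e$len
      cur_tgt <- cur_tgt + e$len
    }
  }
  blocks <- rbind(blocks, data.frame(size = emit_match(L), dt = 0L, dq = 0L))
  list(target = paste(tgt, collapse = ""), segs = segs, blocks = blocks,
       inversions = inversions)
}

#' Map one 0-based source position through the generator's segment map
#' @noRd
seg_map_point <- function(segs, pos1) {
  for (s in segs) {
    if (pos1 >= s$src_start && pos1 <= s$src_end) {
      tp <- if (s$strand == "+") s$tgt_start + (pos1 - s$src_start)
            else s$tgt_start + (s$src_end - pos1)
      return(list(tgt = tp, strand = s$strand))
    }
  }
  NULL
}

#' Expected lift status of a variant from the segment map alone
#' @noRd
seg_expected_lift <- function(segs, pos, ref, alt, on_chain) {
  if (!on_chain) {
    return(list(status = "NO_CHAIN", transform = NA, tgt_pos = NA,
                strand = NA))
  }
  extra <- if (nchar(alt) > nchar(ref)) 1L else 0L
  span <- pos:(pos + nchar(ref) - 1L + extra)
  maps <- lapply(span, function(p) seg_map_point(segs, p))
  if (all(vapply(maps, is.null, TRUE))) {
    return(list(status = "SPANS_GAP", transform = NA, tgt_pos = NA, strand = NA))
  }
  if (any(vapply(maps, is.null, TRUE))) {
    return(list(status = "SPANS_GAP", transform = NA, tgt_pos = NA, strand = NA))
  }
  strands <- vapply(maps, `[[`, "", "strand")
  tps <- vapply(maps, function(m) as.integer(m$tgt), integer(1))
  step <- if (strands[1] == "+") 1L else -1L
  if (length(unique(strands)) > 1 ||
      (length(tps) > 1 && !all(diff(tps) == step))) {
    return(list(status = "SPANS_GAP", transform = NA, tgt_pos = NA, strand = NA))
  }
  ref_tps <- tps[seq_len(nchar(ref))]
  list(status = "LIFTED",
       transform = if (strands[1] == "-") "REVCOMP" else "NONE",
       tgt_pos = min(ref_tps), strand = strands[1])
}

# ---- the generator ---------------------------------------------------------

#' Generate a synthetic fixture bundle
#'
#' Writes every input the annotation pipeline consumes, plus `truth.json`
#' recording the generator's own expectations (lift status and target locus
#' per variant, clinical/score/interval matches, consequence categories from
#' a translate-and-diff of the planted coding sequences, Mendelian verdicts,
#' realized allele-frequency tallies and a variants-of-interest list) and a
#' ready-to-run `config.yaml`. Identical specs produce byte-identical
#' bundles.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list of file paths plus the in-memory `truth` list, invisibly.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, generate_fixture_impl(spec, dir))
}

#' @noRd
generate_fixture_impl <- function(spec, dir) {
  p <- function(f) file.path(dir, f)
  # genomes
  seq1 <- plant_genes(rand_dna(spec$contig_len))
  seq2 <- rand_dna(spec$contig2_len)
  es <- apply_edit_script(seq1, spec$edits)
  tgt_seq <- es$target

  # variants: distinct, spaced positions; normalized-by-construction alleles
  n2 <- round(spec$n_variants * spec$frac_contig2)
  n1 <- spec$n_variants - n2
  pick_positions <- function(n, len) {
    # spaced >= 12 bp so ref spans (<= 6 bp) of distinct variants never overlap
    cand <- sample(100:(len - 100), min(6 * n, len - 200))
    keep <- integer()
    for (x in sort(cand)) {
      if (!length(keep) || x - keep[length(keep)] >= 12L) keep <- c(keep, x)
      if (length(keep) == n * 2L) break
    }
    sort(sample(keep, min(n, length(keep))))
  }
  src_genome_chr <- function(chrom) if (chrom == "mchr1") seq1 else seq2
  make_variant <- function(chrom, pos, want_indel) {
    sq <- src_genome_chr(chrom)
    base <- substr(sq, pos, pos)
    if (!want_indel) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      return(list(chrom = chrom, pos = pos, ref = base, alt = alt))
    }
    len <- sample(1:4, 1)
    if (runif(1) < 0.5) {  # insertion
      list(chrom = chrom, pos = pos, ref = base,
           alt = paste0(base, rand_dna(len)))
    } else {               # deletion
      list(chrom = chrom, pos = pos,
           ref = substr(sq, pos, pos + len), alt = base)
    }
  }
  genome_src <- Biostrings::DNAStringSet(c(mchr1 = seq1, mchr2 = seq2))
  vars <- list()
  for (chrom in c("mchr1", "mchr2")) {
    n <- if (chrom == "mchr1") n1 else n2
    poss <- pick_positions(n, nchar(src_genome_chr(chrom)))
    indel <- runif(n) < spec$indel_frac
    for (j in seq_len(n)) {
      v <- make_variant(chrom, poss[j], indel[j])
      # plant the normalized representation; a left shift beyond 5 bp could
      # break the spacing guarantee, so such draws (rare) are dropped
      nv <- normalize_one(v$chrom, v$pos, v$ref, v$alt, genome_src)
      if (v$pos - nv$pos > 5L) next
      vars[[length(vars) + 1L]] <- list(chrom = v$chrom, pos = nv$pos,
                                        ref = nv$ref, alt = nv$alt)
    }
  }
  nv_tot <- length(vars)
  vchrom <- vapply(vars, `[[`, "", "chrom")
  vpos <- vapply(vars, function(v) as.integer(v$pos), integer(1))
  vref <- vapply(vars, `[[`, "", "ref")
  valt <- vapply(vars, `[[`, "", "alt")
  keys <- paste(vchrom, vpos, vref, valt, sep = ":")

  # expected lift per variant from the segment map
  lifts <- lapply(seq_len(nv_tot), function(i)
    seg_expected_lift(es$segs, vpos[i], vref[i], valt[i],
                      on_chain = vchrom[i] == "mchr1"))
  status <- vapply(lifts, `[[`, "", "status")

  # plant ALLELE_SWAP and REF_MISMATCH by editing the target sequence at
  # lifted SNV sites
  snv_lifted <- which(status == "LIFTED" & nchar(vref) == 1 & nchar(valt) == 1)
  snv_lifted <- sample(snv_lifted)
  swap_idx <- utils::head(snv_lifted, spec$n_swap)
  mm_idx <- utils::head(setdiff(snv_lifted, swap_idx), spec$n_mismatch)
  tchars <- strsplit(tgt_seq, "")[[1]]
  tr_allele <- function(i, a) {
    if (lifts[[i]]$strand == "-") revcomp(a) else a
  }
  for (i in swap_idx) {
    tchars[lifts[[i]]$tgt_pos] <- tr_allele(i, valt[i])
    status[i] <- "ALLELE_SWAP"
  }
  for (i in mm_idx) {
    other <- setdiff(c("A", "C", "G", "T"),
                     c(tr_allele(i, vref[i]), tr_allele(i, valt[i])))
    tchars[lifts[[i]]$tgt_pos] <- sample(other, 1)
    status[i] <- "REF_MISMATCH"
  }
  tgt_seq <- paste(tchars, collapse = "")
  # target-space representation of each annotation-eligible variant: apply
  # the strand transform, then normalize against the target sequence so the
  # representation is anchored and left-aligned like any target-space record
  genome_tgt <- Biostrings::DNAStringSet(c(hchr1 = tgt_seq))
  tgt_rep <- lapply(seq_len(nv_tot), function(i) {
    if (!status[i] %in% c("LIFTED", "ALLELE_SWAP")) return(NULL)
    r <- tr_allele(i, vref[i]); a <- tr_allele(i, valt[i])
    tp <- lifts[[i]]$tgt_pos
    if (status[i] == "ALLELE_SWAP") { tmp <- r; r <- a; a <- tmp }
    nv <- normalize_one("hchr1", tp, r, a, genome_tgt)
    list(chrom = "hchr1", pos = nv$pos, ref = nv$ref, alt = nv$alt)
  })

  # pedigree and genotypes
  founders <- sprintf("F%02d", seq_len(spec$n_founders))
  children <- sprintf("C%02d", seq_len(spec$n_children))
  samples <- c(founders, children)
  sire <- founders[2 * ((seq_len(spec$n_children) - 1) %% (spec$n_founders %/% 2)) + 1]
  dam <- founders[2 * ((seq_len(spec$n_children) - 1) %% (spec$n_founders %/% 2)) + 2]
  ped_df <- data.frame(
    id = samples,
    sire = c(rep("0", spec$n_founders), sire),
    dam = c(rep("0", spec$n_founders), dam),
    sex = rep(c("M", "F"), length.out = length(samples)),
    stringsAsFactors = FALSE)

  freqs <- switch(spec$freq_law,
    neutral = exp(runif(nv_tot, log(0.025), log(0.95))),
    uniform = runif(nv_tot, 0.05, 0.95),
    grid = sample(seq(0.05, 0.95, by = 0.05), nv_tot, TRUE),
    la_stop("unknown frequency law", "liftann_spec_error"))
  nf <- spec$n_founders
  ns <- length(samples)
  g1 <- matrix(NA_integer_, nv_tot, ns, dimnames = list(NULL, samples))
  g2 <- g1
  for (i in seq_len(nv_tot)) {
    if (spec$genotype_mode == "deterministic") {
      k <- round(2 * nf * freqs[i])
      alleles <- c(rep(1L, k), rep(0L, 2 * nf - k))
    } else {
      alleles <- rbinom(2 * nf, 1, freqs[i])
    }
    g1[i, 1:nf] <- alleles[seq_len(nf)]
    g2[i, 1:nf] <- alleles[nf + seq_len(nf)]
    for (j in seq_len(spec$n_children)) {
      ci <- nf + j
      si <- match(sire[j], samples); di <- match(dam[j], samples)
      g1[i, ci] <- if (runif(1) < 0.5) g1[i, si] else g2[i, si]
      g2[i, ci] <- if (runif(1) < 0.5) g1[i, di] else g2[i, di]
    }
  }
  # planted Mendelian violations: both parents hom-ref, child hom-alt
  viol_idx <- sample(nv_tot, min(spec$n_mendel_violations, nv_tot))
  viol_child <- sample(spec$n_children, length(viol_idx), TRUE)
  for (k in seq_along(viol_idx)) {
    i <- viol_idx[k]; j <- viol_child[k]
    si <- match(sire[j], samples); di <- match(dam[j], samples)
    g1[i, si] <- 0L; g2[i, si] <- 0L
    g1[i, di] <- 0L; g2[i, di] <- 0L
    g1[i, nf + j] <- 1L; g2[i, nf + j] <- 1L
  }
  # missingness (never on planted-violation cells)
  miss <- matrix(runif(nv_tot * ns) < spec$missing_rate, nv_tot, ns)
  for (k in seq_along(viol_idx)) {
    i <- viol_idx[k]; j <- viol_child[k]
    miss[i, c(match(sire[j], samples), match(dam[j], samples), nf + j)] <- FALSE
  }
  g1[miss] <- NA_integer_; g2[miss] <- NA_integer_

  # annotation tables in target coordinates
  eligible <- which(!vapply(tgt_rep, is.null, TRUE))
  eligible <- sample(eligible)
  clin_idx <- utils::head(eligible, spec$n_clinical)
  sigs <- rep(c("Pathogenic", "Likely_pathogenic",
                "Pathogenic/Likely_pathogenic", "Benign",
                "Uncertain_significance", "Likely_benign"),
              length.out = length(clin_idx))
  clin <- data.frame(
    chrom = vapply(tgt_rep[clin_idx], `[[`, "", "chrom"),
    pos = vapply(tgt_rep[clin_idx], function(x) as.integer(x$pos), integer(1)),
    ref = vapply(tgt_rep[clin_idx], `[[`, "", "ref"),
    alt = vapply(tgt_rep[clin_idx], `[[`, "", "alt"),
    significance = sigs,
    condition = sprintf("disorder_%02d", seq_along(clin_idx)),
    gene = sprintf("HGENE%02d", seq_along(clin_idx)),
    stringsAsFactors = FALSE)
  # decoys: same position, different alternate allele (never a match)
  decoy_idx <- utils::head(setdiff(eligible, clin_idx), spec$n_clinical_decoy)
  decoys <- do.call(rbind, lapply(decoy_idx, function(i) {
    tr <- tgt_rep[[i]]
    if (nchar(tr$ref) == 1 && nchar(tr$alt) == 1) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), c(tr$ref, tr$alt)), 1)
    } else {
      alt <- paste0(tr$ref, "A")  # different-shape allele at the same site
      if (alt == tr$alt) alt <- paste0(tr$ref, "C")
    }
    data.frame(chrom = tr$chrom, pos = tr$pos, ref = tr$ref, alt = alt,
               significance = "Pathogenic", condition = "decoy_condition",
               gene = "DECOY", stringsAsFactors = FALSE)
  }))
  clin_all <- rbind(clin, decoys)
  clin_all <- clin_all[order(clin_all$pos, clin_all$alt), ]
  utils::write.table(clin_all, p("clinical.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  score_idx <- utils::head(setdiff(eligible, c(clin_idx, decoy_idx)),
                           spec$n_scores)
  score_vals <- round(runif(length(score_idx)), 3)
  scores <- data.frame(
    chrom = vapply(tgt_rep[score_idx], `[[`, "", "chrom"),
    pos = vapply(tgt_rep[score_idx], function(x) as.integer(x$pos), integer(1)),
    score = score_vals, stringsAsFactors = FALSE)
  scores <- scores[order(scores$pos), ]
  utils::write.table(scores, p("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tgt_len <- nchar(tgt_seq)
  iv_starts <- sort(sample(seq(1L, tgt_len - 400L), 4))
  intervals <- data.frame(chrom = "hchr1", start0 = iv_starts - 1L,
                          end = iv_starts + 299L,
                          name = sprintf("elem%02d", seq_along(iv_starts)))
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start0,
                     intervals$end, intervals$name), p("intervals.bed"))

  # files: genomes, chain, VCF, GFF, pedigree
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(mchr1 = seq1, mchr2 = seq2)), p("source.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(hchr1 = tgt_seq)), p("target.fa"))
  chains <- list(list(
    score = 1000, src_name = "mchr1", src_size = nchar(seq1),
    src_strand = "+", src_start = 0L, src_end = nchar(seq1),
    tgt_name = "hchr1", tgt_size = tgt_len, tgt_strand = "+",
    tgt_start = 0L, tgt_end = tgt_len, chain_id = "1", blocks = es$blocks))
  for (k in seq_along(es$inversions)) {
    inv <- es$inversions[[k]]
    w <- inv$src_end - inv$src_start + 1L
    tgt_fwd_start0 <- inv$tgt_start - 1L
    chains[[length(chains) + 1L]] <- list(
      score = 900, src_name = "mchr1", src_size = nchar(seq1),
      src_strand = "+", src_start = inv$src_start - 1L, src_end = inv$src_end,
      tgt_name = "hchr1", tgt_size = tgt_len, tgt_strand = "-",
      tgt_start = tgt_len - (tgt_fwd_start0 + w), tgt_end = tgt_len - tgt_fwd_start0,
      chain_id = as.character(k + 1L),
      blocks = data.frame(size = w, dt = 0L, dq = 0L))
  }
  write_chain(chains, p("lift.chain"))
  ord <- order(match(vchrom, c("mchr1", "mchr2")), vpos)
  vt <- variant_table(vchrom[ord], vpos[ord], vref[ord], valt[ord],
                      id = sprintf("v%04d", seq_len(nv_tot)),
                      gt1 = g1[ord, , drop = FALSE],
                      gt2 = g2[ord, , drop = FALSE],
                      samples = samples, assembly = "source_v1")
  write_vcf(vt, p("cohort.vcf"),
            header_meta = list(contigs = c(mchr1 = nchar(seq1),
                                           mchr2 = nchar(seq2))))
  write_fixture_gff(p("genes.gff3"), spec$contig_len)
  utils::write.table(ped_df, p("pedigree.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ---- truth bookkeeping ----
  called <- !is.na(g1) & !is.na(g2)
  altn <- (g1 == 1L) + (g2 == 1L)
  ac <- rowSums(ifelse(called, altn, 0L))
  an <- 2L * rowSums(called)
  af <- ifelse(an > 0, ac / an, NA_real_)
  carriers <- rowSums(((!is.na(g1) & g1 == 1L) | (!is.na(g2) & g2 == 1L)))
  vtype <- ifelse(nchar(vref) == 1 & nchar(valt) == 1, "SNV",
                  ifelse(nchar(vref) < nchar(valt), "insertion", "deletion"))
  region <- vapply(seq_len(nv_tot), function(i)
    gen_region(vchrom[i], vpos[i], vref[i], valt[i],
               contig_len = spec$contig_len), character(1))
  csq <- vapply(seq_len(nv_tot), function(i)
    gen_consequence(vchrom[i], vpos[i], vref[i], valt[i], region[i], seq1),
    character(1))
  clin_flag <- seq_len(nv_tot) %in% clin_idx
  clin_path <- rep(FALSE, nv_tot)
  clin_path[clin_idx] <- parse_significance(sigs)$pathogenic
  score_of <- rep(NA_real_, nv_tot)
  score_of[score_idx] <- score_vals
  iv_hit <- vapply(seq_len(nv_tot), function(i) {
    tr <- tgt_rep[[i]]
    if (is.null(tr)) return(NA_character_)
    hit <- which(intervals$start0 + 1L <= tr$pos + nchar(tr$ref) - 1L &
                 intervals$end >= tr$pos)
    if (length(hit)) paste(intervals$name[hit], collapse = ",") else NA_character_
  }, character(1))
  impact <- unname(CONSEQUENCE_IMPACT[csq])
  voi <- clin_path | impact == "HIGH" |
    (!is.na(score_of) & score_of >= spec$damaging_threshold)
  mendel_violation <- rep(FALSE, nv_tot)
  mendel_violation[viol_idx] <- TRUE
  afs_bins <- 20L
  fpos <- af[!is.na(af) & af > 0]
  truth <- list(
    seed = spec$seed,
    n_variants = nv_tot,
    samples = samples,
    contigs = list(mchr1 = nchar(seq1), mchr2 = nchar(seq2),
                   hchr1 = tgt_len),
    status_counts = as.list(table(status)),
    lift_rate_pct = 100 * mean(status %in% c("LIFTED", "ALLELE_SWAP")),
    n_by_type = as.list(table(vtype)),
    n_private = sum(carriers == 1L),
    afs = as.integer(tabulate(pmin(ceiling(fpos * afs_bins), afs_bins),
                              nbins = afs_bins)),
    region_counts = as.list(table(region)),
    n_clinical_match = length(clin_idx),
    n_clinical_pathogenic = sum(clin_path),
    n_voi = sum(voi),
    n_mendel_violation = length(viol_idx),
    variants = lapply(seq_len(nv_tot), function(i) {
      tr <- tgt_rep[[i]]
      list(key = keys[i], status = status[i],
           transform = if (is.null(tr)) NA else {
             base <- if (lifts[[i]]$strand == "-") "REVCOMP" else "NONE"
             if (status[i] == "ALLELE_SWAP")
               (if (base == "REVCOMP") "REVCOMP_AND_SWAP" else "SWAP")
             else base
           },
           tgt = if (is.null(tr)) NA
                 else paste(tr$chrom, tr$pos, sep = ":"),
           type = vtype[i], af = af[i], carriers = carriers[i],
           region = region[i], csq = csq[i], impact = impact[i],
           clinical = clin_flag[i], clinical_pathogenic = clin_path[i],
           score = score_of[i], interval = iv_hit[i],
           mendel_violation = mendel_violation[i], voi = voi[i])
    }))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  config <- list(
    source_fasta = "source.fa", target_fasta = "target.fa",
    chain = "lift.chain", gff = "genes.gff3", pedigree = "pedigree.tsv",
    vcf = "cohort.vcf",
    source_assembly = "source_v1", target_assembly = "target_v1",
    contig_order = c("mchr1", "mchr2"),
    sources = list(
      list(name = "clinvar", kind = "ALLELE_KEYED", path = "clinical.tsv",
           fields = c("significance", "condition", "gene"), clinical = TRUE),
      list(name = "polyphen", kind = "POSITION_KEYED", path = "scores.tsv",
           fields = "score"),
      list(name = "regulatory", kind = "INTERVAL", path = "intervals.bed",
           fields = "element")),
    damaging = list(list(key = "MG_POLYPHEN_SCORE",
                         threshold = spec$damaging_threshold)),
    afs_bins = afs_bins,
    genome_length = nchar(seq1) + nchar(seq2),
    mendel_max_rate = 0)
  yaml::write_yaml(config, p("config.yaml"))

  invisible(list(dir = dir, truth = truth,
                 paths = setNames(file.path(dir, c(
                   "source.fa", "target.fa", "lift.chain", "cohort.vcf",
                   "genes.gff3", "pedigree.tsv", "clinical.tsv", "scores.tsv",
                   "intervals.bed", "truth.json", "config.yaml")),
                   c("source_fasta", "target_fasta", "chain", "vcf", "gff",
                     "pedigree", "clinical", "scores", "intervals", "truth",
                     "config"))))
}

# ---- generator-side truth for regions and consequences ---------------------

#' Region category by direct interval arithmetic over the planted genes
#' @noRd
gen_region <- function(chrom, pos, ref, alt, splice_width = 3L,
                       contig_len = .Machine$integer.max) {
  if (chrom != "mchr1") return("intergenic")
  lo <- pos; hi <- pos + nchar(ref) - 1L
  ov <- function(s, e) hi >= s & lo <= e
  defs <- fixture_genes_def(contig_len)
  best <- "intergenic"
  rank <- c(coding = 1, utr = 2, splice_region = 3, intron = 4,
            non_coding_gene = 5, upstream_gene = 6, downstream_gene = 7,
            intergenic = 8)
  consider <- function(cat) if (rank[cat] < rank[best]) best <<- cat
  for (g in defs) {
    if (nrow(g$cds) > 0 && any(ov(g$cds$start, g$cds$end))) consider("coding")
    if (nrow(g$cds) > 0 && any(ov(g$exons$start, g$exons$end))) consider("utr")
    ex <- g$exons[order(g$exons$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      for (j in seq_len(nrow(ex) - 1)) {
        i_s <- ex$end[j] + 1L; i_e <- ex$start[j + 1] - 1L
        if (i_s > i_e) next
        if (ov(i_s, min(i_e, i_s + splice_width - 1L)) ||
            ov(max(i_s, i_e - splice_width + 1L), i_e)) consider("splice_region")
      }
    }
    if (ov(g$start, g$end)) {
      consider(if (nrow(g$cds) > 0) "intron" else "non_coding_gene")
    }
    up <- if (g$strand == "-") c(g$end + 1L, g$end + GENE_FLANK_BP)
          else c(g$start - GENE_FLANK_BP, g$start - 1L)
    dn <- if (g$strand == "-") c(g$start - GENE_FLANK_BP, g$start - 1L)
          else c(g$end + 1L, g$end + GENE_FLANK_BP)
    if (ov(up[1], up[2])) consider("upstream_gene")
    if (ov(dn[1], dn[2])) consider("downstream_gene")
  }
  best
}

#' Consequence category by mutate / re-extract / translate on the planted
#' genes (the generator's independent oracle)
#' @noRd
gen_consequence <- function(chrom, pos, ref, alt, region, seq1) {
  if (region != "coding") return(region)
  defs <- fixture_genes_def(nchar(seq1))
  best <- NULL
  for (g in defs) {
    if (nrow(g$cds) == 0) next
    if (!any(pos + nchar(ref) - 1L >= g$cds$start & pos <= g$cds$end)) next
    if (nchar(ref) != nchar(alt)) {
      d <- nchar(alt) - nchar(ref)
      cat_g <- if (d %% 3L != 0L) "frameshift"
               else if (d > 0) "inframe_insertion" else "inframe_deletion"
    } else {
      mut <- paste0(substr(seq1, 1, pos - 1L), alt,
                    substr(seq1, pos + nchar(ref), nchar(seq1)))
      get_cds <- function(s) {
        fwd <- paste(vapply(seq_len(nrow(g$cds)), function(j)
          substr(s, g$cds$start[j], g$cds$end[j]), character(1)),
          collapse = "")
        if (g$strand == "-") revcomp(fwd) else fwd
      }
      aa_ref <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(get_cds(seq1)), no.init.codon = TRUE)), "")[[1]]
      aa_alt <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(get_cds(mut)), no.init.codon = TRUE)), "")[[1]]
      changed <- which(aa_ref != aa_alt)
      ref_codon1 <- substr(get_cds(seq1), 1, 3)
      alt_codon1 <- substr(get_cds(mut), 1, 3)
      cat_g <- if (ref_codon1 == "ATG" && alt_codon1 != "ATG") "start_lost"
               else if (length(changed) == 0) "synonymous"
               else if (any(aa_alt[changed] == "*")) "stop_gained"
               else if (any(aa_ref[changed] == "*")) "stop_lost"
               else "missense"
    }
    if (is.null(best) || severity_rank(cat_g) < severity_rank(best)) best <- cat_g
  }
  best %||% "coding"
}
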