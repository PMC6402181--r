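#' Read a pipeline configuration file
#'
#' YAML configuration listing input paths (source/target FASTA, chain, GFF3,
#' pedigree, cohort VCF), annotation sources (name, kind, path, fields,
#' optional `clinical` marker), damaging-score rules, AFS bin count,
#' non-masked genome length and assembly tags. Relative paths are resolved
#' against the config file's directory; all referenced paths must exist.
#'
#' @param path path to a YAML config (for instance the `config.yaml` written
#'   by [generate_fixture()]).
#' @return a config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) {
      la_stop(sprintf("configured path '%s' does not exist", p),
              "liftann_config_error")
    }
    p
  }
  for (f in c("source_fasta", "target_fasta", "chain", "gff", "pedigree",
              "vcf")) {
    cfg[[f]] <- fix(cfg[[f]])
  }
  cfg$sources <- lapply(cfg$sources, function(s) { s$path <- fix(s$path); s })
  nm <- vapply(cfg$sources, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    la_stop("annotation source names must be unique", "liftann_config_error")
  }
  cfg
}

#' Run the full annotation pipeline
#'
#' Executes the stages in order: normalize, lift to the target assembly,
#' annotate in target coordinates (clinical flags plus generic sources),
#' translate back to source coordinates, merge with the unlifted stream,
#' call gene-region and coding consequences on the source gene models, and
#' summarize the catalog with Mendelian validation and variants-of-interest
#' prioritization. The output VCF contains exactly one record per input
#' record; a per-stage run report (lift rate, per-status counts, matches per
#' source) is written alongside and logged. On any stage failure, partial
#' outputs are removed and the error names the stage.
#'
#' @param config list from [read_pipeline_config()] (or built in code).
#' @param out_dir output directory.
#' @param in_vcf optional input VCF overriding `config$vcf`.
#' @return list with `vt` (the final annotated [variant_table]), `summary`
#'   (the `catalog_summary`), `report` (named list of per-stage counts) and
#'   `paths` (output files), invisibly.
#' @export
run_pipeline <- function(config, out_dir, in_vcf = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    src_genome <- read_genome(config$source_fasta)
    tgt_genome <- read_genome(config$target_fasta)
    chains <- parse_chain(config$chain)
    genes <- read_gene_models(config$gff)
    ped <- if (!is.null(config$pedigree)) read_pedigree(config$pedigree)
           else NULL
    sources <- lapply(config$sources, function(s) {
      src <- load_source(s$path, s$kind, unlist(s$fields), s$name,
                         genome = if (s$kind == "ALLELE_KEYED") tgt_genome
                                  else NULL)
      src$clinical <- isTRUE(s$clinical)
      src
    })
    contig_order <- unlist(config$contig_order) %||% names(src_genome)

    stage <- "read"
    vt <- read_vcf(in_vcf %||% config$vcf,
                   assembly = config$source_assembly %||% "source")
    n_in <- n_variants(vt)

    stage <- "normalize"
    vt <- normalize_variants(vt, src_genome)

    stage <- "lift"
    lifted <- lift_variants(vt, chains, tgt_genome,
                            target_assembly = config$target_assembly %||% "target")
    status_counts <- table(lifted$results$status)
    lift_rate <- 100 * mean(lifted$results$status %in%
                              c("LIFTED", "ALLELE_SWAP"))
    message(sprintf("lift: %.1f%% of %d variants lifted (%s)", lift_rate,
                    n_in, paste(names(status_counts), status_counts,
                                sep = "=", collapse = ", ")))

    stage <- "annotate"
    ann <- lifted$lifted
    matches <- list()
    for (src in sources) {
      if (isTRUE(src$clinical)) {
        ann <- flag_clinical(ann, src)
        matches[[src$name]] <- sum(info_has(ann, "MG_CLN_SIG") |
                                     info_has(ann, "MG_CLN_SIG_RAW"))
      }
    }
    generic <- Filter(function(s) !isTRUE(s$clinical), sources)
    ann <- annotate_variants(ann, generic)
    for (src in generic) {
      key1 <- paste0("MG_", toupper(src$name), "_", toupper(src$fields[1]))
      matches[[src$name]] <- sum(info_has(ann, key1))
    }
    message(sprintf("annotate: %s",
                    paste(names(matches), unlist(matches), sep = "=",
                          collapse = ", ")))

    stage <- "back_translate"
    back <- back_translate(ann, assembly = config$source_assembly %||% "source")

    stage <- "merge"
    merged <- merge_streams(back, lifted$unlifted, contig_order)
    if (n_variants(merged) != n_in) {
      la_stop(sprintf("conservation violated: %d in, %d out", n_in,
                      n_variants(merged)), "liftann_internal_error")
    }

    stage <- "consequence"
    merged <- call_consequences(merged, genes, src_genome)

    stage <- "catalog"
    damaging <- lapply(config$damaging %||% list(), function(d)
      list(key = d$key, threshold = as.numeric(d$threshold),
           direction = d$direction %||% ">="))
    summary <- summarize_catalog(
      merged, genes = genes, ped = ped,
      n_bins = config$afs_bins %||% 20L,
      genome_length = config$genome_length %||% sum(genome_lengths(src_genome)),
      damaging = damaging)

    stage <- "write"
    hm <- list(contigs = genome_lengths(src_genome)[contig_order])
    out_vcf <- file.path(out_dir, "annotated.vcf")
    written <- c(written, out_vcf)
    write_vcf(merged, out_vcf, header_meta = hm)
    written <- c(written, write_catalog_summary(
      summary, file.path(out_dir, "summary")))
    voi_idx <- which(summary$voi)
    voi_vt <- merged[voi_idx]
    voi_path <- file.path(out_dir, "voi.vcf")
    written <- c(written, voi_path)
    write_vcf(voi_vt, voi_path, header_meta = hm)
    voi_tsv <- file.path(out_dir, "voi.tsv")
    written <- c(written, voi_tsv)
    utils::write.table(data.frame(
      chrom = voi_vt$chrom, pos = voi_vt$pos, ref = voi_vt$ref,
      alt = voi_vt$alt, gene = info_get(voi_vt, "MG_GENE"),
      category = info_get(voi_vt, "MG_CSQ"),
      impact = info_get(voi_vt, "MG_IMPACT"),
      clinical_significance = info_get(voi_vt, "MG_CLN_SIG"),
      condition = info_get(voi_vt, "MG_CLN_DN"),
      stringsAsFactors = FALSE), voi_tsv, sep = "\t", quote = FALSE,
      row.names = FALSE)
    report <- list(
      n_input = n_in, n_output = n_variants(merged),
      lift_rate_pct = lift_rate,
      status_counts = as.list(status_counts),
      matches = matches,
      n_voi = summary$n_voi,
      n_private = summary$n_private,
      n_mendel_violation = summary$n_mendel_violation)
    report_path <- file.path(out_dir, "report.json")
    written <- c(written, report_path)
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    message(sprintf("catalog: %d variants, %d private, %d of interest",
                    summary$n_variants, summary$n_private, summary$n_voi))
    list(vt = merged, summary = summary, report = report,
         paths = c(vcf = out_vcf, voi = voi_path, report = report_path))
  }, liftann_error = function(e) {
    unlink(written)
    la_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "liftann_pipeline_error")
  })
  invisible(result)
}
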