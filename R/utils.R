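#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed liftann error
#'
#' All package errors carry class `liftann_error` plus a specific subclass so
#' callers can trap individual failure modes.
#' @noRd
la_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "liftann_error", "error")))
}

#' Reverse complement of a plain character vector of DNA strings
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
is_acgt <- function(x) grepl("^[ACGT]+$", x)

#' Read a genome FASTA into memory
#'
#' Loads a FASTA file as a named [Biostrings::DNAStringSet]. Sequence names
#' are truncated at the first whitespace, matching the convention of `.fai`
#' indexes. All fixture and pipeline genomes in this package are small enough
#' to hold in memory.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return a [Biostrings::DNAStringSet] keyed by contig name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch genome sequence as an uppercase character string
#'
#' @param genome a [Biostrings::DNAStringSet] from [read_genome()].
#' @param chrom contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    la_stop(sprintf("contig '%s' not present in genome", chrom),
            "liftann_config_error")
  }
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    la_stop(sprintf("coordinates %d-%d out of range for contig '%s' (length %d)",
                    start, end, chrom, len), "liftann_config_error")
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
}

#' Contig lengths of a genome
#' @noRd
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
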