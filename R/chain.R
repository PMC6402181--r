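# UCSC chain format. Header: "chain score srcName srcSize srcStrand srcStart
# srcEnd tgtName tgtSize tgtStrand tgtStart tgtEnd id". Coordinates are
# 0-based half-open and strand-relative: when a side's strand is '-', its
# start/end count from the end of the reverse-complemented sequence. Each
# alignment is a list of ungapped blocks "size dt dq" (dt = unaligned bases
# on the source side, dq = on the target side) ending with a bare size.

#' Parse a UCSC chain file
#'
#' Reads all chains from a chain file and verifies the block arithmetic of
#' each: block sizes plus dt gaps must span exactly `src_end - src_start`,
#' and block sizes plus dq gaps exactly `tgt_end - tgt_start`.
#'
#' @param path path to a chain file.
#' @return an object of class `chain_set`: a list of chains (each a list with
#'   the header fields and a `blocks` data.frame of `size`, `dt`, `dq`),
#'   indexed by source contig for mapping queries.
#' @export
parse_chain <- function(path) {
  lines <- trimws(readLines(path))
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain")) {
      la_stop(sprintf("expected chain header at line %d of '%s'", i, path),
              "liftann_chain_error")
    }
    h <- strsplit(lines[i], "\\s+")[[1]]
    if (length(h) < 12) {
      la_stop(sprintf("short chain header at line %d", i), "liftann_chain_error")
    }
    ch <- list(
      score = as.numeric(h[2]),
      src_name = h[3], src_size = as.integer(h[4]), src_strand = h[5],
      src_start = as.integer(h[6]), src_end = as.integer(h[7]),
      tgt_name = h[8], tgt_size = as.integer(h[9]), tgt_strand = h[10],
      tgt_start = as.integer(h[11]), tgt_end = as.integer(h[12]),
      chain_id = if (length(h) >= 13) h[13] else NA_character_)
    i <- i + 1L
    sizes <- integer(); dts <- integer(); dqs <- integer()
    repeat {
      if (i > length(lines)) la_stop(sprintf(
        "chain %s: unterminated block list", ch$chain_id), "liftann_chain_error")
      parts <- strsplit(lines[i], "\\s+")[[1]]
      i <- i + 1L
      if (length(parts) == 1) {
        sizes <- c(sizes, as.integer(parts[1]))
        dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        break
      } else if (length(parts) == 3) {
        sizes <- c(sizes, as.integer(parts[1]))
        dts <- c(dts, as.integer(parts[2]))
        dqs <- c(dqs, as.integer(parts[3]))
      } else {
        la_stop(sprintf("chain %s: malformed block line", ch$chain_id),
                "liftann_chain_error")
      }
    }
    if (any(sizes < 1L) || any(dts < 0L) || any(dqs < 0L)) {
      la_stop(sprintf("chain %s: block sizes must be >= 1 and gaps >= 0",
                      ch$chain_id), "liftann_chain_error")
    }
    if (sum(sizes) + sum(dts) != ch$src_end - ch$src_start ||
        sum(sizes) + sum(dqs) != ch$tgt_end - ch$tgt_start) {
      la_stop(sprintf(
        "chain %s: blocks span %d/%d bases but header declares %d/%d",
        ch$chain_id, sum(sizes) + sum(dts), sum(sizes) + sum(dqs),
        ch$src_end - ch$src_start, ch$tgt_end - ch$tgt_start),
        "liftann_chain_error")
    }
    ch$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    # strand-relative block start offsets for fast point queries
    ch$src_block_start <- ch$src_start +
      cumsum(c(0L, utils::head(sizes + dts, -1)))
    ch$tgt_block_start <- ch$tgt_start +
      cumsum(c(0L, utils::head(sizes + dqs, -1)))
    chains[[length(chains) + 1L]] <- ch
  }
  structure(list(chains = chains,
                 by_src = split(seq_along(chains),
                                vapply(chains, `[[`, "", "src_name"))),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set: %d chain(s) over source contig(s) %s\n",
              length(x$chains), paste(names(x$by_src), collapse = ", ")))
  invisible(x)
}

#' Write chains to a UCSC chain file
#' @param chains a `chain_set` or plain list of chains as built by
#'   [parse_chain()].
#' @param path output path.
#' @export
write_chain <- function(chains, path) {
  if (inherits(chains, "chain_set")) chains <- chains$chains
  out <- character()
  for (ch in chains) {
    out <- c(out, sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                          format(ch$score, scientific = FALSE, trim = TRUE),
                          ch$src_name, ch$src_size, ch$src_strand,
                          ch$src_start, ch$src_end,
                          ch$tgt_name, ch$tgt_size, ch$tgt_strand,
                          ch$tgt_start, ch$tgt_end, ch$chain_id))
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1) {
      out <- c(out, sprintf("%d %d %d", b$size[-n], b$dt[-n], b$dq[-n]))
    }
    out <- c(out, as.character(b$size[n]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Map a single 0-based source position through a chain set
#'
#' A position inside an ungapped block maps by offset arithmetic;
#' strand-relative chain coordinates are converted to forward-strand target
#' coordinates when the chain's target strand is '-'. A position falling in a
#' source-side (dt) gap of some chain but in no block of any chain reports
#' `SPANS_GAP`; a position covered by no chain reports `NO_CHAIN`; a position
#' mapped by two or more chains to different target loci reports
#' `AMBIGUOUS_MULTIMAP`.
#'
#' @param chains a `chain_set` from [parse_chain()].
#' @param chrom source contig name.
#' @param pos0 0-based source position.
#' @return list with `status` ("LIFTED", "NO_CHAIN", "SPANS_GAP" or
#'   "AMBIGUOUS_MULTIMAP") and, when lifted, `tgt_chrom`, `tgt_pos0` (0-based
#'   forward strand), `tgt_strand`, `chain_id`.
#' @export
map_point <- function(chains, chrom, pos0) {
  idx <- chains$by_src[[chrom]]
  if (is.null(idx)) return(list(status = "NO_CHAIN"))
  hits <- list()
  in_gap <- FALSE
  for (k in idx) {
    ch <- chains$chains[[k]]
    rel <- if (ch$src_strand == "+") pos0 else ch$src_size - 1L - pos0
    if (rel < ch$src_start || rel >= ch$src_end) next
    bi <- findInterval(rel, ch$src_block_start)
    bstart <- ch$src_block_start[bi]
    if (rel < bstart + ch$blocks$size[bi]) {
      trel <- ch$tgt_block_start[bi] + (rel - bstart)
      tfwd <- if (ch$tgt_strand == "+") trel else ch$tgt_size - 1L - trel
      hits[[length(hits) + 1L]] <- list(
        status = "LIFTED", tgt_chrom = ch$tgt_name, tgt_pos0 = tfwd,
        tgt_strand = ch$tgt_strand, chain_id = ch$chain_id)
    } else {
      in_gap <- TRUE
    }
  }
  if (length(hits) == 0) {
    return(list(status = if (in_gap) "SPANS_GAP" else "NO_CHAIN"))
  }
  locus <- vapply(hits, function(h)
    paste(h$tgt_chrom, h$tgt_pos0, h$tgt_strand), character(1))
  if (length(unique(locus)) > 1) return(list(status = "AMBIGUOUS_MULTIMAP"))
  hits[[1]]
}
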