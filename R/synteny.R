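#' Filter assembly-vs-assembly alignments into collinearity blocks
#'
#' Retains primary alignments whose reference (target) span is at least
#' `minBlock` (default 20 kb) as homologous blocks, with orientation taken
#' from the alignment strand.
#'
#' @param x a [PafAlignments-class] object of assembly-vs-assembly
#'   alignments (query = the other assembly, target = the reference).
#' @param minBlock minimum reference span in bp.
#' @return A `GRanges` on the reference (1-based closed), sorted by
#'   (chromosome, start), with metadata columns `qryChrom`, `qryStart`,
#'   `qryEnd` (0-based half-open, as aligned), `orientation`
#'   (`"forward"`/`"inverted"`) and `identity`.
#' @seealso [inversionEvents()]
#' @export
syntenyBlocks <- function(x, minBlock = 20000) {
  stopifnot(is(x, "PafAlignments"))
  df <- x@records
  keep <- df$isPrimary & (df$tend - df$tstart) >= minBlock
  df <- df[keep, , drop = FALSE]
  o <- order(df$tname, df$tstart, method = "radix")
  df <- df[o, , drop = FALSE]
  gr <- GRanges(df$tname, IRanges(df$tstart + 1, df$tend))
  mcols(gr) <- DataFrame(
    qryChrom = df$qname, qryStart = df$qstart, qryEnd = df$qend,
    orientation = ifelse(df$strand == "-", "inverted", "forward"),
    identity = if (nrow(df)) df$nmatch / df$alen else numeric())
  gr
}

#' Group inverted blocks into inversion events
#'
#' Within each (reference chromosome, query chromosome) pair, consecutive
#' inverted blocks in reference order merge into a single inversion event;
#' up to `maxIntervening` forward blocks of the same pair are tolerated
#' inside an event (default 0: any intervening forward block splits).
#'
#' @param blocks a `GRanges` from [syntenyBlocks()].
#' @param maxIntervening forward blocks tolerated inside one event.
#' @return A `GRanges` of events (span of the grouped inverted blocks on the
#'   reference) with metadata columns `qryChrom` and `nBlocks`.
#' @export
inversionEvents <- function(blocks, maxIntervening = 0L) {
  stopifnot(is(blocks, "GRanges"))
  if (!length(blocks)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(qryChrom = character(), nBlocks = integer())
    return(gr)
  }
  df <- data.frame(ref = as.character(seqnames(blocks)),
                   start = start(blocks), end = end(blocks),
                   qry = mcols(blocks)$qryChrom,
                   inv = mcols(blocks)$orientation == "inverted")
  df <- df[order(df$ref, df$start), , drop = FALSE]
  out <- list()
  for (key in unique(paste(df$ref, df$qry, sep = "\r"))) {
    sub <- df[paste(df$ref, df$qry, sep = "\r") == key, , drop = FALSE]
    cur <- NULL; seenFwd <- 0L
    flush <- function() {
      if (!is.null(cur))
        out[[length(out) + 1L]] <<- data.frame(
          ref = sub$ref[1L], start = cur$start, end = cur$end,
          qry = sub$qry[1L], nBlocks = cur$n)
      cur <<- NULL; seenFwd <<- 0L
    }
    for (i in seq_len(nrow(sub))) {
      if (sub$inv[i]) {
        if (is.null(cur)) cur <- list(start = sub$start[i], end = sub$end[i],
                                      n = 1L)
        else {
          cur$end <- max(cur$end, sub$end[i]); cur$n <- cur$n + 1L
        }
        seenFwd <- 0L
      } else if (!is.null(cur)) {
        seenFwd <- seenFwd + 1L
        if (seenFwd > maxIntervening) flush()
      }
    }
    flush()
  }
  if (!length(out)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(qryChrom = character(), nBlocks = integer())
    return(gr)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start), , drop = FALSE]
  gr <- GRanges(res$ref, IRanges(res$start, res$end))
  mcols(gr) <- DataFrame(qryChrom = res$qry, nBlocks = res$nBlocks)
  gr
}
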