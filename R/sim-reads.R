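#' Simulate error-free long reads from a truth genome
#'
#' Draws reads per chromosome until the cumulative read bases reach the
#' target fold-coverage. Lengths are lognormal (mean `readLengthMean`,
#' spread `readLengthSdlog`) floored at the per-platform minimum; starts are
#' uniform, with reads overhanging either chromosome edge clipped to the
#' chromosome — molecules end where the chromosome does — so expected depth
#' is uniform along the chromosome. Reads are error-free by design: the
#' perfect-read detector responds to alignment structure (partial versus
#' full-length), not base errors.
#'
#' @param genome a [SimGenome-class] or `DNAStringSet` truth assembly.
#' @param params a [SimParams-class].
#' @param readType `"hifi"` or `"ont"`.
#' @param seed integer seed; the same seed reproduces the identical read set.
#' @param depth optional fold-coverage override (default `params@depth`).
#' @return A `data.frame` with `id`, `readType`, `chrom`, `start`, `end`
#'   (1-based closed truth coordinates).
#' @seealso [readSequences()], [truthAlign()]
#' @export
simulateReads <- function(genome, params = simParams(),
                          readType = c("hifi", "ont"), seed = 1L,
                          depth = NULL) {
  readType <- match.arg(readType)
  truth <- if (is(genome, "SimGenome")) genome@assembly else genome
  stopifnot(is(truth, "DNAStringSet"))
  depth <- depth %||% unname(params@depth[readType])
  stopifnot(depth > 0)
  mu <- unname(params@readLengthMean[readType])
  minL <- unname(params@readLengthMin[readType])
  sdlog <- params@readLengthSdlog
  meanlog <- log(mu) - sdlog^2 / 2
  lens <- .seqLens(truth)
  withSeed(seed, {
    out <- list()
    for (ch in names(truth)) {
      L <- lens[[ch]]
      if (L < minL) {
        .warnf("chromosome '%s' shorter than the minimum %s read length; skipped",
               ch, readType)
        next
      }
      target <- depth * L
      starts <- integer(); ends <- integer(); total <- 0
      while (total < target) {
        n <- 512L
        rl <- pmax(minL, round(stats::rlnorm(n, meanlog, sdlog)))
        s <- floor(stats::runif(n, 2 - rl, L + 1))
        a <- pmax(1, s); b <- pmin(L, s + rl - 1)
        w <- b - a + 1
        cum <- total + cumsum(w)
        keep <- seq_len(if (any(cum >= target)) which(cum >= target)[1L]
                        else n)
        starts <- c(starts, a[keep]); ends <- c(ends, b[keep])
        total <- cum[keep[length(keep)]]
      }
      out[[ch]] <- data.frame(
        id = sprintf("%s_%s_r%05d", ch, readType, seq_along(starts)),
        readType = readType, chrom = ch, start = starts, end = ends,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Extract read sequences from the truth genome
#'
#' Materialises the (error-free) sequences of simulated reads; each read is
#' the exact truth substring at its recorded coordinates.
#'
#' @param genome a [SimGenome-class] or `DNAStringSet` truth assembly.
#' @param reads a `data.frame` from [simulateReads()].
#' @return A `DNAStringSet` named by read id.
#' @export
readSequences <- function(genome, reads) {
  truth <- if (is(genome, "SimGenome")) genome@assembly else genome
  out <- vector("list", length(unique(reads$chrom)))
  names(out) <- unique(reads$chrom)
  for (ch in names(out)) {
    sub <- reads[reads$chrom == ch, , drop = FALSE]
    seqs <- extractAt(truth[[ch]], IRanges(sub$start, sub$end))
    names(seqs) <- sub$id
    out[[ch]] <- seqs
  }
  res <- do.call(c, unname(out))
  res[reads$id]
}

#' Lift simulated reads onto a corrupted assembly
#'
#' Produces the alignments an idealised aligner would report for error-free
#' reads against the corrupted assembly, by intersecting each read's truth
#' interval with the corrupted assembly's mappable segments. A read wholly
#' inside one segment yields a single full-length primary record
#' (`nmatch = alen =` read length). A read crossing an event breakpoint is
#' clipped: its longest piece becomes the primary record (leaving unaligned
#' query ends — the signature that removes it from the perfect set) and the
#' other pieces become secondary records. Reads from removed tandem copies
#' map onto the surviving copy, multiplying its depth; reads wholly inside
#' deleted sequence yield nothing.
#'
#' @param reads a `data.frame` from [simulateReads()].
#' @param corrupted a [CorruptedAssembly-class] from [injectErrors()].
#' @param minPiece drop alignment pieces shorter than this many bases.
#' @return A [PafAlignments-class] object.
#' @export
truthAlign <- function(reads, corrupted, minPiece = 1L) {
  stopifnot(is(corrupted, "CorruptedAssembly"), is.data.frame(reads))
  ck <- corrupted@alignChunks
  lens <- .seqLens(corrupted@assembly)
  readsGR <- GRanges(reads$chrom, IRanges(reads$start, reads$end))
  chunksGR <- GRanges(ck$truthChrom, IRanges(ck$truthStart, ck$truthEnd))
  hits <- findOverlaps(readsGR, chunksGR)
  ri <- queryHits(hits); ci <- subjectHits(hits)
  is1 <- pmax(reads$start[ri], ck$truthStart[ci])
  ie1 <- pmin(reads$end[ri], ck$truthEnd[ci])
  plen <- ie1 - is1 + 1
  keep <- plen >= max(1L, minPiece)
  ri <- ri[keep]; ci <- ci[keep]; is1 <- is1[keep]; ie1 <- ie1[keep]
  plen <- plen[keep]
  if (!length(ri)) return(.emptyPaf())
  qstart <- is1 - reads$start[ri]          # 0-based on the read
  qend <- qstart + plen
  plus <- ck$strand[ci] == "+"
  # 0-based target start; '-' chunks mirror the piece within the segment
  tstart <- ifelse(plus,
                   ck$corrStart[ci] + (is1 - ck$truthStart[ci]) - 1,
                   ck$corrEnd[ci] - (ie1 - ck$truthStart[ci]) - 1)
  tend <- tstart + plen
  df <- data.frame(
    qname = reads$id[ri], qlen = reads$end[ri] - reads$start[ri] + 1,
    qstart = qstart, qend = qend,
    strand = ifelse(plus, "+", "-"),
    tname = ck$corrChrom[ci], tlen = unname(lens[ck$corrChrom[ci]]),
    tstart = tstart, tend = tend, nmatch = plen, alen = plen,
    mapq = 60, readType = reads$readType[ri], stringsAsFactors = FALSE)
  o <- order(df$qname, -df$nmatch, df$tname, df$tstart, method = "radix")
  df <- df[o, , drop = FALSE]
  df$isPrimary <- !duplicated(df$qname)
  rownames(df) <- NULL
  new("PafAlignments", records = df[, .paf_cols])
}

#' Write a complete simulation to disk
#'
#' Emits the standard file set for one simulated scenario: `truth.fa`,
#' `assembly.fa` (corrupted), per-platform read FASTAs and truth-lifted PAF
#' alignments, `truth_events.bed` (events in corrupted coordinates) and
#' `features.bed` (truth feature tiling).
#'
#' @param genome a [SimGenome-class].
#' @param corrupted a [CorruptedAssembly-class].
#' @param reads named list of read tables (`hifi`, `ont`), as from
#'   [simulateReads()].
#' @param outdir output directory.
#' @param writeReads also materialise read sequences as gzipped FASTA
#'   (sizeable; off by default).
#' @return The output directory, invisibly.
#' @export
writeSimulation <- function(genome, corrupted, reads, outdir,
                            writeReads = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeAssembly(genome@assembly, file.path(outdir, "truth.fa"))
  writeAssembly(corrupted@assembly, file.path(outdir, "assembly.fa"))
  feats <- genome@features
  writeBed(feats, file.path(outdir, "features.bed"),
           name = mcols(feats)$kind, score = rep(0, length(feats)))
  tr <- corrupted@truthRegions
  writeBed(tr, file.path(outdir, "truth_events.bed"),
           name = mcols(tr)$kind, score = mcols(tr)$eventId)
  for (rt in names(reads)) {
    aln <- truthAlign(reads[[rt]], corrupted)
    writePaf(aln, file.path(outdir, sprintf("alignments.%s.paf", rt)))
    if (writeReads)
      writeXStringSet(readSequences(genome, reads[[rt]]),
                      file.path(outdir, sprintf("reads.%s.fa.gz", rt)),
                      compress = TRUE)
  }
  invisible(outdir)
}
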