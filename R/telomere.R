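#' Find chained motif runs
#'
#' Locates every exact occurrence of a pentamer motif and chains consecutive
#' occurrences whose gap (bases between the end of one match and the start
#' of the next) is at most `maxInterruption` into runs. With
#' `maxInterruption = 0` a run is a pure tandem array; positive values admit
#' the variant repeats real telomeric arrays carry.
#'
#' @param seq a `DNAString` (or character scalar).
#' @param motif the pentamer to scan for.
#' @param maxInterruption maximum gap in bp chained across.
#' @return An `IRanges` of run spans (1-based closed), in order.
#' @examples
#' s <- Biostrings::DNAString(strrep("TTAGG", 600))
#' motifRuns(s, "TTAGG", 0)   # one 3000-bp run
#' @export
motifRuns <- function(seq, motif = "TTAGG", maxInterruption = 100) {
  if (is.character(seq)) seq <- DNAString(seq)
  stopifnot(is(seq, "DNAString"), nchar(motif) == 5L, maxInterruption >= 0)
  m <- matchPattern(motif, seq, fixed = TRUE)
  if (!length(m)) return(IRanges())
  s <- start(m); e <- end(m)
  # gap between consecutive matches; <= maxInterruption chains them
  newRun <- c(TRUE, (s[-1L] - e[-length(e)] - 1L) > maxInterruption)
  run <- cumsum(newRun)
  IRanges(tapply(s, run, min), tapply(e, run, max))
}

.sideMotif <- function(side, params) {
  if (side == "right") params@motif
  else as.character(reverseComplement(DNAString(params@motif)))
}

#' Call telomere completeness at one chromosome end
#'
#' Scans the strand-appropriate motif (`TTAGG` at the right end, its reverse
#' complement `CCTAA` at the left end, so both scans read the forward
#' strand), picks the motif run with the largest overlap with the terminal
#' window, and calls the end complete when at least `minRun` bases of that
#' run fall inside the window. The overlap rule — rather than full
#' containment — is deliberate: complete telomeres typically exceed the
#' window itself. `blockCount` reports non-overlapping left-to-right matches
#' of the 25-bp pentamer block (motif x 5) inside the terminal window.
#'
#' @param chromSeq a `DNAString` (or character) chromosome sequence.
#' @param chrom chromosome id for the output row.
#' @param side `"left"` or `"right"`.
#' @param params a [TelomereParams-class].
#' @return A one-row `data.frame`: `chrom`, `side`, `runStart`, `runEnd`,
#'   `runInWindow`, `blockCount`, `complete`. Chromosomes shorter than the
#'   terminal window are called incomplete with a warning.
#' @export
callTelomere <- function(chromSeq, chrom, side = c("left", "right"),
                         params = telomereParams()) {
  side <- match.arg(side)
  if (is.character(chromSeq)) chromSeq <- DNAString(chromSeq)
  stopifnot(is(chromSeq, "DNAString"), is(params, "TelomereParams"))
  L <- length(chromSeq)
  short <- L < params@terminalWindow
  if (short)
    .warnf("chromosome '%s' (%d bp) is shorter than the terminal window",
           chrom, L)
  win <- if (side == "left") IRanges(1L, min(params@terminalWindow, L))
         else IRanges(max(1L, L - params@terminalWindow + 1L), L)
  motif <- .sideMotif(side, params)
  runs <- motifRuns(chromSeq, motif, params@maxInterruption)
  runStart <- NA_integer_; runEnd <- NA_integer_; inWin <- 0
  if (length(runs)) {
    ov <- pmax(0L, pmin(end(runs), end(win)) - pmax(start(runs), start(win)) + 1L)
    best <- which.max(ov)
    runStart <- start(runs)[best]; runEnd <- end(runs)[best]
    inWin <- ov[best]
  }
  block <- strrep(motif, 5L)
  bm <- matchPattern(block, Biostrings::subseq(chromSeq, start(win), end(win)),
                     fixed = TRUE)
  blockCount <- .greedyCount(start(bm), nchar(block))
  data.frame(chrom = chrom, side = side, runStart = runStart,
             runEnd = runEnd, runInWindow = as.numeric(inWin),
             blockCount = blockCount,
             complete = !short && inWin >= params@minRun,
             stringsAsFactors = FALSE)
}

# non-overlapping left-to-right selection among sorted match starts
.greedyCount <- function(starts, width) {
  n <- 0L; lastEnd <- 0L
  for (s in starts) {
    if (s > lastEnd) { n <- n + 1L; lastEnd <- s + width - 1L }
  }
  n
}

#' Telomere census of an assembly
#'
#' Calls both ends of every chromosome and summarises how many chromosomes
#' carry a pair of complete telomeres, exactly one, or none.
#'
#' @param assembly a `DNAStringSet`.
#' @param params a [TelomereParams-class].
#' @return A [TelomereCensus-class] object.
#' @seealso [callTelomere()], [telomereSummary()]
#' @export
telomereCensus <- function(assembly, params = telomereParams()) {
  stopifnot(is(assembly, "DNAStringSet"))
  calls <- do.call(rbind, lapply(names(assembly), function(ch) {
    rbind(callTelomere(assembly[[ch]], ch, "left", params),
          callTelomere(assembly[[ch]], ch, "right", params))
  }))
  rownames(calls) <- NULL
  new("TelomereCensus", calls = calls, params = params)
}

#' @describeIn TelomereCensus-class the per-end call table.
#' @export
setMethod("telomereCalls", "TelomereCensus", function(x) x@calls)

setMethod("show", "TelomereCensus", function(object) {
  s <- telomereSummary(object)
  cat(sprintf(paste0("TelomereCensus: %d chromosome(s); %d with a pair of ",
                     "telomeres, %d with one, %d with none\n"),
              s$nChrom, s$pairs, s$singles, s$none))
})

#' Summarise a telomere census
#'
#' @param x a [TelomereCensus-class] object.
#' @return A list: `nChrom`, `pairs` (both ends complete), `singles`
#'   (exactly one end), `none`.
#' @export
telomereSummary <- function(x) {
  stopifnot(is(x, "TelomereCensus"))
  perChrom <- tapply(x@calls$complete, x@calls$chrom, sum)
  list(nChrom = length(perChrom),
       pairs = sum(perChrom == 2L),
       singles = sum(perChrom == 1L),
       none = sum(perChrom == 0L))
}

#' Telomere runs as genomic ranges
#'
#' Best motif runs from a census as a `GRanges` (for BED export); ends with
#' no motif run are omitted.
#'
#' @param x a [TelomereCensus-class] object.
#' @return A `GRanges` with `name` (`<side>_<complete|incomplete>`) and
#'   `score` (run bases inside the terminal window).
#' @export
telomereRuns <- function(x) {
  stopifnot(is(x, "TelomereCensus"))
  df <- x@calls[!is.na(x@calls$runStart), , drop = FALSE]
  GRanges(df$chrom, IRanges(df$runStart, df$runEnd),
          name = paste0(df$side, "_",
                        ifelse(df$complete, "complete", "incomplete")),
          score = df$runInWindow)
}
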