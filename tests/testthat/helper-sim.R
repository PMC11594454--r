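# Shared simulation scaffolding. The detection scenario mirrors the study
# geometry scaled down tenfold: 1 Mb chromosomes with 5 kb / 2.5 kb windows
# and a 2 kb end exclusion, read profiles at the study's platform scale.

scaledParams <- function(mergeGap = 0)
  pbdParams(window = 5000, step = 2500, endExclusion = 2000,
            mergeGap = mergeGap)

# compact genome for fast module tests
smallSimParams <- function()
  simParams(nChroms = 2, chromLen = 2e5, telomereLen = 5000,
            repeatUnitLen = 10000, repeatCopies = 3,
            intersperseLen = 1000, intersperseCopies = 2,
            depth = c(hifi = 30, ont = 30),
            readLengthMean = c(hifi = 3000, ont = 15000),
            readLengthMin = c(hifi = 1000, ont = 8000))

# one full detection scenario: three injected errors (a 20 kb deletion, a
# 4-to-1 tandem collapse, a chimeric tail swap) or an error-free control
simScenario <- function(seed, withEvents = TRUE, depth = 60) {
  p <- simParams()
  g <- simulateGenome(p, seed = seed)
  feat <- genomeFeatures(g)
  arr2 <- range(feat[GenomicRanges::seqnames(feat) == "chr2" &
                       feat$kind == "tandem_repeat"])
  ev <- if (withEvents) suppressWarnings(c(
    deletionEvent("chr1", 300001, 320000),
    collapseEvent("chr2", GenomicRanges::start(arr2),
                  GenomicRanges::end(arr2), 4),
    chimericJoinEvent("chr1", 700000, "chr3", 250000)))
  else GenomicRanges::GRanges()
  corr <- injectErrors(g, ev)
  rh <- simulateReads(g, p, "hifi", seed = seed * 17 + 1, depth = depth)
  ro <- simulateReads(g, p, "ont", seed = seed * 17 + 2, depth = depth)
  list(params = p, genome = g, events = ev, corrupted = corr,
       reads = list(hifi = rh, ont = ro),
       aln = list(hifi = truthAlign(rh, corr),
                  ont = truthAlign(ro, corr)))
}

runScan <- function(scn, params = scaledParams()) {
  list(hifi = pbdDetect(scn$aln$hifi, assemblySeq(scn$corrupted), params),
       ont = pbdDetect(scn$aln$ont, assemblySeq(scn$corrupted), params))
}

# motif-free spacer sequence
spacer <- function(n) substr(strrep("AC", ceiling(n / 2) + 1), 1, n)

# chromosome with a right-end telomeric run of exactly `runLen` bases
# (runs of length 4 mod 5 use a single 4-bp interruption)
chromWithRightRun <- function(runLen, L = 30000) {
  stopifnot(runLen %% 5 %in% c(0, 4))
  tail <- if (runLen %% 5 == 0) strrep("TTAGG", runLen / 5)
          else paste0("TTAGG", "AAAA", strrep("TTAGG", (runLen - 9) / 5))
  paste0(spacer(L - runLen), tail)
}

# distance in bp between a point/region of truth and the nearest flagged
# region of the required kind (0 when overlapping)
flagDistance <- function(flagged, kind, region) {
  fl <- flagged[S4Vectors::mcols(flagged)$kind == kind &
                  as.character(GenomicRanges::seqnames(flagged)) ==
                    as.character(GenomicRanges::seqnames(region))]
  if (!length(fl)) return(Inf)
  d <- GenomicRanges::distance(region, fl)
  min(d, na.rm = TRUE)
}
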