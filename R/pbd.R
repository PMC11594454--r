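#' Windowed perfect-read coverage for one chromosome
#'
#' Computes mean per-base depth of the supplied (already perfect-filtered)
#' alignments in sliding windows over the evaluated region of a chromosome.
#' Windows start at `endExclusion`, advance by `step`, and the last window is
#' truncated so that it ends at `chromLen - endExclusion`; a truncated window
#' shorter than `step` is dropped. A chromosome whose evaluated region is
#' shorter than `step` yields an empty track with a warning.
#'
#' @param x a [PafAlignments-class] object whose records all target `chrom`;
#'   typically the output of [selectPerfect()].
#' @param chrom chromosome id.
#' @param chromLen chromosome length in bp.
#' @param params a [PbdParams-class].
#' @return A `GRanges` of windows (1-based closed) with metadata column
#'   `meanCov`.
#' @seealso [classifyWindows()], [pbdDetect()]
#' @export
perfectCoverageTrack <- function(x, chrom, chromLen, params = pbdParams()) {
  stopifnot(is(x, "PafAlignments"), is(params, "PbdParams"))
  df <- x@records
  if (nrow(df) && !all(df$tname == chrom))
    .stopf("alignments target other chromosomes than '%s'", chrom)
  if (nrow(df) && any(df$tend > chromLen))
    .stopf("alignment beyond chromosome bounds on '%s'", chrom)
  excl <- params@endExclusion
  evalStart <- excl + 1
  evalEnd <- chromLen - excl
  empty <- GRanges(seqlengths = stats::setNames(chromLen, chrom))
  mcols(empty)$meanCov <- numeric()
  if (evalEnd - evalStart + 1 < params@step) {
    .warnf("chromosome '%s' too short to evaluate (length %s)", chrom,
           chromLen)
    return(empty)
  }
  starts <- seq(evalStart, evalEnd, by = params@step)
  ends <- pmin(starts + params@window - 1, evalEnd)
  keep <- (ends - starts + 1) >= params@step
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)
  cov <- coverage(IRanges(df$tstart + 1, df$tend), width = chromLen)
  means <- viewMeans(Views(cov, start = starts, end = ends))
  gr <- GRanges(chrom, IRanges(starts, ends),
                seqlengths = stats::setNames(chromLen, chrom))
  mcols(gr)$meanCov <- as.numeric(means)
  gr
}

#' Mean depth over the evaluated region
#'
#' Length-weighted mean of window means — the per-chromosome normalizer for
#' window depth ratios. Computed from the perfect-read track itself so the
#' ratio is self-consistent per chromosome (essential for e.g. a
#' half-depth Z chromosome in a female-derived read set).
#'
#' @param track a window `GRanges` from [perfectCoverageTrack()].
#' @return A single number.
#' @export
chromosomeMeanDepth <- function(track) {
  stopifnot(is(track, "GRanges"))
  if (!length(track)) .stopf("chromosome too short to evaluate")
  w <- BiocGenerics::width(track)
  sum(mcols(track)$meanCov * w) / sum(w)
}

#' Classify coverage windows against the correctness band
#'
#' Each window's ratio `meanCov / meanDepth` is compared with the band:
#' strictly below `lowRatio` flags `low` (candidate misjoin or missing
#' sequence — reads spanning a breakpoint lose their full-length status and
#' drop out of the perfect set); strictly above `highRatio` flags `high`
#' (candidate collapsed repeat — reads from several true copies pile onto
#' the surviving one). Consecutive or overlapping flagged windows of the same
#' kind merge into one region; `mergeGap` unflagged windows are tolerated
#' inside a region, but a window of the opposite kind always closes it.
#'
#' @param track a window `GRanges` from [perfectCoverageTrack()] (one
#'   chromosome, windows in order).
#' @param meanDepth the per-chromosome mean depth (> 0).
#' @param params a [PbdParams-class].
#' @return A `GRanges` of flagged regions with metadata columns `kind`
#'   (`"low"`/`"high"`), `ratio` (minimum window ratio for `low` regions,
#'   maximum for `high`) and `nWindows` (flagged windows merged).
#' @export
classifyWindows <- function(track, meanDepth, params = pbdParams()) {
  stopifnot(is(track, "GRanges"), is(params, "PbdParams"))
  if (!is.numeric(meanDepth) || length(meanDepth) != 1L || meanDepth <= 0)
    .stopf("meanDepth must be a single positive number")
  ratio <- mcols(track)$meanCov / meanDepth
  kind <- rep("none", length(track))
  kind[ratio < params@lowRatio] <- "low"
  kind[ratio > params@highRatio] <- "high"
  .mergeFlags(track, kind, ratio, params@mergeGap)
}

# Merge runs of same-kind flagged windows, tolerating up to mergeGap
# unflagged windows in between; an opposite-kind window closes the run.
.mergeFlags <- function(track, kind, ratio, mergeGap) {
  out <- list()
  cur <- NULL
  gap <- 0
  flush <- function() {
    if (is.null(cur)) return()
    idx <- cur$idx
    r <- if (cur$kind == "low") min(ratio[idx]) else max(ratio[idx])
    out[[length(out) + 1L]] <<- data.frame(
      chrom = as.character(seqnames(track))[idx[1L]],
      start = min(start(track)[idx]), end = max(end(track)[idx]),
      kind = cur$kind, ratio = r, nWindows = length(idx))
    cur <<- NULL
  }
  for (i in seq_along(kind)) {
    k <- kind[i]
    if (k == "none") {
      if (!is.null(cur)) {
        gap <- gap + 1
        if (gap > mergeGap) flush()
      }
      next
    }
    if (!is.null(cur) && cur$kind == k) {
      cur$idx <- c(cur$idx, i); gap <- 0
    } else {
      flush()
      cur <- list(kind = k, idx = i); gap <- 0
    }
  }
  flush()
  if (!length(out)) {
    gr <- GRanges(seqlengths = seqlengths(track))
    mcols(gr) <- DataFrame(kind = character(), ratio = numeric(),
                           nWindows = integer())
    return(gr)
  }
  df <- do.call(rbind, out)
  GRanges(df$chrom, IRanges(df$start, df$end), kind = df$kind,
          ratio = df$ratio, nWindows = df$nWindows,
          seqlengths = seqlengths(track))
}

#' Genome-wide perfect-read error scan
#'
#' Runs the full scan for one read set: optionally filters alignments to the
#' perfect set, then per chromosome builds the window track, computes the
#' mean depth, and classifies windows. Chromosomes whose evaluated region is
#' too short, or with zero perfect-read depth, are skipped with a warning.
#'
#' @param x a [PafAlignments-class] object (one read type).
#' @param assembly a `DNAStringSet` or named vector of chromosome lengths.
#' @param params a [PbdParams-class].
#' @param filter apply [selectPerfect()] first (set `FALSE` when `x` is
#'   already filtered).
#' @param policy a [FullLengthPolicy-class], used when `filter = TRUE`.
#' @return A [PbdResult-class] object.
#' @examples
#' aln <- pafAlignments("r1", 100000, 0, 100000, "+", "c1", 2e5,
#'                      20000, 120000, 100000, 100000, 60, TRUE, "hifi")
#' res <- pbdDetect(aln, c(c1 = 2e5), filter = FALSE)
#' meanDepth(res)
#' @export
pbdDetect <- function(x, assembly, params = pbdParams(), filter = TRUE,
                      policy = fullLengthPolicy()) {
  stopifnot(is(x, "PafAlignments"))
  if (filter) x <- selectPerfect(x, policy)
  lens <- .seqLens(assembly)
  df <- x@records
  rt <- unique(df$readType)
  if (length(rt) > 1L)
    .stopf("pbdDetect expects a single read type; got %s",
           paste(rt, collapse = ","))
  unknown <- setdiff(unique(df$tname), names(lens))
  if (length(unknown))
    .stopf("alignments target unknown chromosome(s): %s",
           paste(unknown, collapse = ","))
  winL <- list(); flagL <- list(); md <- numeric()
  for (ch in names(lens)) {
    track <- perfectCoverageTrack(x[df$tname == ch], ch, lens[[ch]], params)
    if (!length(track)) next
    m <- chromosomeMeanDepth(track)
    md[ch] <- m
    winTrack <- track
    mcols(winTrack)$ratio <- if (m > 0) mcols(track)$meanCov / m else NA_real_
    winL[[ch]] <- winTrack
    if (m <= 0) {
      .warnf("chromosome '%s' has zero perfect-read depth; not classified", ch)
      next
    }
    flagL[[ch]] <- classifyWindows(track, m, params)
  }
  emptyW <- GRanges(seqlengths = lens)
  mcols(emptyW) <- DataFrame(meanCov = numeric(), ratio = numeric())
  emptyF <- GRanges(seqlengths = lens)
  mcols(emptyF) <- DataFrame(kind = character(), ratio = numeric(),
                             nWindows = integer())
  wins <- if (length(winL)) .bindGRanges(winL, lens) else emptyW
  flags <- if (length(flagL)) .bindGRanges(flagL, lens) else emptyF
  new("PbdResult", windows = wins, flagged = flags, meanDepth = md,
      readType = if (length(rt)) rt else NA_character_, params = params)
}

.bindGRanges <- function(grl, lens) {
  dfs <- lapply(grl, function(g) {
    d <- as.data.frame(g)[, c("seqnames", "start", "end"), drop = FALSE]
    cbind(d, as.data.frame(mcols(g)))
  })
  df <- do.call(rbind, dfs)
  gr <- GRanges(df$seqnames, IRanges(df$start, df$end), seqlengths = lens)
  mcols(gr) <- DataFrame(df[, setdiff(names(df), c("seqnames", "start", "end")),
                            drop = FALSE])
  gr
}

#' @describeIn PbdResult-class evaluated windows with `meanCov` and `ratio`.
#' @export
setMethod("coverageWindows", "PbdResult", function(x) x@windows)

#' @describeIn PbdResult-class merged flagged regions.
#' @export
setMethod("flaggedRegions", "PbdResult", function(x) x@flagged)

#' @describeIn PbdResult-class per-chromosome mean perfect-read depth.
#' @export
setMethod("meanDepth", "PbdResult", function(x) x@meanDepth)

setMethod("show", "PbdResult", function(object) {
  fl <- object@flagged
  cat(sprintf("PbdResult (%s): %d chromosome(s), %d window(s)\n",
              object@readType, length(object@meanDepth),
              length(object@windows)))
  cat(sprintf("  flagged: %d low, %d high\n",
              sum(mcols(fl)$kind == "low"), sum(mcols(fl)$kind == "high")))
})

#' Combine flagged regions across read sets
#'
#' Merges per-read-set flagged regions into one report. In `union` mode a
#' region is reported when flagged in any read set; in `intersection` mode
#' only where regions of the same kind overlap in every read set. Each
#' reported region carries the supporting read sets in `provenance`.
#'
#' @param flagged a named list of flagged `GRanges` (or [PbdResult-class]
#'   objects), one per read set, e.g. `list(hifi = ..., ont = ...)`.
#' @param mode `"union"` or `"intersection"`.
#' @return A `GRanges` with metadata columns `kind` and `provenance`.
#' @export
pbdReport <- function(flagged, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(is.list(flagged), length(flagged) >= 1L,
            !is.null(names(flagged)))
  flagged <- lapply(flagged, function(f)
    if (is(f, "PbdResult")) flaggedRegions(f) else f)
  sets <- names(flagged)
  out <- list()
  for (k in c("low", "high")) {
    byset <- lapply(flagged, function(g) reduce(g[mcols(g)$kind == k]))
    merged <- if (mode == "union") {
      reduce(do.call(c, unname(byset)))
    } else {
      Reduce(GenomicRanges::intersect, byset)
    }
    if (!length(merged)) next
    prov <- vapply(seq_along(merged), function(i) {
      supp <- sets[vapply(byset, function(g)
        length(findOverlaps(merged[i], g)) > 0, NA)]
      paste(sort(supp), collapse = ",")
    }, "")
    mcols(merged) <- DataFrame(kind = k, provenance = prov)
    out[[k]] <- merged
  }
  if (!length(out)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(kind = character(), provenance = character())
    return(gr)
  }
  sort(do.call(c, unname(out)), ignore.strand = TRUE)
}
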