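# Independent brute-force reference implementations used to check the
# package's vectorized/IRanges-based code on randomized instances. These are
# deliberately naive: per-base accumulators, per-record loops, explicit
# chains.

suppressPackageStartupMessages({
  library(Biostrings)
  library(IRanges)
  library(GenomicRanges)
  library(S4Vectors)
})

# maximal N runs by run-length encoding of a character scan
oracleFindGaps <- function(seqchar, minRun = 1L) {
  isN <- strsplit(seqchar, "")[[1L]] == "N"
  r <- rle(isN)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  data.frame(start = starts[keep], end = ends[keep])
}

# record-by-record filter, then per-read best by the stated tie-breaks
oracleSelectPerfect <- function(df, tolHifi = 200, tolOnt = 1000) {
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    tol <- if (df$readType[i] == "hifi") tolHifi else tolOnt
    ok[i] <- df$isPrimary[i] && df$qstart[i] <= tol &&
      (df$qlen[i] - df$qend[i]) <= tol
  }
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) return(df)
  pick <- integer(0)
  for (qn in unique(df$qname)) {
    idx <- which(df$qname == qn)
    idx <- idx[order(-df$nmatch[idx], df$tstart[idx], df$tname[idx])]
    pick <- c(pick, idx[1L])
  }
  out <- df[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base accumulator coverage and window means (1-based closed windows)
oracleWindowMeans <- function(tstart0, tend0, chromLen, window, step, excl) {
  depth <- numeric(chromLen)
  for (i in seq_along(tstart0)) {
    idx <- seq(tstart0[i] + 1, tend0[i])
    depth[idx] <- depth[idx] + 1
  }
  evalS <- excl + 1; evalE <- chromLen - excl
  if (evalE - evalS + 1 < step)
    return(data.frame(start = integer(), end = integer(), mean = numeric()))
  starts <- seq(evalS, evalE, by = step)
  ends <- pmin(starts + window - 1, evalE)
  keep <- (ends - starts + 1) >= step
  starts <- starts[keep]; ends <- ends[keep]
  means <- vapply(seq_along(starts),
                  function(j) mean(depth[starts[j]:ends[j]]), 0)
  data.frame(start = starts, end = ends, mean = means)
}

# group flagged windows by checking the kinds of every intervening window
oracleClassify <- function(starts, ends, means, meanDepth, low = 0.5,
                           high = 2.5, mergeGap = 0) {
  ratio <- means / meanDepth
  kind <- ifelse(ratio < low, "low", ifelse(ratio > high, "high", "none"))
  fl <- which(kind != "none")
  if (!length(fl))
    return(data.frame(start = integer(), end = integer(),
                      kind = character(), ratio = numeric(), n = integer()))
  grp <- integer(length(fl)); grp[1L] <- 1L
  for (j in seq_along(fl)[-1L]) {
    a <- fl[j - 1L]; b <- fl[j]
    between <- if (b - a > 1L) kind[seq(a + 1L, b - 1L)] else character()
    same <- kind[a] == kind[b] && all(between == "none") &&
      length(between) <= mergeGap
    grp[j] <- if (same) grp[j - 1L] else grp[j - 1L] + 1L
  }
  do.call(rbind, lapply(split(fl, grp), function(idx) data.frame(
    start = min(starts[idx]), end = max(ends[idx]), kind = kind[idx[1L]],
    ratio = if (kind[idx[1L]] == "low") min(ratio[idx]) else max(ratio[idx]),
    n = length(idx))))
}

# scan every offset for an exact motif match, then chain by gap
oracleMotifRuns <- function(seqchar, motif, maxInterruption) {
  w <- nchar(motif)
  n <- nchar(seqchar)
  hits <- integer(0)
  for (i in seq_len(max(0L, n - w + 1L)))
    if (substr(seqchar, i, i + w - 1L) == motif) hits <- c(hits, i)
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  runs <- list(c(hits[1L], hits[1L] + w - 1L))
  for (h in hits[-1L]) {
    last <- runs[[length(runs)]]
    if (h - last[2L] - 1L <= maxInterruption)
      runs[[length(runs)]][2L] <- h + w - 1L
    else runs[[length(runs) + 1L]] <- c(h, h + w - 1L)
  }
  data.frame(start = vapply(runs, `[`, 0, 1L),
             end = vapply(runs, `[`, 0, 2L))
}

# per-read evaluation of the three triage predicates
oracleSelectReads <- function(df, gapStart, gapEnd, chromLen, region,
                              minHomolog, minIdentity) {
  lo <- max(0, gapStart - region); hi <- min(chromLen, gapEnd + region)
  sel <- character(0)
  for (i in seq_len(nrow(df))) {
    inter <- df$tstart[i] < hi && df$tend[i] > lo
    span <- (df$tend[i] - df$tstart[i]) >= minHomolog
    ident <- (df$nmatch[i] / df$alen[i]) >= minIdentity
    if (inter && span && ident) sel <- c(sel, df$qname[i])
  }
  sort(unique(sel))
}

oracleAcceptPatch <- function(df, acceptOverlap, acceptIdentity) {
  df <- df[df$isPrimary, , drop = FALSE]
  if (!nrow(df)) return(list(accepted = FALSE, bestOverlap = 0))
  span <- df$tend - df$tstart
  ident <- df$nmatch / df$alen
  best <- order(-span, -ident, df$tstart)[1L]
  list(accepted = span[best] >= acceptOverlap &&
         ident[best] >= acceptIdentity,
       bestOverlap = span[best], bestIdentity = ident[best])
}

oracleFilterBlocks <- function(df, minBlock) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df)))
    keep[i] <- df$isPrimary[i] && (df$tend[i] - df$tstart[i]) >= minBlock
  out <- df[keep, , drop = FALSE]
  out[order(out$tname, out$tstart), , drop = FALSE]
}

# per-base union / intersection of flagged interval sets over a universe
oracleCombine <- function(sets, mode, universe) {
  member <- lapply(sets, function(iv) {
    m <- logical(universe)
    for (i in seq_len(nrow(iv))) m[seq(iv$start[i], iv$end[i])] <- TRUE
    m
  })
  comb <- Reduce(if (mode == "union") `|` else `&`, member)
  r <- rle(comb)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# --- randomized instance generators -----------------------------------------

randPafDf <- function(n, nReads = max(2L, n %/% 2L), chromLen = 200000,
                      nChrom = 3L) {
  qlen <- sample(2000:30000, n, replace = TRUE)
  lead <- sample(0:1500, n, replace = TRUE)
  trail <- sample(0:1500, n, replace = TRUE)
  qstart <- pmin(lead, qlen - 1)
  qend <- pmax(qstart + 1, qlen - trail)
  maxSpan <- max(1001, min(40000, chromLen - 1))
  span <- sample(1000:maxSpan, n, replace = TRUE)
  tstart <- vapply(span, function(s) sample.int(chromLen - s, 1L) - 1L, 0L)
  alen <- pmax(span, qend - qstart)
  data.frame(
    qname = sprintf("r%02d", sample.int(nReads, n, replace = TRUE)),
    qlen = qlen, qstart = qstart, qend = qend,
    strand = sample(c("+", "-"), n, replace = TRUE),
    tname = sprintf("c%d", sample.int(nChrom, n, replace = TRUE)),
    tlen = rep(chromLen, n), tstart = tstart, tend = tstart + span,
    nmatch = floor(alen * runif(n, 0.5, 1)), alen = alen,
    mapq = rep(60, n), isPrimary = runif(n) < 0.7,
    readType = sample(c("hifi", "ont"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

asPaf <- function(df) {
  pafAlignments(df$qname, df$qlen, df$qstart, df$qend, df$strand, df$tname,
                df$tlen, df$tstart, df$tend, df$nmatch, df$alen, df$mapq,
                df$isPrimary, df$readType)
}

randDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
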