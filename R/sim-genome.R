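#' Simulate a toy truth genome
#'
#' Builds `nChroms` chromosomes, each: a left `CCTAA` telomeric array, unique
#' random sequence carrying a few identical interspersed repeat copies, one
#' central tandem array of a shared repeat family, and a right `TTAGG` array.
#' Both repeat families are shared across chromosomes. The layout is
#' deterministic under `seed`, and the returned feature track tiles every
#' chromosome exactly.
#'
#' @param params a [SimParams-class].
#' @param seed integer seed; the same seed reproduces identical sequences.
#' @return A [SimGenome-class] object.
#' @examples
#' g <- simulateGenome(simParams(nChroms = 2, chromLen = 2e5,
#'                               repeatUnitLen = 10000, repeatCopies = 3),
#'                     seed = 1)
#' assemblySeq(g)
#' @export
simulateGenome <- function(params = simParams(), seed = 1L) {
  stopifnot(is(params, "SimParams"))
  withSeed(seed, {
    n <- params@nChroms
    L <- params@chromLen
    tel <- params@telomereLen
    unit <- .randDna(params@repeatUnitLen)
    interEl <- .randDna(params@intersperseLen)
    arrLen <- params@repeatUnitLen * params@repeatCopies
    seqs <- character(n)
    featL <- list()
    for (i in seq_len(n)) {
      chrom <- sprintf("chr%d", i)
      arrStart <- floor(L / 2 - arrLen / 2) + 1
      occupied <- IRanges(c(1, arrStart, L - tel + 1),
                          c(tel, arrStart + arrLen - 1, L))
      interStarts <- integer(0)
      if (params@intersperseCopies > 0) {
        cand <- floor(L * c(0.15, 0.25, 0.75, 0.85))[
          seq_len(params@intersperseCopies)]
        interStarts <- sort(cand)
        ir <- IRanges(interStarts, interStarts + params@intersperseLen - 1)
        if (any(IRanges::overlapsAny(ir, occupied)))
          .stopf("layout infeasible: interspersed copies collide")
      }
      feat <- data.frame(start = c(1, L - tel + 1), end = c(tel, L),
                         kind = "telomere", copy = NA_integer_)
      feat <- rbind(feat, data.frame(
        start = arrStart + (seq_len(params@repeatCopies) - 1) *
          params@repeatUnitLen,
        end = arrStart + seq_len(params@repeatCopies) *
          params@repeatUnitLen - 1,
        kind = "tandem_repeat", copy = seq_len(params@repeatCopies)))
      if (length(interStarts))
        feat <- rbind(feat, data.frame(
          start = interStarts, end = interStarts + params@intersperseLen - 1,
          kind = "interspersed_repeat", copy = NA_integer_))
      feat <- feat[order(feat$start), , drop = FALSE]
      # unique fill between planted features
      gapsS <- c(1, feat$end + 1); gapsE <- c(feat$start - 1, L)
      uq <- data.frame(start = gapsS, end = gapsE)
      uq <- uq[uq$start <= uq$end, , drop = FALSE]
      if (nrow(uq))
        feat <- rbind(feat, data.frame(start = uq$start, end = uq$end,
                                       kind = "unique", copy = NA_integer_))
      feat <- feat[order(feat$start), , drop = FALSE]
      piece <- vapply(seq_len(nrow(feat)), function(j) {
        w <- feat$end[j] - feat$start[j] + 1
        switch(feat$kind[j],
               telomere = if (feat$start[j] == 1)
                 strrep("CCTAA", w / 5) else strrep("TTAGG", w / 5),
               tandem_repeat = unit,
               interspersed_repeat = interEl,
               unique = .randDna(w))
      }, "")
      seqs[i] <- paste(piece, collapse = "")
      featL[[i]] <- cbind(chrom = chrom, feat)
    }
    names(seqs) <- sprintf("chr%d", seq_len(n))
    fdf <- do.call(rbind, featL)
    features <- GRanges(fdf$chrom, IRanges(fdf$start, fdf$end),
                        kind = fdf$kind, copy = fdf$copy,
                        seqlengths = stats::setNames(rep(L, n), names(seqs)))
    new("SimGenome", assembly = DNAStringSet(seqs), features = features,
        params = params)
  })
}

.randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @describeIn SimGenome-class the truth chromosome sequences.
#' @export
setMethod("assemblySeq", "SimGenome", function(x) x@assembly)

#' @describeIn SimGenome-class the feature tiling (`telomere`,
#'   `tandem_repeat`, `interspersed_repeat`, `unique`).
#' @export
setMethod("genomeFeatures", "SimGenome", function(x) x@features)

setMethod("show", "SimGenome", function(object) {
  cat(sprintf("SimGenome: %d chromosome(s) of %s bp\n",
              length(object@assembly),
              .fmtNum(object@params@chromLen)))
})

.eventRow <- function(chrom, start, end, kind, copies = NA_integer_,
                      partnerChrom = NA_character_, partnerPos = NA_real_) {
  GRanges(chrom, IRanges(start, end), kind = kind, copies = copies,
          partnerChrom = partnerChrom, partnerPos = partnerPos)
}

#' Truth-event constructors
#'
#' Build injectable assembly errors in truth coordinates (1-based closed).
#' Events returned by these constructors share a metadata schema and can be
#' concatenated with `c()` and passed to [injectErrors()].
#'
#' * `deletionEvent` removes `start..end` (a missing region / misjoin).
#' * `collapseEvent` replaces `copies` tandem copies occupying `start..end`
#'   with the single last copy (a collapsed repeat); the interval width must
#'   be a multiple of `copies`.
#' * `expansionEvent` duplicates `start..end` in place.
#' * `inversionEvent` reverse-complements `start..end`.
#' * `chimericJoinEvent` swaps the tails of two chromosomes: corrupted `chromA`
#'   is `chromA[1..posA] + chromB[posB+1..]` and vice versa.
#'
#' @param chrom,start,end event location in truth coordinates.
#' @param copies tandem copy count collapsed to one.
#' @param chromA,posA,chromB,posB chimeric-join breakpoints.
#' @return A `GRanges` with metadata columns `kind`, `copies`,
#'   `partnerChrom`, `partnerPos`.
#' @name truth-events
NULL

#' @rdname truth-events
#' @export
deletionEvent <- function(chrom, start, end)
  .eventRow(chrom, start, end, "deletion")

#' @rdname truth-events
#' @export
collapseEvent <- function(chrom, start, end, copies) {
  if ((end - start + 1) %% copies != 0)
    .stopf("collapse interval must be a multiple of 'copies'")
  if (copies < 2) .stopf("collapse needs at least 2 copies")
  .eventRow(chrom, start, end, "collapse", copies = as.integer(copies))
}

#' @rdname truth-events
#' @export
expansionEvent <- function(chrom, start, end)
  .eventRow(chrom, start, end, "expansion")

#' @rdname truth-events
#' @export
inversionEvent <- function(chrom, start, end)
  .eventRow(chrom, start, end, "inversion")

#' @rdname truth-events
#' @export
chimericJoinEvent <- function(chromA, posA, chromB, posB)
  .eventRow(chromA, posA, posA, "chimeric_join", partnerChrom = chromB,
            partnerPos = posB)

#' @rdname truth-events
#' @param ... event `GRanges` from the constructors above.
#' @export
truthEvents <- function(...) suppressWarnings(c(...))

#' Inject assembly errors into a truth genome
#'
#' Applies non-overlapping truth events to the genome and returns the
#' corrupted assembly together with a truth-to-corrupted segment map (the
#' liftover the alignment simulator uses) and the events expressed in
#' corrupted coordinates. Removed tandem copies are recorded as alias
#' segments mapping onto the surviving copy, so reads drawn from any copy
#' later align onto the survivor — the mechanism that turns a collapse into
#' a depth gain.
#'
#' @param genome a [SimGenome-class] or `DNAStringSet` truth assembly.
#' @param events a `GRanges` of events from the [truth-events] constructors.
#' @return A [CorruptedAssembly-class] object.
#' @seealso [truthAlign()], [liftTruthToCorrupted()]
#' @export
injectErrors <- function(genome, events) {
  truth <- if (is(genome, "SimGenome")) genome@assembly else genome
  stopifnot(is(truth, "DNAStringSet"), is(events, "GRanges"))
  lens <- .seqLens(truth)
  .checkEvents(events, lens)
  kinds <- mcols(events)$kind
  joins <- events[kinds == "chimeric_join"]
  others <- events[kinds != "chimeric_join"]
  pid <- 0L
  newPiece <- function(srcChrom, tstart, tend, strand = "+", emit = TRUE,
                       alias = FALSE, aliasKey = NA_integer_,
                       eventId = NA_integer_) {
    pid <<- pid + 1L
    data.frame(pieceId = pid, srcChrom = srcChrom, tstart = tstart,
               tend = tend, strand = strand, emit = emit, alias = alias,
               aliasKey = aliasKey, eventId = eventId,
               stringsAsFactors = FALSE)
  }
  eventIds <- stats::setNames(seq_along(events), NULL)
  pieces <- list()
  for (ch in names(truth)) {
    L <- lens[[ch]]
    ev <- others[as.character(seqnames(others)) == ch]
    ids <- which(kinds != "chimeric_join" &
                   as.character(seqnames(events)) == ch)
    o <- order(start(ev))
    ev <- ev[o]; ids <- ids[o]
    rows <- list()
    cur <- 1
    for (j in seq_along(ev)) {
      s <- start(ev)[j]; e <- end(ev)[j]
      kind <- mcols(ev)$kind[j]
      id <- ids[j]
      if (s > cur) rows[[length(rows) + 1L]] <- newPiece(ch, cur, s - 1)
      if (kind == "deletion") {
        # nothing survives
      } else if (kind == "collapse") {
        k <- mcols(ev)$copies[j]
        u <- (e - s + 1) / k
        surv <- newPiece(ch, e - u + 1, e, eventId = id)
        for (cp in seq_len(k - 1L))
          rows[[length(rows) + 1L]] <- newPiece(
            ch, s + (cp - 1) * u, s + cp * u - 1, emit = FALSE, alias = TRUE,
            aliasKey = surv$pieceId, eventId = id)
        rows[[length(rows) + 1L]] <- surv
      } else if (kind == "expansion") {
        rows[[length(rows) + 1L]] <- newPiece(ch, s, e, eventId = id)
        rows[[length(rows) + 1L]] <- newPiece(ch, s, e, alias = TRUE,
                                              eventId = id)
      } else if (kind == "inversion") {
        rows[[length(rows) + 1L]] <- newPiece(ch, s, e, strand = "-",
                                              eventId = id)
      } else .stopf("unknown event kind '%s'", kind)
      cur <- e + 1
    }
    if (cur <= L) rows[[length(rows) + 1L]] <- newPiece(ch, cur, L)
    pieces[[ch]] <- do.call(rbind, rows)
  }
  # chimeric joins: swap tails between two piece lists
  for (j in seq_along(joins)) {
    chA <- as.character(seqnames(joins))[j]
    posA <- start(joins)[j]
    chB <- mcols(joins)$partnerChrom[j]
    posB <- mcols(joins)$partnerPos[j]
    id <- which(kinds == "chimeric_join")[j]
    a <- .splitPieces(pieces[[chA]], chA, posA)
    b <- .splitPieces(pieces[[chB]], chB, posB)
    pieces[[chA]] <- rbind(a$head, b$tail)
    pieces[[chB]] <- rbind(b$head, a$tail)
    attr(pieces[[chA]], "junction") <- c(attr(pieces[[chA]], "junction"),
                                         stats::setNames(posA, id))
    attr(pieces[[chB]], "junction") <- c(attr(pieces[[chB]], "junction"),
                                         stats::setNames(posB, id))
  }
  # corrupted sequences and the chunk table
  chunkL <- list()
  corrSeqs <- vector("list", length(pieces))
  names(corrSeqs) <- names(pieces)
  for (ch in names(pieces)) {
    pp <- pieces[[ch]]
    w <- pp$tend - pp$tstart + 1
    corrEndAll <- cumsum(ifelse(pp$emit, w, 0))
    corrStart <- ifelse(pp$emit, corrEndAll - w + 1, NA_real_)
    corrEnd <- ifelse(pp$emit, corrEndAll, NA_real_)
    # alias pieces inherit the corrupted interval of their target piece
    for (i in which(!is.na(pp$aliasKey))) {
      tgt <- which(pp$pieceId == pp$aliasKey[i])
      corrStart[i] <- corrStart[tgt]; corrEnd[i] <- corrEnd[tgt]
    }
    chunkL[[ch]] <- data.frame(
      truthChrom = pp$srcChrom, truthStart = pp$tstart, truthEnd = pp$tend,
      corrChrom = ch, corrStart = corrStart, corrEnd = corrEnd,
      strand = pp$strand, alias = pp$alias, emit = pp$emit,
      eventId = pp$eventId, stringsAsFactors = FALSE)
    parts <- lapply(which(pp$emit), function(i) {
      s <- Biostrings::subseq(truth[[pp$srcChrom[i]]], pp$tstart[i],
                              pp$tend[i])
      if (pp$strand[i] == "-") reverseComplement(s) else s
    })
    corrSeqs[[ch]] <- if (length(parts) > 1L) do.call(Biostrings::xscat,
                                                      parts)
                      else if (length(parts)) parts[[1L]]
                      else DNAString("")
  }
  chunks <- do.call(rbind, chunkL)
  rownames(chunks) <- NULL
  corrupted <- DNAStringSet(corrSeqs)
  obj <- new("CorruptedAssembly", assembly = corrupted, chunks = chunks,
             alignChunks = .mergeChunks(chunks),
             truthRegions = GRanges())
  obj@truthRegions <- .eventRegions(obj, events, pieces)
  obj
}

.checkEvents <- function(events, lens) {
  if (!length(events)) return(invisible())
  need <- c("kind", "copies", "partnerChrom", "partnerPos")
  if (!all(need %in% names(mcols(events))))
    .stopf("events must come from the truth-event constructors")
  unknown <- setdiff(as.character(seqnames(events)), names(lens))
  if (length(unknown))
    .stopf("event on unknown chromosome: %s", unknown[1L])
  if (any(end(events) > lens[as.character(seqnames(events))]))
    .stopf("event extends beyond its chromosome")
  # occupied footprint, joins contributing both breakpoints
  occ <- granges(events)
  isJoin <- mcols(events)$kind == "chimeric_join"
  if (any(isJoin)) {
    jp <- events[isJoin]
    occ <- suppressWarnings(
      c(occ, GRanges(mcols(jp)$partnerChrom,
                     IRanges(mcols(jp)$partnerPos, mcols(jp)$partnerPos))))
  }
  hits <- findOverlaps(occ, occ)
  if (length(hits) > length(occ))
    .stopf("events overlap in truth coordinates")
  invisible()
}

#' @importFrom GenomicRanges granges
NULL

# Split a piece list between truth positions pos and pos+1; the breakpoint
# must fall inside an untouched (event-free, forward) piece.
.splitPieces <- function(pp, chrom, pos) {
  cand <- which(pp$emit & !pp$alias & pp$strand == "+" &
                  is.na(pp$eventId) & pp$srcChrom == chrom &
                  pp$tstart <= pos & pp$tend >= pos)
  if (length(cand) != 1L)
    .stopf("chimeric-join breakpoint at %s:%s is not in untouched sequence",
           chrom, .fmtNum(pos))
  i <- cand
  before <- pp[seq_len(i - 1L), , drop = FALSE]
  after <- if (i < nrow(pp)) pp[seq(i + 1L, nrow(pp)), , drop = FALSE]
           else pp[0L, , drop = FALSE]
  headPart <- pp[i, , drop = FALSE]; headPart$tend <- pos
  tailPart <- pp[i, , drop = FALSE]; tailPart$tstart <- pos + 1
  tail <- if (tailPart$tstart <= tailPart$tend) rbind(tailPart, after)
          else after
  list(head = rbind(before, headPart), tail = tail)
}

# merge truth- and corrupted-contiguous '+' chunks into maximal mappable
# segments: the map reads are lifted through
.mergeChunks <- function(chunks) {
  ck <- chunks[order(chunks$truthChrom, chunks$truthStart, chunks$corrStart),
               , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(ck))) {
    row <- ck[i, ]
    if (!is.null(cur) &&
        cur$truthChrom == row$truthChrom &&
        cur$strand == "+" && row$strand == "+" &&
        cur$corrChrom == row$corrChrom &&
        row$truthStart == cur$truthEnd + 1 &&
        row$corrStart == cur$corrEnd + 1) {
      cur$truthEnd <- row$truthEnd
      cur$corrEnd <- row$corrEnd
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row[, c("truthChrom", "truthStart", "truthEnd", "corrChrom",
                     "corrStart", "corrEnd", "strand")]
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.eventRegions <- function(obj, events, pieces) {
  if (!length(events)) {
    gr <- GRanges(seqlengths = .seqLens(obj@assembly))
    mcols(gr) <- DataFrame(kind = character(), eventId = integer())
    return(gr)
  }
  ck <- obj@chunks
  lens <- .seqLens(obj@assembly)
  rows <- list()
  add <- function(chrom, s, e, kind, id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = max(1, s), end = min(lens[[chrom]], e),
      kind = kind, eventId = id)
  }
  kinds <- mcols(events)$kind
  for (id in seq_along(events)) {
    kind <- kinds[id]
    ch <- as.character(seqnames(events))[id]
    s <- start(events)[id]; e <- end(events)[id]
    sub <- ck[!is.na(ck$eventId) & ck$eventId == id, , drop = FALSE]
    if (kind == "deletion") {
      p <- .liftPoint(ck, ch, s - 1)
      if (is.na(p$pos)) p <- .liftPoint(ck, ch, e + 1)
      if (!is.na(p$pos)) add(p$chrom, p$pos, p$pos + 1, kind, id)
    } else if (kind == "collapse") {
      surv <- sub[sub$emit & !sub$alias, , drop = FALSE]
      add(surv$corrChrom[1L], surv$corrStart[1L], surv$corrEnd[1L], kind, id)
    } else if (kind %in% c("expansion", "inversion")) {
      add(sub$corrChrom[1L], min(sub$corrStart), max(sub$corrEnd), kind, id)
    } else if (kind == "chimeric_join") {
      pA <- .liftPoint(ck, ch, s)
      add(pA$chrom, pA$pos, pA$pos + 1, kind, id)
      pB <- .liftPoint(ck, mcols(events)$partnerChrom[id],
                       mcols(events)$partnerPos[id])
      add(pB$chrom, pB$pos, pB$pos + 1, kind, id)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), kind = df$kind,
                eventId = df$eventId, seqlengths = lens)
  sort(gr, ignore.strand = TRUE)
}

.liftPoint <- function(chunks, chrom, pos) {
  hit <- which(!chunks$alias & chunks$truthChrom == chrom &
                 chunks$truthStart <= pos & chunks$truthEnd >= pos)
  if (!length(hit))
    return(list(chrom = NA_character_, pos = NA_real_, strand = NA_character_))
  i <- hit[1L]
  p <- if (chunks$strand[i] == "+")
    chunks$corrStart[i] + (pos - chunks$truthStart[i])
  else chunks$corrEnd[i] - (pos - chunks$truthStart[i])
  list(chrom = chunks$corrChrom[i], pos = p, strand = chunks$strand[i])
}

#' Lift truth positions into corrupted coordinates
#'
#' Maps positions on the truth genome through the segment map of a corrupted
#' assembly. Positions whose primary image was removed (deleted sequence, or
#' tandem copies removed by a collapse) return `NA`.
#'
#' @param corrupted a [CorruptedAssembly-class].
#' @param chrom,pos vectors of truth chromosome ids and 1-based positions.
#' @return A `data.frame` with `corrChrom`, `corrPos`, `strand`.
#' @export
liftTruthToCorrupted <- function(corrupted, chrom, pos) {
  stopifnot(is(corrupted, "CorruptedAssembly"))
  ck <- corrupted@chunks
  res <- lapply(seq_along(pos), function(i) .liftPoint(ck, chrom[i], pos[i]))
  data.frame(corrChrom = vapply(res, `[[`, "", "chrom"),
             corrPos = vapply(res, `[[`, 0, "pos"),
             strand = vapply(res, `[[`, "", "strand"),
             stringsAsFactors = FALSE)
}

#' Lift corrupted positions back to truth coordinates
#'
#' Inverse of [liftTruthToCorrupted()] via the emitting segments (every
#' corrupted base has exactly one source).
#'
#' @param corrupted a [CorruptedAssembly-class].
#' @param chrom,pos vectors of corrupted chromosome ids and 1-based positions.
#' @return A `data.frame` with `truthChrom`, `truthPos`, `strand`.
#' @export
liftCorruptedToTruth <- function(corrupted, chrom, pos) {
  stopifnot(is(corrupted, "CorruptedAssembly"))
  ck <- corrupted@chunks[corrupted@chunks$emit, , drop = FALSE]
  res <- lapply(seq_along(pos), function(i) {
    hit <- which(ck$corrChrom == chrom[i] & ck$corrStart <= pos[i] &
                   ck$corrEnd >= pos[i])
    if (!length(hit))
      return(list(chrom = NA_character_, p = NA_real_, st = NA_character_))
    j <- hit[1L]
    p <- if (ck$strand[j] == "+")
      ck$truthStart[j] + (pos[i] - ck$corrStart[j])
    else ck$truthEnd[j] - (pos[i] - ck$corrStart[j])
    list(chrom = ck$truthChrom[j], p = p, st = ck$strand[j])
  })
  data.frame(truthChrom = vapply(res, `[[`, "", "chrom"),
             truthPos = vapply(res, `[[`, 0, "p"),
             strand = vapply(res, `[[`, "", "st"),
             stringsAsFactors = FALSE)
}

#' @describeIn CorruptedAssembly-class the corrupted sequences.
#' @export
setMethod("assemblySeq", "CorruptedAssembly", function(x) x@assembly)

#' @describeIn CorruptedAssembly-class injected events in corrupted
#'   coordinates.
#' @export
setMethod("truthRegions", "CorruptedAssembly", function(x) x@truthRegions)

#' @describeIn CorruptedAssembly-class the truth-to-corrupted segment map.
#' @export
setMethod("liftoverChunks", "CorruptedAssembly", function(x) x@chunks)

setMethod("show", "CorruptedAssembly", function(object) {
  cat(sprintf("CorruptedAssembly: %d chromosome(s), %d injected event(s)\n",
              length(object@assembly),
              length(unique(mcols(object@truthRegions)$eventId))))
})
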