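#' Select reads around a gap or chromosome end for local assembly
#'
#' A read qualifies when it has an alignment whose target interval
#' intersects the gap neighborhood — the gap extended by `region` bp on each
#' side, clamped to the chromosome — with aligned reference span
#' (`tend - tstart`) at least `minHomolog` and identity at least
#' `minIdentity`. Chromosome ends are triaged exactly like gaps, as
#' zero-length gaps at positions 0 and `chromLen` (see [triageBins()]).
#'
#' @param x a [PafAlignments-class] object (alignments on one chromosome).
#' @param gapStart,gapEnd the gap in 0-based half-open coordinates (PAF
#'   convention); `gapStart == gapEnd` denotes a chromosome-end marker.
#' @param chromLen chromosome length in bp.
#' @param params a [TriageParams-class]; its `readType` must match the
#'   alignments.
#' @return Character vector of qualifying read ids (sorted, unique).
#' @export
selectReadsForGap <- function(x, gapStart, gapEnd, chromLen,
                              params = triageParams("hifi")) {
  stopifnot(is(x, "PafAlignments"), is(params, "TriageParams"),
            gapStart <= gapEnd)
  df <- x@records
  if (nrow(df) && !all(df$readType == params@readType))
    .stopf("alignments and TriageParams disagree on read type")
  lo <- max(0, gapStart - params@region)
  hi <- min(chromLen, gapEnd + params@region)
  if (!nrow(df)) return(character())
  ok <- df$tstart < hi & df$tend > lo &
    (df$tend - df$tstart) >= params@minHomolog &
    alignmentIdentity(x) >= params@minIdentity
  sort(unique(df$qname[ok]))
}

#' Triage bins for every gap and chromosome end
#'
#' Builds one read bin per gap (from [findGaps()]) and, optionally, per
#' chromosome end, for a single read set.
#'
#' @param x a [PafAlignments-class] object (one read type, possibly spanning
#'   several chromosomes).
#' @param assembly a `DNAStringSet` or named vector of chromosome lengths.
#' @param params a [TriageParams-class].
#' @param gaps a `GRanges` of gaps (1-based closed, as from [findGaps()]);
#'   defaults to scanning `assembly` when it is a `DNAStringSet`.
#' @param includeEnds triage chromosome ends as zero-length gaps.
#' @return A `data.frame` with one row per bin: `bin` (deterministic id
#'   `chrom_start_end`, 0-based half-open), `chrom`, `gapStart`, `gapEnd`,
#'   `kind` (`"gap"`/`"end"`), `nReads`, and a list column `readIds`.
#' @export
triageBins <- function(x, assembly, params = triageParams("hifi"),
                       gaps = NULL, includeEnds = TRUE) {
  lens <- .seqLens(assembly)
  if (is.null(gaps)) {
    if (!is(assembly, "DNAStringSet"))
      .stopf("supply 'gaps' when 'assembly' is not a DNAStringSet")
    gaps <- findGaps(assembly)
  }
  sites <- data.frame(chrom = character(), s = numeric(), e = numeric(),
                      kind = character())
  if (length(gaps))
    sites <- rbind(sites, data.frame(
      chrom = as.character(seqnames(gaps)), s = start(gaps) - 1,
      e = as.numeric(end(gaps)), kind = "gap"))
  if (includeEnds)
    sites <- rbind(sites, data.frame(
      chrom = rep(names(lens), 2L),
      s = c(rep(0, length(lens)), unname(lens)),
      e = c(rep(0, length(lens)), unname(lens)),
      kind = "end"))
  sites <- sites[order(sites$chrom, sites$s), , drop = FALSE]
  df <- x@records
  ids <- lapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    selectReadsForGap(x[df$tname == ch], sites$s[i], sites$e[i],
                      lens[[ch]], params)
  })
  data.frame(bin = sprintf("%s_%s_%s", sites$chrom, .fmtNum(sites$s),
                           .fmtNum(sites$e)),
             chrom = sites$chrom, gapStart = sites$s, gapEnd = sites$e,
             kind = sites$kind, nReads = lengths(ids),
             readIds = I(ids), row.names = NULL, stringsAsFactors = FALSE)
}

#' Write triage bins as FASTA files
#'
#' One FASTA per bin, named `<bin>.<readtype>.fasta`; each read is written
#' once per bin even when multiply aligned. Empty bins produce an empty file
#' with a warning.
#'
#' @param bins a `data.frame` from [triageBins()].
#' @param reads a named `DNAStringSet` of read sequences.
#' @param outdir output directory (created if needed).
#' @param readType label used in file names.
#' @return Character vector of file paths, invisibly.
#' @export
writeBins <- function(bins, reads, outdir, readType = "hifi") {
  stopifnot(is.data.frame(bins), is(reads, "DNAStringSet"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  missing <- setdiff(unique(unlist(bins$readIds)), names(reads))
  if (length(missing))
    .stopf("read sequence(s) missing from FASTA: %s",
           paste(utils::head(missing, 10), collapse = ","))
  paths <- character(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    ids <- bins$readIds[[i]]
    path <- file.path(outdir, sprintf("%s.%s.fasta", bins$bin[i], readType))
    if (!length(ids)) {
      .warnf("bin '%s' is empty", bins$bin[i])
      file.create(path)
    } else {
      writeXStringSet(reads[ids], path)
    }
    paths[i] <- path
  }
  invisible(paths)
}

#' Validate a candidate patch contig against the reference
#'
#' Judges one locally assembled contig from its alignments back to the
#' reference: the best primary alignment (largest target span; ties broken
#' by higher identity, then smaller target start) must span at least
#' `acceptOverlap` with identity at least `acceptIdentity`. When the gap is
#' supplied, the action is `fill` if qualifying alignments flank it on both
#' sides, `extend` if on one side only, `reject` otherwise; without a gap an
#' accepted contig is reported as `fill`.
#'
#' @param x a [PafAlignments-class] object — all records for one candidate
#'   contig (sharing `qname`) against the reference.
#' @param params a [TriageParams-class] for the platform route.
#' @param gap optional numeric `c(start, end)` of the target gap, 0-based
#'   half-open.
#' @param chain treat the contig's primary alignments as one chained match:
#'   overlap becomes the summed target span and identity the
#'   length-weighted identity, for aligners that split a long match into
#'   colinear pieces. Default uses the single best alignment.
#' @return A one-row `data.frame`: `contig`, `accepted`, `bestOverlap`,
#'   `bestIdentity`, `action`.
#' @examples
#' ctg <- pafAlignments("tig1", 2e5, 0, 1e5, "+", "c1", 1e6, 5e5, 6e5,
#'                      94000, 1e5, 60, TRUE, "ont")
#' acceptPatch(ctg, triageParams("ont"))   # 100 kb at 94%: accepted
#' @export
acceptPatch <- function(x, params = triageParams("hifi"), gap = NULL,
                        chain = FALSE) {
  stopifnot(is(x, "PafAlignments"), is(params, "TriageParams"))
  df <- x@records
  contig <- if (nrow(df)) unique(df$qname) else NA_character_
  if (length(contig) > 1L)
    .stopf("acceptPatch expects alignments of a single contig")
  df <- df[df$isPrimary, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(contig = contig, accepted = FALSE, bestOverlap = 0,
                      bestIdentity = NA_real_, action = "reject",
                      stringsAsFactors = FALSE))
  span <- df$tend - df$tstart
  ident <- df$nmatch / df$alen
  if (chain) {
    span <- rep(sum(span), nrow(df))
    ident <- rep(sum(df$nmatch) / sum(df$alen), nrow(df))
  }
  best <- order(-span, -ident, df$tstart)[1L]
  accepted <- span[best] >= params@acceptOverlap &&
    ident[best] >= params@acceptIdentity
  action <- "reject"
  if (accepted) {
    if (is.null(gap)) action <- "fill"
    else {
      qual <- span >= params@acceptOverlap & ident >= params@acceptIdentity
      leftOf <- any(df$tstart[qual] < gap[1L])
      rightOf <- any(df$tend[qual] > gap[2L])
      action <- if (leftOf && rightOf) "fill" else "extend"
    }
  }
  data.frame(contig = contig, accepted = accepted,
             bestOverlap = as.numeric(span[best]),
             bestIdentity = ident[best], action = action,
             stringsAsFactors = FALSE)
}
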