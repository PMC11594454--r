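#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges Views viewMeans coverage
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps reduce
#' @importFrom GenomeInfoDb seqlengths
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet matchPattern vmatchPattern reverseComplement
#'   alphabetFrequency extractAt
NULL

.READ_TYPES <- c("hifi", "ont")

.paf_cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
               "tstart", "tend", "nmatch", "alen", "mapq", "isPrimary",
               "readType")

#' Full-length alignment policy
#'
#' Holds the per-platform tolerances for unaligned read ends that still count
#' as a full-length ("perfectly mapped") alignment: a read qualifies when both
#' the leading (`query_start`) and trailing (`query_len - query_end`) unaligned
#' stubs are at most the tolerance for its read type. Defaults are 200 bp for
#' HiFi reads and 1 kb for ultra-long ONT reads.
#'
#' @slot endToleranceHifi Maximum unaligned bases at each end of a HiFi read.
#' @slot endToleranceOnt Maximum unaligned bases at each end of an ONT read.
#' @aliases FullLengthPolicy
#' @exportClass FullLengthPolicy
setClass("FullLengthPolicy",
  representation(endToleranceHifi = "numeric", endToleranceOnt = "numeric"),
  prototype(endToleranceHifi = 200, endToleranceOnt = 1000))

setValidity("FullLengthPolicy", function(object) {
  for (s in c("endToleranceHifi", "endToleranceOnt")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      return(sprintf("'%s' must be a single non-negative number", s))
  }
  TRUE
})

#' @rdname FullLengthPolicy-class
#' @param hifi,ont end tolerances in bp.
#' @return A `FullLengthPolicy` object.
#' @examples
#' fullLengthPolicy()          # 200 bp HiFi, 1000 bp ONT
#' fullLengthPolicy(ont = 500)
#' @export
fullLengthPolicy <- function(hifi = 200, ont = 1000) {
  new("FullLengthPolicy", endToleranceHifi = hifi, endToleranceOnt = ont)
}

#' Parameters for windowed perfect-read depth classification
#'
#' Geometry and thresholds for the perfect-read-coverage error scan: mean
#' per-base depth of full-length reads is computed in sliding windows
#' (default 50 kb, step 25 kb) over each chromosome with the terminal
#' 20 kb excluded, and each window's ratio to the per-chromosome mean depth
#' is compared against a correctness band (default 0.5-2.5x). Windows below
#' the band flag candidate misjoins or missing sequence; windows above it
#' flag candidate collapsed repeats.
#'
#' @slot window Window width in bp.
#' @slot step Step between window starts in bp (`0 < step <= window`).
#' @slot endExclusion Bases excluded at each chromosome end.
#' @slot lowRatio Windows with depth ratio strictly below this are `low`.
#' @slot highRatio Windows with depth ratio strictly above this are `high`.
#' @slot mergeGap Number of unflagged windows tolerated between two flagged
#'   windows of the same kind when merging them into one region.
#' @aliases PbdParams
#' @exportClass PbdParams
setClass("PbdParams",
  representation(window = "numeric", step = "numeric",
                 endExclusion = "numeric", lowRatio = "numeric",
                 highRatio = "numeric", mergeGap = "numeric"),
  prototype(window = 50000, step = 25000, endExclusion = 20000,
            lowRatio = 0.5, highRatio = 2.5, mergeGap = 0))

setValidity("PbdParams", function(object) {
  if (object@step <= 0 || object@step > object@window)
    return("need 0 < step <= window")
  if (object@endExclusion < 0)
    return("endExclusion must be >= 0")
  if (object@lowRatio < 0 || object@lowRatio >= object@highRatio)
    return("need 0 <= lowRatio < highRatio")
  if (object@mergeGap < 0)
    return("mergeGap must be >= 0")
  TRUE
})

#' @rdname PbdParams-class
#' @param window,step,endExclusion,lowRatio,highRatio,mergeGap see slots.
#' @return A `PbdParams` object.
#' @examples
#' pbdParams()                                  # study-scale geometry
#' pbdParams(window = 5000, step = 2500, endExclusion = 2000)  # toy scale
#' @export
pbdParams <- function(window = 50000, step = 25000, endExclusion = 20000,
                      lowRatio = 0.5, highRatio = 2.5, mergeGap = 0) {
  new("PbdParams", window = window, step = step, endExclusion = endExclusion,
      lowRatio = lowRatio, highRatio = highRatio, mergeGap = mergeGap)
}

#' Parameters for the telomere completeness criterion
#'
#' A chromosome end is called complete when a telomeric motif run overlaps the
#' terminal window (default 10 kb) by at least `minRun` bases (default
#' 2.5 kb). The right end is scanned for the insect telomere pentamer
#' (default `TTAGG`), the left end for its reverse complement (`CCTAA`), so
#' both scans run on the forward strand of the assembly. `blockCount` in the
#' resulting calls counts non-overlapping matches of the pentamer repeated
#' five times (a 25-bp block) inside the terminal window.
#'
#' @slot motif The right-end telomeric pentamer.
#' @slot terminalWindow Terminal window size in bp.
#' @slot minRun Minimum run overlap with the terminal window, in bp.
#' @slot maxInterruption Maximum gap in bp between consecutive motif matches
#'   chained into one run (0 demands a pure tandem array).
#' @aliases TelomereParams
#' @exportClass TelomereParams
setClass("TelomereParams",
  representation(motif = "character", terminalWindow = "numeric",
                 minRun = "numeric", maxInterruption = "numeric"),
  prototype(motif = "TTAGG", terminalWindow = 10000, minRun = 2500,
            maxInterruption = 100))

setValidity("TelomereParams", function(object) {
  if (length(object@motif) != 1L || nchar(object@motif) != 5L)
    return("motif must be a single pentamer")
  if (!grepl("^[ACGT]+$", object@motif))
    return("motif must be over A/C/G/T")
  if (object@minRun > object@terminalWindow)
    return("minRun must be <= terminalWindow")
  if (object@maxInterruption < 0)
    return("maxInterruption must be >= 0")
  TRUE
})

#' @rdname TelomereParams-class
#' @param motif,terminalWindow,minRun,maxInterruption see slots.
#' @return A `TelomereParams` object.
#' @export
telomereParams <- function(motif = "TTAGG", terminalWindow = 10000,
                           minRun = 2500, maxInterruption = 100) {
  new("TelomereParams", motif = motif, terminalWindow = terminalWindow,
      minRun = minRun, maxInterruption = maxInterruption)
}

#' Parameters for local-assembly read triage and patch validation
#'
#' Thresholds governing which reads are pooled for local re-assembly around a
#' gap or chromosome end, and when a candidate patch contig is accepted
#' against the reference. A read qualifies for a bin when it has an alignment
#' intersecting the gap neighborhood (`region` bp of flank on each side) with
#' aligned reference span at least `minHomolog` and identity at least
#' `minIdentity`. A patch contig is accepted when its best primary alignment
#' spans at least `acceptOverlap` with identity at least `acceptIdentity`.
#' Defaults per platform: HiFi 50 kb / 8 kb / 80% selection and
#' 80 kb / 95% acceptance; ONT 200 kb / 18 kb / 80% selection and
#' 100 kb / 94% acceptance.
#'
#' @slot readType `"hifi"` or `"ont"`.
#' @slot region Flank in bp around the gap/end defining the neighborhood.
#' @slot minHomolog Minimum aligned reference span in bp for read selection.
#' @slot minIdentity Minimum alignment identity for read selection.
#' @slot acceptOverlap Minimum best alignment span in bp to accept a patch.
#' @slot acceptIdentity Minimum identity of that alignment to accept a patch.
#' @aliases TriageParams
#' @exportClass TriageParams
setClass("TriageParams",
  representation(readType = "character", region = "numeric",
                 minHomolog = "numeric", minIdentity = "numeric",
                 acceptOverlap = "numeric", acceptIdentity = "numeric"))

setValidity("TriageParams", function(object) {
  if (!object@readType %in% .READ_TYPES)
    return("readType must be 'hifi' or 'ont'")
  for (s in c("region", "minHomolog", "acceptOverlap")) {
    if (slot(object, s) <= 0) return(sprintf("'%s' must be positive", s))
  }
  for (s in c("minIdentity", "acceptIdentity")) {
    v <- slot(object, s)
    if (v <= 0 || v > 1) return(sprintf("'%s' must be in (0, 1]", s))
  }
  TRUE
})

#' @rdname TriageParams-class
#' @param readType `"hifi"` or `"ont"`; chooses the per-platform defaults.
#' @param region,minHomolog,minIdentity,acceptOverlap,acceptIdentity
#'   overrides for individual thresholds.
#' @return A `TriageParams` object.
#' @examples
#' triageParams("hifi")
#' triageParams("ont")
#' @export
triageParams <- function(readType = c("hifi", "ont"), region = NULL,
                         minHomolog = NULL, minIdentity = NULL,
                         acceptOverlap = NULL, acceptIdentity = NULL) {
  readType <- match.arg(readType)
  def <- if (readType == "hifi") {
    list(region = 50000, minHomolog = 8000, minIdentity = 0.80,
         acceptOverlap = 80000, acceptIdentity = 0.95)
  } else {
    list(region = 200000, minHomolog = 18000, minIdentity = 0.80,
         acceptOverlap = 100000, acceptIdentity = 0.94)
  }
  new("TriageParams", readType = readType,
      region = region %||% def$region,
      minHomolog = minHomolog %||% def$minHomolog,
      minIdentity = minIdentity %||% def$minIdentity,
      acceptOverlap = acceptOverlap %||% def$acceptOverlap,
      acceptIdentity = acceptIdentity %||% def$acceptIdentity)
}

#' Parameters for the misassembly simulator
#'
#' Describes the toy genomes and read sets the simulator generates: each
#' chromosome carries a left `CCTAA` telomeric array, a central tandem repeat
#' array (one shared family), a few interspersed repeat copies, unique
#' sequence elsewhere, and a right `TTAGG` array. Read profiles follow the
#' study's data: HiFi-like reads (lognormal, mean 15 kb, minimum 5 kb) and
#' ultra-long ONT-like reads (mean 90 kb, minimum 50 kb), at per-platform
#' depths (defaults 85.8x and 133.7x).
#'
#' @slot nChroms Number of chromosomes.
#' @slot chromLen Chromosome length in bp.
#' @slot telomereLen Telomere array length per end (multiple of 5).
#' @slot repeatUnitLen Tandem repeat unit length in bp.
#' @slot repeatCopies Tandem copies planted per chromosome.
#' @slot intersperseLen Interspersed element length in bp.
#' @slot intersperseCopies Interspersed copies per chromosome (at most 4).
#' @slot depth Named fold-coverage vector (`hifi`, `ont`).
#' @slot readLengthMean Named mean read length vector.
#' @slot readLengthMin Named minimum read length vector.
#' @slot readLengthSdlog Lognormal sdlog of read lengths.
#' @aliases SimParams
#' @exportClass SimParams
setClass("SimParams",
  representation(nChroms = "numeric", chromLen = "numeric",
                 telomereLen = "numeric", repeatUnitLen = "numeric",
                 repeatCopies = "numeric", intersperseLen = "numeric",
                 intersperseCopies = "numeric", depth = "numeric",
                 readLengthMean = "numeric", readLengthMin = "numeric",
                 readLengthSdlog = "numeric"))

setValidity("SimParams", function(object) {
  if (object@nChroms < 1) return("nChroms must be >= 1")
  if (object@telomereLen %% 5 != 0)
    return("telomereLen must be a multiple of the pentamer length")
  if (object@chromLen <= 2 * object@telomereLen)
    return("chromLen must exceed twice telomereLen")
  arr <- object@repeatUnitLen * object@repeatCopies
  if (arr + 2 * object@telomereLen + 2 * object@intersperseLen *
        object@intersperseCopies >= object@chromLen)
    return("repeat layout does not fit in chromLen")
  if (object@intersperseCopies > 4)
    return("at most 4 interspersed copies are supported")
  for (s in c("depth", "readLengthMean", "readLengthMin")) {
    v <- slot(object, s)
    if (!all(.READ_TYPES %in% names(v)))
      return(sprintf("'%s' must be named with 'hifi' and 'ont'", s))
    if (any(v[.READ_TYPES] <= 0)) return(sprintf("'%s' must be positive", s))
  }
  if (object@readLengthSdlog <= 0) return("readLengthSdlog must be positive")
  TRUE
})

#' @rdname SimParams-class
#' @param nChroms,chromLen,telomereLen,repeatUnitLen,repeatCopies,intersperseLen,intersperseCopies,depth,readLengthMean,readLengthMin,readLengthSdlog
#'   see slots.
#' @return A `SimParams` object.
#' @examples
#' simParams(nChroms = 2, chromLen = 5e5)
#' @export
simParams <- function(nChroms = 3, chromLen = 1e6, telomereLen = 10000,
                      repeatUnitLen = 50000, repeatCopies = 4,
                      intersperseLen = 2000, intersperseCopies = 4,
                      depth = c(hifi = 85.8, ont = 133.7),
                      readLengthMean = c(hifi = 15000, ont = 90000),
                      readLengthMin = c(hifi = 5000, ont = 50000),
                      readLengthSdlog = 0.35) {
  new("SimParams", nChroms = nChroms, chromLen = chromLen,
      telomereLen = telomereLen, repeatUnitLen = repeatUnitLen,
      repeatCopies = repeatCopies, intersperseLen = intersperseLen,
      intersperseCopies = intersperseCopies, depth = depth,
      readLengthMean = readLengthMean, readLengthMin = readLengthMin,
      readLengthSdlog = readLengthSdlog)
}

#' Read-to-assembly alignments in PAF semantics
#'
#' A validated table of pairwise alignments with the mandatory PAF columns
#' plus primary/secondary status (from the `tp:A` tag) and the sequencing
#' platform of the read. Query and target intervals keep the PAF convention:
#' 0-based, half-open. Use [readPaf()] to build one from a file and
#' [pafAlignments()] to build one from vectors.
#'
#' @slot records A `data.frame` with columns `qname`, `qlen`, `qstart`,
#'   `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`,
#'   `mapq`, `isPrimary`, `readType`.
#' @aliases PafAlignments
#' @exportClass PafAlignments
setClass("PafAlignments", representation(records = "data.frame"))

setValidity("PafAlignments", function(object) {
  df <- object@records
  miss <- setdiff(.paf_cols, names(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (!all(df$readType %in% .READ_TYPES))
    return("readType must be 'hifi' or 'ont'")
  if (!is.logical(df$isPrimary) || anyNA(df$isPrimary))
    return("isPrimary must be logical and non-missing")
  if (any(df$qstart < 0 | df$qstart >= df$qend | df$qend > df$qlen))
    return("need 0 <= qstart < qend <= qlen")
  if (any(df$tstart < 0 | df$tstart >= df$tend | df$tend > df$tlen))
    return("need 0 <= tstart < tend <= tlen")
  if (any(df$nmatch < 0 | df$nmatch > df$alen))
    return("need 0 <= nmatch <= alen")
  if (any(df$mapq < 0 | df$mapq > 255)) return("mapq must be in 0..255")
  TRUE
})

#' Result of a perfect-read coverage scan
#'
#' Bundles, for one read set, the evaluated coverage windows (with mean
#' perfect-read depth and its ratio to the chromosome mean), the
#' per-chromosome mean depths, and the flagged regions after merging.
#'
#' @slot windows `GRanges` of evaluated windows with metadata columns
#'   `meanCov` and `ratio`.
#' @slot flagged `GRanges` of merged flagged regions with metadata columns
#'   `kind` (`"low"`/`"high"`), `ratio` (extreme window ratio inside the
#'   region) and `nWindows`.
#' @slot meanDepth Named numeric, mean perfect-read depth per chromosome over
#'   the evaluated region.
#' @slot readType Which read set was scanned.
#' @slot params The `PbdParams` used.
#' @aliases PbdResult
#' @exportClass PbdResult
setClass("PbdResult",
  representation(windows = "GRanges", flagged = "GRanges",
                 meanDepth = "numeric", readType = "character",
                 params = "PbdParams"))

#' Telomere census of an assembly
#'
#' Per chromosome-end motif-run calls and the derived completeness summary.
#'
#' @slot calls A `data.frame` with one row per chromosome end: `chrom`,
#'   `side`, `runStart`, `runEnd` (1-based coordinates of the best motif run,
#'   `NA` when no motif was found), `runInWindow` (bases of that run inside
#'   the terminal window), `blockCount` (non-overlapping 25-bp pentamer-block
#'   matches in the terminal window) and `complete`.
#' @slot params The `TelomereParams` used.
#' @aliases TelomereCensus
#' @exportClass TelomereCensus
setClass("TelomereCensus",
  representation(calls = "data.frame", params = "TelomereParams"))

#' A simulated truth genome
#'
#' @slot assembly `DNAStringSet` of truth chromosomes.
#' @slot features `GRanges` tiling each chromosome with `kind`
#'   (`telomere`/`tandem_repeat`/`interspersed_repeat`/`unique`) and, for
#'   tandem copies, the 1-based `copy` index.
#' @slot params The `SimParams` used.
#' @aliases SimGenome
#' @exportClass SimGenome
setClass("SimGenome",
  representation(assembly = "DNAStringSet", features = "GRanges",
                 params = "SimParams"))

#' A corrupted assembly with its truth liftover
#'
#' Produced by [injectErrors()]: the corrupted sequences, the truth-to-
#' corrupted segment map ("chunks"), and the injected events expressed in
#' corrupted coordinates.
#'
#' @slot assembly `DNAStringSet` of corrupted chromosomes.
#' @slot chunks Segment map: one row per corrupted (or aliased) segment with
#'   `truthChrom`, `truthStart`, `truthEnd`, `corrChrom`, `corrStart`,
#'   `corrEnd` (all 1-based closed), `strand`, `alias` (TRUE when the truth
#'   interval's primary image lies elsewhere, e.g. removed tandem copies
#'   mapping onto the surviving copy), `emit` (TRUE when the segment
#'   contributes corrupted sequence) and `eventId`.
#' @slot alignChunks Chunks merged across truth- and corrupted-contiguous
#'   neighbours; the map used to lift reads into alignments.
#' @slot truthRegions `GRanges` on the corrupted assembly marking each
#'   injected event (`kind`, `eventId`) — breakpoints for deletions and
#'   chimeric joins, affected intervals otherwise.
#' @aliases CorruptedAssembly
#' @exportClass CorruptedAssembly
setClass("CorruptedAssembly",
  representation(assembly = "DNAStringSet", chunks = "data.frame",
                 alignChunks = "data.frame", truthRegions = "GRanges"))
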