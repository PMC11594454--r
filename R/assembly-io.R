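#' Read an assembly FASTA
#'
#' Loads a multi-record FASTA (plain or gzipped) as an uppercase
#' `DNAStringSet` over the five-letter alphabet `{A,C,G,T,N}`. Lowercase
#' input is uppercased; any other letter — including `U` and IUPAC ambiguity
#' codes other than `N` — is rejected rather than silently converted, because
#' downstream coverage and motif scans assume the five-letter alphabet.
#' Record ids are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` named by sequence id.
#' @seealso [findGaps()], [writeAssembly()]
#' @export
readAssembly <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  bad <- FALSE
  x <- withCallingHandlers(
    tryCatch(readDNAStringSet(path),
             error = function(e) .stopf("invalid FASTA '%s': %s", path,
                                        conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        bad <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (bad)
    .stopf("'%s' contains sequence letters outside the DNA alphabet", path)
  if (length(x) == 0L) .stopf("empty FASTA: %s", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(names(x)))) .stopf("empty sequence id in %s", path)
  if (anyDuplicated(names(x)))
    .stopf("duplicate id in %s: %s", path,
           names(x)[duplicated(names(x))][1L])
  if (any(BiocGenerics::width(x) < 1L)) .stopf("zero-length sequence in %s", path)
  af <- alphabetFrequency(x)
  extra <- af[, setdiff(colnames(af), c("A", "C", "G", "T", "N")), drop = FALSE]
  if (any(extra > 0))
    .stopf("'%s' contains letters other than A/C/G/T/N (ambiguity codes are rejected)",
           path)
  x
}

#' Write an assembly FASTA
#'
#' @param x a `DNAStringSet`.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
writeAssembly <- function(x, path, width = 80L) {
  writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Locate assembly gaps (N runs)
#'
#' Finds maximal runs of `N` of at least `minRun` bases in each chromosome.
#' A gap is any such run; the default `minRun = 1` counts every N.
#'
#' @param assembly a `DNAStringSet` (or single `DNAString`).
#' @param minRun minimum run length in bp (>= 1).
#' @return A sorted `GRanges` (1-based closed) of gaps, with `seqlengths`
#'   set. Gap intervals on a chromosome never overlap or abut.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "ACGTNNNNNACGT"))
#' findGaps(g)   # one 5-bp gap at 5..9
#' @export
findGaps <- function(assembly, minRun = 1L) {
  if (is(assembly, "DNAString"))
    assembly <- DNAStringSet(stats::setNames(list(assembly), "seq"))
  stopifnot(is(assembly, "DNAStringSet"))
  if (minRun < 1L) .stopf("minRun must be >= 1")
  lens <- .seqLens(assembly)
  hits <- vmatchPattern("N", assembly, fixed = TRUE)
  per <- lapply(seq_along(assembly), function(i) {
    r <- IRanges::reduce(hits[[i]])
    r[BiocGenerics::width(r) >= minRun]
  })
  gr <- GRanges(rep(names(assembly), vapply(per, length, 0L)),
                do.call(c, c(per, list(IRanges()))),
                seqlengths = lens)
  sort(gr)
}

#' Gap census
#'
#' Per-chromosome gap counts and total gapped bases.
#'
#' @inheritParams findGaps
#' @return A list with `gaps` (the [findGaps()] `GRanges`) and `summary`
#'   (a `data.frame` with `chrom`, `nGaps`, `gapBases`, including zero rows
#'   for gapless chromosomes).
#' @export
gapCensus <- function(assembly, minRun = 1L) {
  gaps <- findGaps(assembly, minRun)
  chroms <- names(assembly)
  cnt <- table(factor(as.character(seqnames(gaps)), levels = chroms))
  bases <- vapply(chroms, function(ch)
    sum(BiocGenerics::width(gaps[seqnames(gaps) == ch])), 0)
  list(gaps = gaps,
       summary = data.frame(chrom = chroms, nGaps = as.integer(cnt),
                            gapBases = as.numeric(bases),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Write intervals as BED5
#'
#' Writes a `GRanges` as 5-column BED (0-based half-open, tab separated),
#' sorted by chromosome then start. The `name` and `score` metadata columns
#' are used when present (defaulting to `"."` and `0`); `score` may be
#' fractional (e.g. a coverage ratio). Output is byte-deterministic for
#' identical input.
#'
#' @param x a `GRanges`; zero-width ranges are an error.
#' @param path output file.
#' @param name,score optional vectors overriding the metadata columns.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path, name = NULL, score = NULL) {
  stopifnot(is(x, "GRanges"))
  if (length(x) && any(BiocGenerics::width(x) < 1L))
    .stopf("BED intervals must satisfy start < end")
  name <- name %||% mcols(x)$name %||% rep(".", length(x))
  score <- score %||% mcols(x)$score %||% rep(0, length(x))
  o <- order(as.character(seqnames(x)), start(x), end(x), method = "radix")
  lines <- sprintf("%s\t%s\t%s\t%s\t%s",
                   as.character(seqnames(x))[o], .fmtNum(start(x)[o] - 1),
                   .fmtNum(end(x)[o]), as.character(name)[o],
                   .fmtNum(as.numeric(score)[o]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED5 file
#'
#' Inverse of [writeBed()]: returns a 1-based `GRanges` with `name` and
#' `score` metadata columns.
#'
#' @param path a BED file with at least 3 columns.
#' @return A `GRanges`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GRanges(character(), IRanges(), name = character(),
                   score = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) .stopf("BED line with fewer than 3 columns")
  col <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[[i]] else default, "")
  GRanges(col(1, NA),
          IRanges(as.numeric(col(2, NA)) + 1, as.numeric(col(3, NA))),
          name = col(4, "."),
          score = as.numeric(ifelse(col(5, "0") == ".", "0", col(5, "0"))))
}

#' Write a coverage track as bedGraph
#'
#' @param windows a `GRanges` with a numeric metadata column `meanCov` (or
#'   the column named in `value`).
#' @param path output file.
#' @param value metadata column to write.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(windows, path, value = "meanCov") {
  stopifnot(is(windows, "GRanges"), value %in% names(mcols(windows)))
  o <- order(as.character(seqnames(windows)), start(windows), method = "radix")
  lines <- sprintf("%s\t%s\t%s\t%s",
                   as.character(seqnames(windows))[o],
                   .fmtNum(start(windows)[o] - 1), .fmtNum(end(windows)[o]),
                   .fmtNum(round(mcols(windows)[[value]][o], 6)))
  writeLines(lines, path)
  invisible(path)
}
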