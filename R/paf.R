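#' Construct a PafAlignments object from vectors
#'
#' @param qname,qlen,qstart,qend query name, length and 0-based half-open
#'   aligned interval on the read.
#' @param strand `"+"` or `"-"`.
#' @param tname,tlen,tstart,tend target name, length and 0-based half-open
#'   aligned interval on the assembly.
#' @param nmatch residue matches (PAF column 10).
#' @param alen alignment block length (PAF column 11).
#' @param mapq mapping quality (0-255).
#' @param isPrimary logical; `TRUE` for primary alignments (`tp:A:P`).
#' @param readType `"hifi"` or `"ont"`, recycled.
#' @return A [PafAlignments-class] object.
#' @examples
#' pafAlignments("r1", 15000, 0, 15000, "+", "c1", 5e5, 1000, 16000,
#'               14950, 15000, 60, TRUE, "hifi")
#' @export
pafAlignments <- function(qname, qlen, qstart, qend, strand, tname, tlen,
                          tstart, tend, nmatch, alen, mapq = 60L,
                          isPrimary = TRUE, readType = "hifi") {
  df <- data.frame(qname = as.character(qname), qlen = as.numeric(qlen),
                   qstart = as.numeric(qstart), qend = as.numeric(qend),
                   strand = as.character(strand),
                   tname = as.character(tname), tlen = as.numeric(tlen),
                   tstart = as.numeric(tstart), tend = as.numeric(tend),
                   nmatch = as.numeric(nmatch), alen = as.numeric(alen),
                   mapq = as.numeric(mapq), isPrimary = isPrimary,
                   readType = readType, stringsAsFactors = FALSE)
  new("PafAlignments", records = df)
}

.emptyPaf <- function() {
  pafAlignments(character(), numeric(), numeric(), numeric(), character(),
                character(), numeric(), numeric(), numeric(), numeric(),
                numeric(), numeric(), logical(), character())
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns plus the `tp:A` tag (minimap2
#' dialect): `tp:A:P` marks a primary alignment, `tp:A:S` (secondary) and
#' `tp:A:I` (inversion) mark non-primary ones. Records without a `tp` tag
#' are treated as primary, since some aligner configurations omit it; a
#' message reports how many. The read platform is supplied by the caller,
#' never inferred from the file.
#'
#' @param path a PAF file, plain or gzipped.
#' @param readType `"hifi"` or `"ont"` for every record in this file.
#' @return A [PafAlignments-class] object.
#' @seealso [writePaf()], [selectPerfect()]
#' @export
readPaf <- function(path, readType = c("hifi", "ont")) {
  readType <- match.arg(readType)
  if (!file.exists(path)) .stopf("PAF file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.emptyPaf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    .stopf("PAF line %d: fewer than 12 columns", which(nf < 12L)[1L])
  getcol <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(getcol(i)))
    if (anyNA(v))
      .stopf("PAF line %d: malformed numeric field '%s'",
             which(is.na(v))[1L], what)
    v
  }
  tp <- vapply(parts, function(p) {
    tag <- grep("^tp:A:", p[-(1:12)], value = TRUE)
    if (length(tag)) substring(tag[[1L]], 6L, 6L) else NA_character_
  }, "")
  if (anyNA(tp))
    message(sum(is.na(tp)), " PAF record(s) lack a tp:A tag; treated as primary")
  isPrimary <- is.na(tp) | tp == "P"
  pafAlignments(getcol(1), num(2, "qlen"), num(3, "qstart"), num(4, "qend"),
                getcol(5), getcol(6), num(7, "tlen"), num(8, "tstart"),
                num(9, "tend"), num(10, "nmatch"), num(11, "alen"),
                num(12, "mapq"), isPrimary, readType)
}

#' Write alignments as PAF
#'
#' Emits the 12 mandatory columns plus a `tp:A:P`/`tp:A:S` tag.
#'
#' @param x a [PafAlignments-class] object.
#' @param path output file (gzipped when the name ends in `.gz`).
#' @return `path`, invisibly.
#' @export
writePaf <- function(x, path) {
  stopifnot(is(x, "PafAlignments"))
  df <- x@records
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\ttp:A:%s",
                   df$qname, .fmtNum(df$qlen), .fmtNum(df$qstart),
                   .fmtNum(df$qend), df$strand, df$tname, .fmtNum(df$tlen),
                   .fmtNum(df$tstart), .fmtNum(df$tend), .fmtNum(df$nmatch),
                   .fmtNum(df$alen), .fmtNum(df$mapq),
                   ifelse(df$isPrimary, "P", "S"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @describeIn PafAlignments-class the underlying record table.
#' @export
setMethod("pafRecords", "PafAlignments", function(x) x@records)

#' @describeIn PafAlignments-class number of alignment records.
#' @export
setMethod("length", "PafAlignments", function(x) nrow(x@records))

#' @describeIn PafAlignments-class subset records.
#' @param i row index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PafAlignments", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE])
})

setMethod("show", "PafAlignments", function(object) {
  df <- object@records
  cat(sprintf("PafAlignments with %d record(s): %d primary, %d read(s)\n",
              nrow(df), sum(df$isPrimary), length(unique(df$qname))))
  if (nrow(df)) {
    cat(sprintf("  read types: %s; targets: %s\n",
                paste(unique(df$readType), collapse = ","),
                paste(utils::head(unique(df$tname), 5), collapse = ",")))
  }
})

#' Alignment identity
#'
#' Gap-inclusive identity of each record: residue matches (PAF column 10)
#' divided by the alignment block length (PAF column 11).
#'
#' @param x a [PafAlignments-class] object.
#' @return Numeric vector in `[0, 1]`, one value per record.
#' @export
alignmentIdentity <- function(x) {
  stopifnot(is(x, "PafAlignments"))
  df <- x@records
  if (any(df$alen == 0)) .stopf("alignment block length of 0")
  df$nmatch / df$alen
}

#' Classify alignments as full-length (perfectly mapped)
#'
#' A record is full-length when both unaligned read ends are within the
#' platform tolerance: `qstart <= tol` and `qlen - qend <= tol`, with `tol`
#' 200 bp for HiFi and 1 kb for ONT by default. Unaligned ends are measured
#' on read coordinates and are strand-independent.
#'
#' @param x a [PafAlignments-class] object.
#' @param policy a [FullLengthPolicy-class].
#' @return Logical vector, one value per record.
#' @export
isFullLength <- function(x, policy = fullLengthPolicy()) {
  stopifnot(is(x, "PafAlignments"), is(policy, "FullLengthPolicy"))
  df <- x@records
  tol <- ifelse(df$readType == "hifi",
                policy@endToleranceHifi, policy@endToleranceOnt)
  df$qstart <= tol & (df$qlen - df$qend) <= tol
}

#' Select perfectly mapped reads
#'
#' Keeps primary, full-length alignments, then resolves each read to a single
#' record: the one with the most residue matches (ties broken by smaller
#' target start, then lexicographic target name). The result is the "perfect
#' read" set on which windowed coverage is computed.
#'
#' @param x a [PafAlignments-class] object.
#' @param policy a [FullLengthPolicy-class].
#' @return A [PafAlignments-class] object with at most one record per read.
#' @examples
#' aln <- pafAlignments(c("r1", "r1"), 15000, c(0, 0), 15000, "+",
#'                      "c1", 5e5, c(0, 100000), c(15000, 115000),
#'                      c(15000, 14000), 15000, 60, c(TRUE, FALSE), "hifi")
#' length(selectPerfect(aln))  # secondary record removed
#' @export
selectPerfect <- function(x, policy = fullLengthPolicy()) {
  stopifnot(is(x, "PafAlignments"))
  keep <- x@records$isPrimary & isFullLength(x, policy)
  df <- x@records[keep, , drop = FALSE]
  if (nrow(df) > 1L) {
    o <- order(df$qname, -df$nmatch, df$tstart, df$tname, method = "radix")
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(df$qname), , drop = FALSE]
  }
  rownames(df) <- NULL
  initialize(x, records = df)
}
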