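.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-chromosome scan summary
#'
#' @param result a [PbdResult-class].
#' @return A `data.frame` with `chrom`, `meanDepth`, `nLow`, `nHigh`.
#' @export
pbdSummary <- function(result) {
  stopifnot(is(result, "PbdResult"))
  fl <- flaggedRegions(result)
  chroms <- names(meanDepth(result))
  data.frame(
    chrom = chroms,
    meanDepth = round(unname(meanDepth(result)), 3),
    nLow = vapply(chroms, function(ch)
      sum(seqnames(fl) == ch & mcols(fl)$kind == "low"), 0L),
    nHigh = vapply(chroms, function(ch)
      sum(seqnames(fl) == ch & mcols(fl)$kind == "high"), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the outputs of a multi-read-set scan
#'
#' For each read set: a bedGraph coverage track and a BED5 of flagged
#' regions (name = kind, score = extreme ratio); plus a per-chromosome TSV
#' summary and the combined cross-read-set report.
#'
#' @param results named list of [PbdResult-class] objects.
#' @param outdir output directory.
#' @param mode combination rule for [pbdReport()].
#' @return The output directory, invisibly.
#' @export
writePbdOutputs <- function(results, outdir, mode = "union") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sumL <- list()
  for (rt in names(results)) {
    res <- results[[rt]]
    writeBedGraph(coverageWindows(res),
                  file.path(outdir, sprintf("coverage.%s.bedgraph", rt)))
    fl <- flaggedRegions(res)
    writeBed(fl, file.path(outdir, sprintf("flagged.%s.bed", rt)),
             name = mcols(fl)$kind, score = round(mcols(fl)$ratio, 4))
    s <- pbdSummary(res)
    s <- cbind(readSet = rt, s)
    sumL[[rt]] <- s
  }
  .writeTsv(do.call(rbind, sumL), file.path(outdir, "pbd_summary.tsv"))
  rep <- pbdReport(results, mode = mode)
  .writeTsv(data.frame(chrom = as.character(seqnames(rep)),
                       start = start(rep) - 1, end = end(rep),
                       kind = mcols(rep)$kind,
                       provenance = mcols(rep)$provenance),
            file.path(outdir, "pbd_report.tsv"))
  writeBed(rep, file.path(outdir, "pbd_report.bed"),
           name = paste0(mcols(rep)$kind, ":", mcols(rep)$provenance),
           score = rep_len(0, length(rep)))
  invisible(outdir)
}

#' Merge module summaries into one QC report
#'
#' Collects the TSV summaries the subcommands leave in a directory
#' (`gaps_summary.tsv`, `telomere_census.tsv`, `pbd_summary.tsv`) into a
#' single per-chromosome table plus assembly-level counts.
#'
#' @param dir directory holding the module outputs.
#' @return A list with `perChromosome` (`data.frame`) and `totals` (named
#'   numeric); also written to `summary.tsv` in `dir`.
#' @export
qcReport <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p))
      utils::read.table(p, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
  }
  gaps <- rd("gaps_summary.tsv")
  tel <- rd("telomere_census.tsv")
  pbd <- rd("pbd_summary.tsv")
  chroms <- unique(c(gaps$chrom, tel$chrom, pbd$chrom))
  if (!length(chroms)) .stopf("no module summaries found in %s", dir)
  per <- data.frame(chrom = chroms, stringsAsFactors = FALSE)
  if (!is.null(gaps)) per <- merge(per, gaps, by = "chrom", all.x = TRUE)
  if (!is.null(tel)) {
    tp <- stats::aggregate(complete ~ chrom, tel, sum)
    names(tp)[2L] <- "completeTelomeres"
    per <- merge(per, tp, by = "chrom", all.x = TRUE)
  }
  if (!is.null(pbd)) {
    for (rt in unique(pbd$readSet)) {
      sub <- pbd[pbd$readSet == rt, c("chrom", "meanDepth", "nLow", "nHigh")]
      names(sub)[-1L] <- paste0(names(sub)[-1L], "_", rt)
      per <- merge(per, sub, by = "chrom", all.x = TRUE)
    }
  }
  per <- per[order(per$chrom), , drop = FALSE]
  totals <- c(chromosomes = length(chroms),
              gaps = if (!is.null(gaps)) sum(gaps$nGaps) else NA,
              telomerePairs = if (!is.null(tel))
                sum(tapply(tel$complete, tel$chrom, sum) == 2L) else NA,
              flaggedLow = if (!is.null(pbd)) sum(pbd$nLow) else NA,
              flaggedHigh = if (!is.null(pbd)) sum(pbd$nHigh) else NA)
  .writeTsv(per, file.path(dir, "summary.tsv"))
  list(perChromosome = per, totals = totals)
}
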