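mkAln <- function(tstart, tend, nmatch = NULL, alen = NULL, qname = "r1",
                  rt = "hifi", primary = TRUE, tlen = 1e6) {
  alen <- alen %||% (tend - tstart)
  nmatch <- nmatch %||% alen
  pafAlignments(qname, max(alen, 1000), 0, max(alen, 1000), "+", "c1", tlen,
                tstart, tend, nmatch, alen, 60, primary, rt)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("read selection applies the neighborhood, span and identity rules", {
  gapS <- 100000; gapE <- 100100
  # 10 kb span ending 30 kb from the gap at 90% identity: selected
  sel <- selectReadsForGap(mkAln(60000, 70000, nmatch = 9000),
                           gapS, gapE, 1e6, triageParams("hifi"))
  expect_equal(sel, "r1")
  # span one bp under the 8 kb homolog rule: rejected
  expect_length(selectReadsForGap(mkAln(60000, 67999), gapS, gapE, 1e6,
                                  triageParams("hifi")), 0L)
  expect_equal(selectReadsForGap(mkAln(60000, 68000), gapS, gapE, 1e6,
                                 triageParams("hifi")), "r1")
  # identity below 80%: rejected
  expect_length(selectReadsForGap(mkAln(60000, 70000, nmatch = 7999),
                                  gapS, gapE, 1e6, triageParams("hifi")),
                0L)
  # outside the 50 kb neighborhood: rejected
  expect_length(selectReadsForGap(mkAln(10000, 40000), gapS, gapE, 1e6,
                                  triageParams("hifi")), 0L)
})

test_that("read selection matches per-read brute force and is monotone", {
  set.seed(51)
  df <- randPafDf(200, nReads = 150, chromLen = 5e5)
  df$tname <- "c1"; df$readType <- "hifi"
  p <- triageParams("hifi", region = 30000, minHomolog = 5000)
  got <- selectReadsForGap(asPaf(df), 200000, 200500, 5e5, p)
  exp <- oracleSelectReads(df, 200000, 200500, 5e5, 30000, 5000, 0.8)
  expect_equal(got, exp)

  loose <- triageParams("hifi", region = 30000, minHomolog = 2000,
                        minIdentity = 0.6)
  expect_true(all(got %in% selectReadsForGap(asPaf(df), 200000, 200500,
                                             5e5, loose)))
})

test_that("chromosome ends are triaged as zero-length gaps", {
  g <- Biostrings::DNAStringSet(c(c1 = paste0(randDnaStr(5000),
                                              strrep("N", 50),
                                              randDnaStr(5000))))
  df <- randPafDf(40, nReads = 40, chromLen = 10050)
  df$tname <- "c1"; df$readType <- "hifi"
  df$tstart <- sample(0:5000, 40, replace = TRUE)
  df$tend <- df$tstart + sample(1000:4000, 40, replace = TRUE)
  p <- triageParams("hifi", region = 2000, minHomolog = 1000)
  bins <- triageBins(asPaf(df), g, p)
  expect_equal(nrow(bins), 3L)            # one gap + two ends
  expect_setequal(bins$kind, c("gap", "end"))
  expect_equal(bins$bin[bins$kind == "gap"], "c1_5000_5050")
  # each bin equals a direct selection call
  for (i in seq_len(nrow(bins)))
    expect_equal(bins$readIds[[i]],
                 selectReadsForGap(asPaf(df), bins$gapStart[i],
                                   bins$gapEnd[i], 10050, p))
})

test_that("bins are complete against simulator ground truth at identity 1", {
  p <- smallSimParams()
  g <- simulateGenome(p, seed = 52)
  corr <- injectErrors(g, GenomicRanges::GRanges())
  reads <- simulateReads(g, p, "hifi", seed = 53, depth = 5)
  aln <- truthAlign(reads, corr)
  tp <- triageParams("hifi", region = 20000, minHomolog = 500)
  sel <- selectReadsForGap(aln[pafRecords(aln)$tname == "chr1"],
                           100000, 100000, p@chromLen, tp)
  inside <- reads$chrom == "chr1" & reads$start >= 80001 &
    reads$end <= 120000
  expect_true(all(reads$id[inside] %in% sel))
})

test_that("bin FASTAs hold exactly the selected reads", {
  p <- smallSimParams()
  g <- simulateGenome(p, seed = 54)
  reads <- simulateReads(g, p, "hifi", seed = 55, depth = 2)
  seqs <- readSequences(g, reads)
  bins <- data.frame(bin = c("c1_0_0", "c1_9_9"), chrom = "chr1",
                     gapStart = c(0, 9), gapEnd = c(0, 9), kind = "end",
                     nReads = c(2L, 0L), stringsAsFactors = FALSE)
  bins$readIds <- list(reads$id[1:2], character(0))
  outdir <- tempfile()
  expect_warning(paths <- writeBins(bins, seqs, outdir), "empty")
  back <- Biostrings::readDNAStringSet(
    file.path(outdir, "c1_0_0.hifi.fasta"))
  expect_setequal(names(back), reads$id[1:2])
  expect_equal(file.size(file.path(outdir, "c1_9_9.hifi.fasta")), 0)

  bins$readIds <- list(c("absent_read"), character(0))
  expect_error(writeBins(bins, seqs, outdir), "absent_read")
})

test_that("patch acceptance sits exactly on the documented boundaries", {
  # ONT route: 100 kb at 94% is the accept boundary
  d <- acceptPatch(mkAln(0, 100000, nmatch = 94000, alen = 100000,
                         qname = "tig", rt = "ont"),
                   triageParams("ont"))
  expect_true(d$accepted)
  expect_false(acceptPatch(mkAln(0, 99999, nmatch = 93999, alen = 99999,
                                 qname = "tig", rt = "ont"),
                           triageParams("ont"))$accepted)
  # HiFi route: 80 kb at 94.9% fails the 95% identity rule
  expect_false(acceptPatch(mkAln(0, 80000, nmatch = 75920, alen = 80000,
                                 qname = "tig"),
                           triageParams("hifi"))$accepted)
  expect_true(acceptPatch(mkAln(0, 80000, nmatch = 76000, alen = 80000,
                                qname = "tig"),
                          triageParams("hifi"))$accepted)
  # empty stream rejects with zero overlap
  empty <- acceptPatch(mkAln(0, 1000)[0], triageParams("hifi"))
  expect_false(empty$accepted)
  expect_equal(empty$bestOverlap, 0)
  expect_equal(empty$action, "reject")
})

test_that("patch actions depend on which sides of the gap are anchored", {
  p <- triageParams("hifi")
  both <- acceptPatch(mkAln(100000, 300000, qname = "tig"), p,
                      gap = c(200000, 201000))
  expect_equal(both$action, "fill")
  one <- acceptPatch(mkAln(100000, 190000, qname = "tig"), p,
                     gap = c(200000, 201000))
  expect_equal(one$action, "extend")
})

test_that("chained acceptance sums colinear pieces", {
  p <- triageParams("hifi")
  pieces <- asPaf(data.frame(qname = "tig", qlen = 1e5, qstart = 0,
                             qend = 5e4, strand = "+", tname = "c1",
                             tlen = 1e6, tstart = c(0, 50000),
                             tend = c(50000, 95000),
                             nmatch = c(48000, 43000),
                             alen = c(50000, 45000), mapq = 60,
                             isPrimary = TRUE, readType = "hifi",
                             stringsAsFactors = FALSE))
  # single best piece is 50 kb at 96%: under the 80 kb rule
  expect_false(acceptPatch(pieces, p)$accepted)
  # chained: 95 kb at 95.8% passes
  chained <- acceptPatch(pieces, p, chain = TRUE)
  expect_true(chained$accepted)
  expect_equal(chained$bestOverlap, 95000)
  expect_equal(chained$bestIdentity, 91000 / 95000)
})

test_that("patch decisions match brute force on random candidates", {
  set.seed(56)
  for (i in 1:25) {
    df <- randPafDf(sample(1:6, 1), chromLen = 5e5)
    df$qname <- "tig"
    rt <- sample(c("hifi", "ont"), 1)
    df$readType <- rt
    p <- triageParams(rt, acceptOverlap = sample(c(20000, 35000), 1),
                      acceptIdentity = runif(1, 0.6, 0.95))
    got <- acceptPatch(asPaf(df), p)
    exp <- oracleAcceptPatch(df, p@acceptOverlap, p@acceptIdentity)
    expect_equal(got$accepted, exp$accepted)
    expect_equal(got$bestOverlap, exp$bestOverlap)
  }
})
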