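oneAln <- function(tstart, tend, chrom = "c1", tlen = 2e5, rt = "hifi") {
  w <- tend - tstart
  pafAlignments("r1", w, 0, w, "+", chrom, tlen, tstart, tend, w, w, 60,
                TRUE, rt)
}

test_that("window means equal the per-base accumulator", {
  # one alignment covering 20-120 kb of a 200 kb chromosome, study geometry
  track <- perfectCoverageTrack(oneAln(20000, 120000), "c1", 2e5,
                                pbdParams())
  expect_equal(start(track)[1], 20001)
  expect_equal(end(track)[1], 70000)
  expect_equal(track$meanCov[1], 1.0)
  w4 <- which(start(track) == 95001)
  expect_equal(track$meanCov[w4], 0.5)
  exp <- oracleWindowMeans(20000, 120000, 2e5, 50000, 25000, 20000)
  expect_equal(start(track), exp$start)
  expect_equal(end(track), exp$end)
  expect_equal(track$meanCov, exp$mean, tolerance = 1e-9)

  # zero alignments: all means zero
  none <- perfectCoverageTrack(asPaf(randPafDf(0)), "c1", 2e5, pbdParams())
  expect_true(all(none$meanCov == 0))
  expect_gt(length(none), 0)

  # 500 random intervals on a 1 Mb chromosome, scaled windows
  set.seed(31)
  s <- sample.int(1e6 - 30000, 500) - 1
  e <- s + sample(1000:30000, 500, replace = TRUE)
  df <- randPafDf(500, nReads = 500, chromLen = 1e6)
  df$tname <- "c1"; df$tstart <- s; df$tend <- e
  track <- perfectCoverageTrack(asPaf(df), "c1", 1e6, scaledParams())
  exp <- oracleWindowMeans(s, e, 1e6, 5000, 2500, 2000)
  expect_equal(track$meanCov, exp$mean, tolerance = 1e-9)
})

test_that("short chromosomes yield an empty track with a warning", {
  p <- pbdParams()
  expect_warning(track <- perfectCoverageTrack(asPaf(randPafDf(0)), "c1",
                                               60000, p),
                 "too short")
  expect_length(track, 0L)
  expect_error(chromosomeMeanDepth(track), "too short")
  expect_error(perfectCoverageTrack(oneAln(100000, 250000, tlen = 1e6),
                                    "c1", 2e5, p),
               "beyond chromosome bounds")
})

test_that("chromosome mean depth is the length-weighted window mean", {
  mkTrack <- function(means, width = 50000) {
    s <- seq(20001, by = 25000, length.out = length(means))
    gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(s, s + width - 1))
    gr$meanCov <- means
    gr
  }
  # uniform track at the study's HiFi genome coverage
  expect_equal(chromosomeMeanDepth(mkTrack(rep(85.8, 10))), 85.8)
  expect_equal(chromosomeMeanDepth(mkTrack(c(10, 30))), 20)
  set.seed(32)
  means <- runif(40, 0, 100)
  tr <- mkTrack(means)
  tr <- c(tr[1:30], GenomicRanges::resize(tr[31:40], 30000))
  tr$meanCov <- means
  w <- GenomicRanges::width(tr)
  expect_equal(chromosomeMeanDepth(tr), sum(means * w) / sum(w))
})

test_that("windows classify against the 0.5-2.5x band around 85.8x", {
  mkTrack <- function(means) {
    s <- seq(20001, by = 25000, length.out = length(means))
    gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(s, s + 49999))
    gr$meanCov <- means
    gr
  }
  fl <- classifyWindows(mkTrack(c(90, 30, 90)), 85.8, pbdParams())
  expect_equal(fl$kind, "low")
  expect_equal(fl$ratio, 30 / 85.8, tolerance = 1e-12)
  expect_length(classifyWindows(mkTrack(c(90, 90, 90)), 85.8, pbdParams()),
                0L)
  fl <- classifyWindows(mkTrack(c(90, 220, 90)), 85.8, pbdParams())
  expect_equal(fl$kind, "high")
  expect_equal(fl$ratio, 220 / 85.8, tolerance = 1e-12)
  expect_error(classifyWindows(mkTrack(90), 0, pbdParams()), "positive")

  # merging: adjacent same-kind windows merge; mergeGap bridges holes
  means <- c(90, 30, 20, 90, 25, 90, 300, 90)
  fl0 <- classifyWindows(mkTrack(means), 85.8, pbdParams())
  expect_equal(fl0$kind, c("low", "low", "high"))
  expect_equal(fl0$nWindows, c(2L, 1L, 1L))
  fl1 <- classifyWindows(mkTrack(means), 85.8, pbdParams(mergeGap = 1))
  expect_equal(fl1$kind, c("low", "high"))
  expect_equal(fl1$nWindows[1], 3L)
})

test_that("classification matches the brute-force scan on random tracks", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    means <- runif(n, 0, 60) * sample(c(1, 1, 8), n, replace = TRUE)
    md <- runif(1, 10, 50)
    mg <- sample(0:2, 1)
    s <- seq(2001, by = 2500, length.out = n)
    tr <- GenomicRanges::GRanges("c1", IRanges::IRanges(s, s + 4999))
    tr$meanCov <- means
    got <- classifyWindows(tr, md, scaledParams(mergeGap = mg))
    exp <- oracleClassify(s, s + 4999, means, md, mergeGap = mg)
    expect_equal(length(got), nrow(exp))
    if (length(got)) {
      expect_equal(start(got), exp$start)
      expect_equal(end(got), exp$end)
      expect_equal(got$kind, exp$kind)
      expect_equal(got$ratio, exp$ratio, tolerance = 1e-12)
      expect_equal(got$nWindows, exp$n)
    }
  }
})

test_that("coverage conserves aligned bases over the evaluated region", {
  set.seed(34)
  s <- sample.int(2e5 - 20000, 300) - 1
  e <- s + sample(1000:20000, 300, replace = TRUE)
  df <- randPafDf(300, nReads = 300, chromLen = 2e5)
  df$tname <- "c1"; df$tstart <- s; df$tend <- e
  p <- pbdParams(window = 5000, step = 5000, endExclusion = 2500)
  track <- perfectCoverageTrack(asPaf(df), "c1", 2e5, p)
  # non-overlapping windows tile the evaluated region exactly
  covered <- sum(track$meanCov * GenomicRanges::width(track))
  inRegion <- sum(pmax(0, pmin(e, 2e5 - 2500) - pmax(s, 2500)))
  expect_equal(covered, inRegion, tolerance = 1e-6)
})

test_that("cross-read-set reports follow union and intersection semantics", {
  hifi <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 50000),
                                 kind = "low", ratio = 0.3, nWindows = 2L)
  ont <- GenomicRanges::GRanges(character(), IRanges::IRanges(),
                                kind = character(), ratio = numeric(),
                                nWindows = integer())
  u <- pbdReport(list(hifi = hifi, ont = ont), "union")
  expect_length(u, 1L)
  expect_equal(u$provenance, "hifi")
  i <- pbdReport(list(hifi = hifi, ont = ont), "intersection")
  expect_length(i, 0L)

  # random flag sets against per-base interval algebra
  set.seed(35)
  for (rep in 1:10) {
    mk <- function() {
      n <- sample(1:6, 1)
      s <- sort(sample.int(900, n))
      iv <- data.frame(start = s * 10, end = pmin(9990, s * 10 +
                                                    sample(10:300, n, TRUE)))
      iv <- as.data.frame(GenomicRanges::reduce(
        GenomicRanges::GRanges("c1", IRanges::IRanges(iv$start, iv$end))))
      data.frame(start = iv$start, end = iv$end)
    }
    a <- mk(); b <- mk()
    sets <- list(
      hifi = GenomicRanges::GRanges("c1", IRanges::IRanges(a$start, a$end),
                                    kind = "low"),
      ont = GenomicRanges::GRanges("c1", IRanges::IRanges(b$start, b$end),
                                   kind = "low"))
    for (mode in c("union", "intersection")) {
      got <- pbdReport(sets, mode)
      exp <- oracleCombine(list(a, b), mode, 10000)
      expect_equal(start(got), exp$start)
      expect_equal(end(got), exp$end)
    }
  }
})

test_that("identical inputs give byte-identical flagged BED output", {
  scn <- simScenario(101, depth = 25)
  run <- function() {
    res <- pbdDetect(scn$aln$hifi, assemblySeq(scn$corrupted),
                     scaledParams())
    tf <- tempfile(fileext = ".bed")
    fl <- flaggedRegions(res)
    writeBed(fl, tf, name = fl$kind, score = round(fl$ratio, 4))
    readBin(tf, "raw", file.size(tf))
  }
  expect_identical(run(), run())
})
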