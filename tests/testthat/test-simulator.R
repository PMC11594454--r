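test_that("genome construction is deterministic and feature-tiled", {
  p <- smallSimParams()
  g1 <- simulateGenome(p, seed = 71)
  g2 <- simulateGenome(p, seed = 71)
  expect_identical(as.character(assemblySeq(g1)),
                   as.character(assemblySeq(g2)))
  g3 <- simulateGenome(p, seed = 72)
  expect_false(identical(as.character(assemblySeq(g1)),
                         as.character(assemblySeq(g3))))

  feat <- genomeFeatures(g1)
  for (ch in names(assemblySeq(g1))) {
    f <- feat[GenomicRanges::seqnames(feat) == ch]
    f <- f[order(GenomicRanges::start(f))]
    expect_equal(GenomicRanges::start(f)[1], 1L)
    expect_equal(GenomicRanges::end(f)[length(f)], p@chromLen)
    # consecutive features abut exactly: a disjoint tiling
    expect_true(all(GenomicRanges::start(f)[-1] ==
                      GenomicRanges::end(f)[-length(f)] + 1))
  }
  # construction guarantees full telomere pairs
  expect_equal(telomereSummary(telomereCensus(assemblySeq(g1)))$pairs,
               p@nChroms)
})

test_that("injected events change lengths by the expected arithmetic", {
  # hand-built chromosome with 3 tandem copies of a 6 kb unit
  set.seed(73)
  unit <- randDnaStr(6000)
  chrom <- paste0(randDnaStr(30000), strrep(unit, 3), randDnaStr(30000))
  truth <- Biostrings::DNAStringSet(c(c1 = chrom, c2 = randDnaStr(50000)))

  del <- injectErrors(truth, deletionEvent("c1", 10001, 19000))
  expect_equal(BiocGenerics::width(assemblySeq(del))[[1]],
               nchar(chrom) - 9000)

  col <- injectErrors(truth, collapseEvent("c1", 30001, 48000, 3))
  expect_equal(BiocGenerics::width(assemblySeq(col))[[1]],
               nchar(chrom) - 12000)
  # the surviving copy is one verbatim unit
  tr <- truthRegions(col)
  expect_equal(GenomicRanges::width(tr), 6000L)
  surv <- Biostrings::subseq(assemblySeq(col)[["c1"]],
                             GenomicRanges::start(tr),
                             GenomicRanges::end(tr))
  expect_equal(as.character(surv), unit)

  exp <- injectErrors(truth, expansionEvent("c1", 10001, 15000))
  expect_equal(BiocGenerics::width(assemblySeq(exp))[[1]],
               nchar(chrom) + 5000)

  expect_error(injectErrors(truth, suppressWarnings(c(
    deletionEvent("c1", 10001, 19000),
    inversionEvent("c1", 15000, 25000)))), "overlap")
})

test_that("a chimeric join swaps tails between chromosomes", {
  set.seed(74)
  truth <- Biostrings::DNAStringSet(c(cA = randDnaStr(40000),
                                      cB = randDnaStr(60000)))
  corr <- injectErrors(truth, chimericJoinEvent("cA", 10000, "cB", 45000))
  lens <- BiocGenerics::width(assemblySeq(corr))
  expect_equal(unname(lens), c(10000 + 15000, 45000 + 30000))
  expect_equal(as.character(Biostrings::subseq(assemblySeq(corr)[["cA"]],
                                               10001, 25000)),
               as.character(Biostrings::subseq(truth[["cB"]], 45001, 60000)))
  # junctions marked on both corrupted chromosomes
  expect_equal(sort(as.character(
    GenomicRanges::seqnames(truthRegions(corr)))), c("cA", "cB"))
})

test_that("liftover round-trips positions outside events", {
  p <- smallSimParams()
  g <- simulateGenome(p, seed = 75)
  ev <- suppressWarnings(c(deletionEvent("chr1", 50001, 60000),
                           inversionEvent("chr1", 130001, 150000)))
  corr <- injectErrors(g, ev)
  set.seed(76)
  pos <- sample(setdiff(seq_len(p@chromLen), 45000:155000), 1000)
  fwd <- liftTruthToCorrupted(corr, rep("chr1", 1000), pos)
  expect_false(anyNA(fwd$corrPos))
  back <- liftCorruptedToTruth(corr, fwd$corrChrom, fwd$corrPos)
  expect_equal(back$truthPos, pos)
  expect_true(all(back$truthChrom == "chr1"))
  # deleted positions have no image
  gone <- liftTruthToCorrupted(corr, "chr1", 55000)
  expect_true(is.na(gone$corrPos))
})

test_that("read sets hit the depth target and are seed-deterministic", {
  p <- smallSimParams()
  g <- simulateGenome(p, seed = 77)
  reads <- simulateReads(g, p, "hifi", seed = 78, depth = 20)
  genomeLen <- sum(BiocGenerics::width(assemblySeq(g)))
  total <- sum(reads$end - reads$start + 1)
  expect_gt(total, 0.95 * 20 * genomeLen)
  expect_lt(total, 1.05 * 20 * genomeLen)
  expect_identical(reads, simulateReads(g, p, "hifi", seed = 78,
                                        depth = 20))
  expect_false(identical(reads,
                         simulateReads(g, p, "hifi", seed = 79,
                                       depth = 20)))
  # sequences equal the truth substrings at the recorded coordinates
  seqs <- readSequences(g, reads[1:25, ])
  for (i in 1:25)
    expect_equal(as.character(seqs[[reads$id[i]]]),
                 as.character(Biostrings::subseq(
                   assemblySeq(g)[[reads$chrom[i]]],
                   reads$start[i], reads$end[i])))
})

test_that("truth alignment reproduces the partial-read breakpoint signature", {
  p <- smallSimParams()
  g <- simulateGenome(p, seed = 80)
  corr <- injectErrors(g, deletionEvent("chr1", 100001, 120000))
  # a read wholly inside untouched sequence aligns full-length
  whole <- data.frame(id = "w1", readType = "ont", chrom = "chr1",
                      start = 20001, end = 60000)
  rec <- pafRecords(truthAlign(whole, corr))
  expect_equal(rec$qstart, 0)
  expect_equal(rec$qend, rec$qlen)
  expect_true(isFullLength(truthAlign(whole, corr)))

  # an ONT read entering the deletion 4 kb after its 5' end keeps only the
  # 3' piece: 4000 unaligned leading bases exceed the 1 kb tolerance
  straddle <- data.frame(id = "s1", readType = "ont", chrom = "chr1",
                         start = 96001, end = 146000)
  x <- truthAlign(straddle, corr)
  df <- pafRecords(x)
  prim <- df[df$isPrimary, ]
  expect_equal(prim$qstart, 24000)  # 3' piece is longer: 26 kb vs 4 kb
  expect_false(isFullLength(x)[df$isPrimary])
  # pieces together account for the read minus the deleted 20 kb
  expect_equal(sum(df$alen), prim$qlen - 20000)

  # reads wholly inside deleted material vanish
  lost <- data.frame(id = "l1", readType = "ont", chrom = "chr1",
                     start = 102001, end = 118000)
  expect_length(truthAlign(lost, corr), 0L)
})

test_that("collapsed copies stack their reads onto the survivor", {
  # 2 tandem copies of a 30 kb unit collapse to 1; short reads fit inside
  set.seed(81)
  unit <- randDnaStr(30000)
  truth <- Biostrings::DNAStringSet(
    c(c1 = paste0(randDnaStr(50000), strrep(unit, 2), randDnaStr(50000))))
  corr <- injectErrors(truth, collapseEvent("c1", 50001, 110000, 2))
  p <- simParams(nChroms = 1, chromLen = 160000, telomereLen = 10000,
                 repeatUnitLen = 10000, repeatCopies = 2,
                 readLengthMean = c(hifi = 3000, ont = 15000),
                 readLengthMin = c(hifi = 1000, ont = 8000))
  reads <- simulateReads(truth, p, "hifi", seed = 82, depth = 40)
  perfect <- selectPerfect(truthAlign(reads, corr))
  df <- pafRecords(perfect)
  cov <- IRanges::coverage(IRanges::IRanges(df$tstart + 1, df$tend),
                           width = 130000)
  survivor <- mean(as.numeric(cov[65001:75000]))   # survivor interior
  flank <- mean(as.numeric(cov[20001:40000]))
  expect_gt(survivor / flank, 1.6)
  expect_lt(survivor / flank, 2.4)

  # conservation: aligned bases = read bases minus bases over removed copies
  aln <- truthAlign(reads, corr)
  lostPer <- pmax(0, pmin(reads$end, 80000) - pmax(reads$start, 50001) + 1)
  expect_equal(sum(pafRecords(aln)$alen),
               sum(reads$end - reads$start + 1) - 0)
  expect_gt(sum(lostPer), 0)  # the removed-copy reads still align (aliased)
})
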