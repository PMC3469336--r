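# Sequence/interval plumbing: coordinate arithmetic, window content,
# element discovery, restriction sites, BED round-trip.

test_that("interval construction enforces the fully-closed convention", {
  gr <- genomicInterval("chr2", 241151005, 241151733)
  expect_equal(intervalLength(gr), 729L)
  expect_equal(intervalLength(genomicInterval("chrX", 17, 17)), 1L)
  expect_equal(intervalLength(data.frame(start = 5, end = 9)), 5L)
  expect_error(genomicInterval("", 1, 10), "non-empty")
  expect_error(genomicInterval("chr1", 0, 10), ">= 1")
  expect_error(genomicInterval("chr1", 10, 5), ">= start")
  expect_error(intervalLength(data.frame(start = 10, end = 5)), "invalid")
})

test_that("window content matches hand counts and the clipping rule", {
  expect_equal(windowContent(strrep("G", 200), 100, 50, "GC"), 1.0)
  expect_equal(windowContent(strrep("G", 200), 100, 50, "CpG"), 0.0)
  # exact 6-bp window: 4 G/C of 6 bases; CG at slots 1 and 3 of 5
  expect_equal(windowContent("CGCGTT", 3, 6, "GC"), 4 / 6)
  expect_equal(windowContent("CGCGTT", 3, 6, "CpG"), 2 / 5)
  # window overhanging the contig start is clipped: positions 1..51
  set.seed(1)
  s <- randSeq(60)
  chars <- strsplit(s, "")[[1]]
  expect_equal(windowContent(s, 1, 100, "GC"),
               sum(chars[1:51] %in% c("G", "C")) / 51)
  expect_error(windowContent(s, 0, 10), "center")
  expect_error(windowContent(s, 61, 10), "center")
  expect_error(windowContent(s, 5, 1), "windowSize")
})

test_that("ambiguous bases drop out of numerator and denominator", {
  s <- "GGNNAATT"
  # window = whole sequence: 2 G of 6 unambiguous bases
  expect_equal(windowContent(s, 4, 8, "GC"), 2 / 6)
  expect_true(is.na(windowContent(strrep("N", 30), 15, 10, "GC")))
  # oracle agreement on an N-speckled sequence
  set.seed(7)
  sN <- paste(sample(c("A", "C", "G", "T", "N"), 400, TRUE,
                     prob = c(.3, .2, .2, .25, .05)), collapse = "")
  for (ct in c(30L, 200L, 399L)) for (m in c("GC", "CpG"))
    expect_equal(windowContent(sN, ct, 101, m),
                 naiveWindowContent(sN, ct, 101, m), info = paste(ct, m))
})

test_that("content matrix equals exhaustive substring counting", {
  set.seed(11)
  s <- randSeq(10000)
  genome <- Biostrings::DNAStringSet(c(chrA = s))
  pos <- sort(sample.int(10000, 20))
  manifest <- data.frame(probe_id = sprintf("p%02d", 1:20),
                         chrom = "chrA", pos = pos)
  ct <- buildContentMatrix(genome, manifest, windowSizes = c(50L, 500L))
  cm <- contentMatrix(ct)
  expect_identical(dim(cm), c(20L, 4L))
  expect_identical(rownames(cm), manifest$probe_id)
  for (i in 1:20) for (w in c(50L, 500L)) for (m in c("GC", "CpG"))
    expect_equal(cm[i, paste0(m, "_w", w)],
                 naiveWindowContent(s, pos[i], w, m),
                 info = paste(i, w, m))
})

test_that("content matrix shape contract and error naming the probe", {
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(chr1 = randSeq(5000)))
  manifest <- data.frame(probe_id = sprintf("p%03d", 1:100),
                         chrom = "chr1",
                         pos = sort(sample.int(5000, 100)))
  windows <- c(50L, 100L, 500L, 1000L, 2000L)
  ct <- buildContentMatrix(genome, manifest, windows)
  expect_identical(dim(contentMatrix(ct)), c(100L, 10L))
  bad <- manifest
  bad$chrom[50] <- "chrMissing"
  bad <- bad[order(bad$chrom, bad$pos), ]
  expect_error(buildContentMatrix(genome, bad, windows), "chrMissing")
  expect_error(buildContentMatrix(genome, bad, windows), "p050")
})

test_that("no elements are called on a uniform 50% GC background", {
  set.seed(5)
  expect_length(findGcElements(randSeq(50000, gc = 0.5)), 0)
  expect_error(findGcElements(randSeq(5000), minGc = 1.2), "minGc")
  expect_error(findGcElements(randSeq(5000), minGc = 0), "minGc")
})

test_that("a planted 1100 bp 73% GC block is recovered within one step", {
  set.seed(9)
  left <- randSeq(20000); right <- randSeq(20000)
  block <- randSeq(1100, gc = 0.73)
  s <- paste0(left, block, right)
  el <- findGcElements(s)
  expect_length(el, 1)
  expect_lte(abs(GenomicRanges::start(el) - 20001), 50)
  expect_lte(abs(GenomicRanges::end(el) - 21100), 50)
  # reported GC, recomputed from boundaries, respects the tolerance
  chars <- strsplit(s, "")[[1]]
  span <- GenomicRanges::start(el):GenomicRanges::end(el)
  gcRecomputed <- mean(chars[span] %in% c("G", "C"))
  expect_equal(el$gc_fraction, gcRecomputed)
  expect_gte(gcRecomputed, 0.70 - 50 / 500)
})

test_that("blocks separated by less than one step merge", {
  set.seed(13)
  s <- paste0(randSeq(5000), randSeq(900, gc = 0.85), randSeq(30),
              randSeq(900, gc = 0.85), randSeq(5000))
  el <- findGcElements(s)
  expect_length(el, 1)
  expect_gte(intervalLength(el), 1800)
})

test_that("planted high-GC blocks are always recalled", {
  # recall = 1 for blocks comfortably above threshold and >= 2x minLength
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(1:3, 1)
    gaps <- replicate(n + 1, randSeq(15000))
    blocks <- replicate(n, randSeq(1200, gc = 0.76))
    s <- paste0(paste0(gaps[seq_len(n)], blocks, collapse = ""),
                gaps[n + 1])
    el <- findGcElements(s)
    expect_length(el, n)
  }
})

test_that("restriction sites match hand patterns and the IUPAC oracle", {
  ncoI <- restrictionEnzyme("NcoI", "CCATGG", 1)
  expect_equal(findRestrictionSites("CCATGGCCATGG", ncoI), c(2L, 8L))
  expect_length(findRestrictionSites("AAAAAAAA", ncoI), 0)
  avaII <- restrictionEnzyme("AvaII", "GGWCC", 1)
  expect_equal(findRestrictionSites("GGACCTTGGTCC", avaII), c(2L, 9L))
  set.seed(21)
  s <- randSeq(20000, gc = 0.5)
  for (enz in list(ncoI, avaII, restrictionEnzyme("TaqI", "TCGA", 1)))
    expect_equal(findRestrictionSites(s, enz),
                 naiveFindSites(s, enz@recognition, enz@cutOffset),
                 info = enz@name)
  expect_error(restrictionEnzyme("bad", "CCXTGG", 1), "IUPAC")
  expect_error(restrictionEnzyme("bad", "CCATGG", 9), "cutOffset")
})

test_that("intervals round-trip losslessly through BED", {
  gr <- genomicInterval(c("chr1", "chr2"), c(1, 500), c(100, 1733),
                        label = c("a", "b"))
  gr$gc_fraction <- c(0.71, 0.84)
  path <- tempfile(fileext = ".bed")
  writeBed(gr, path, score = "gc_fraction")
  back <- readBed(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$score, gr$gc_fraction)
  # on disk: 0-based half-open
  raw <- read.delim(path, header = FALSE)
  expect_equal(raw$V2, c(0L, 499L))
  expect_equal(raw$V3, c(100L, 1733L))
})
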