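test_that("GenBank write-then-read reproduces features and sequence", {
  cfg <- fixtureConfig(seed = 3)
  sim <- simulateHistory(cfg)
  rec <- sim$records[["SelU"]]
  tf <- tempfile(fileext = ".gb")
  writeGenBank(rec, tf)
  rec2 <- readPlastome(tf)
  expect_equal(as.character(genomeSeq(rec2)), as.character(genomeSeq(rec)))
  fa <- features(rec); fb <- features(rec2)
  expect_equal(nrow(fa), nrow(fb))
  for (col in c("name", "kind", "start", "end", "strand", "copy_index",
                "host_gene"))
    expect_equal(fa[[col]], fb[[col]], info = col)
  expect_equal(lapply(fa$exons, unname), lapply(fb$exons, unname))
})

test_that("FASTA input yields an empty feature table with a warning", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", "ACGTACGTACGT"), tf)
  expect_warning(rec <- readPlastome(tf), "no feature")
  expect_equal(nrow(features(rec)), 0L)
  expect_equal(genomeLength(rec), 12L)
})

test_that("ambiguity characters other than N become N with a warning", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">amb", "ACGTRYACGT"), tf)
  expect_warning(expect_warning(rec <- readPlastome(tf), "ambiguity"),
                 "no feature")
  expect_equal(as.character(genomeSeq(rec)), "ACGTNNACGT")
})

test_that("alignment reader validates shape and alphabet", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGAAATTT", ">b", "ATGAAGTTC"), tf)
  aln <- readAlignment(tf, datatype = "codon")
  expect_s4_class(aln, "Alignment")
  expect_equal(nchar(alignedSeqs(aln)[[1]]) / 3, 3)

  writeLines(c(">a", "ATGAAATTT", ">b", "ATGAAG"), tf)
  expect_error(readAlignment(tf), "ragged")

  writeLines(c(">a", "AT!AAATTT", ">b", "ATGAAGTTC"), tf)
  expect_error(readAlignment(tf), "non-IUPAC")

  writeLines(c(">a", "ATGA", ">b", "ATGC"), tf)
  expect_error(readAlignment(tf, datatype = "codon"), "divisible")
})

test_that("gene order extraction orders by coordinate with strand signs", {
  feats <- rbind(makeFeature("a", "protein", 0L, 100L, 1L),
                 makeFeature("b", "protein", 200L, 300L, -1L),
                 makeFeature("c", "protein", 400L, 500L, 1L))
  rec <- new("PlastomeRecord", id = "toy",
             sequence = Biostrings::DNAString(strrep("ACGT", 150)),
             features = feats, source = "")
  ord <- extractGeneOrder(rec)
  expect_equal(blocks(ord), c("a", "b", "c"))
  expect_equal(signs(ord), c(1L, -1L, 1L))
})

test_that("gene order is invariant to rotation and reverse complement", {
  cfg <- fixtureConfig(seed = 3)
  sim <- simulateHistory(cfg)
  rec <- sim$records[["SelK"]]
  f0 <- features(rec)
  s <- as.character(genomeSeq(rec)); L <- nchar(s)
  off <- f0$end[1] + 5L            # inside the first intergenic spacer
  sh <- function(x) as.integer((x - off) %% L)
  f <- f0
  f$start <- sh(f$start); f$end <- sh(f$end - 1L) + 1L
  f$exons <- lapply(f$exons, function(ex) {
    ex[, 1] <- sh(ex[, 1]); ex[, 2] <- sh(ex[, 2] - 1L) + 1L; ex })
  f <- f[order(f$start), ]
  rot <- new("PlastomeRecord", id = "rot",
             sequence = Biostrings::DNAString(
               paste0(substr(s, off + 1L, L), substr(s, 1L, off))),
             features = f, source = "")
  expect_identical(blocks(extractGeneOrder(rec)),
                   blocks(extractGeneOrder(rot)))
  expect_identical(signs(extractGeneOrder(rec)),
                   signs(extractGeneOrder(rot)))

  f2 <- f0
  f2$start <- as.integer(L - f0$end); f2$end <- as.integer(L - f0$start)
  f2$strand <- -f0$strand
  f2$exons <- lapply(f0$exons, function(ex) {
    nx <- cbind(L - ex[, 2], L - ex[, 1]); nx[order(nx[, 1]), ,
                                             drop = FALSE] })
  f2 <- f2[order(f2$start), ]
  rc <- new("PlastomeRecord", id = "rc",
            sequence = Biostrings::reverseComplement(genomeSeq(rec)),
            features = f2, source = "")
  expect_identical(blocks(extractGeneOrder(rec)),
                   blocks(extractGeneOrder(rc)))
  expect_identical(signs(extractGeneOrder(rec)),
                   signs(extractGeneOrder(rc)))
})

test_that("collapsed gene order recovers the planted signed order", {
  cfg <- fixtureConfig(seed = 5)
  sim <- simulateHistory(cfg)
  for (tip in c("LycA", "SelK", "SelU")) {
    rec <- sim$records[[tip]]
    rp <- findLargeRepeat(rec)
    part <- partitionRegions(rec, rp)
    ord <- extractGeneOrder(rec, collapseRepeat = TRUE, partition = part)
    truth <- sim$truth$tipOrders[[tip]]
    expect_equal(orientationFlag(ord), orientationFlag(truth), info = tip)
    expect_equal(breakpointCount(ord, truth), 0L, info = tip)
  }
})

test_that("gene symbols normalize to the catalog convention", {
  expect_equal(normalizeGeneName(c("trnT(ggu)", "trnT-GGU", "trnT_GGU")),
               rep("trnT-GGU", 3))
  expect_equal(normalizeGeneName("16S ribosomal RNA"), "rrn16")
  expect_equal(normalizeGeneName("ycf9"), "psbZ")
})

test_that("gene-order exchange format round-trips, suffixing duplicates", {
  ords <- list(x = sgo(c("+a", "-b", "+REP", "+c"), circular = TRUE,
                       flag = "IR"))
  tf <- tempfile()
  writeGeneOrders(ords, tf)
  back <- readGeneOrders(tf)
  expect_equal(blocks(back$x), blocks(ords$x))
  expect_equal(signs(back$x), signs(ords$x))
  expect_equal(orientationFlag(back$x), "IR")

  writeLines(c(">dup none", "+a +b +a +c"), tf)
  dup <- readGeneOrders(tf)$dup
  expect_equal(blocks(dup), c("a", "b", "a#1", "c"))
})
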