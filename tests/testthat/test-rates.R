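test_that("rate-class strings parse to dense shared-parameter maps", {
  rc <- parseRateClass("012232")
  expect_equal(unname(rc$classes), c(0L, 1L, 2L, 2L, 3L, 2L))
  expect_equal(names(rc$classes), c("AC", "AG", "AT", "CG", "CT", "GT"))
  expect_equal(rc$freeCount, 4L)
  expect_equal(parseRateClass("000000")$freeCount, 1L)
  expect_equal(parseRateClass("012345")$freeCount, 6L)
  expect_equal(parseRateClass("012312")$freeCount, 4L)
  expect_error(parseRateClass("01223"), "6 digits")
  expect_error(parseRateClass("01223x"), "6 digits")
})

test_that("alignment trimming drops high-gap columns and nothing else", {
  aln <- new("Alignment", datatype = "codon",
             seqs = c(a = "ATG---AAA", b = "ATG---AAA", c = "ATGCCCAAA",
                      d = "ATG---AAA"))
  tr <- trimAlignment(aln, 0.5)
  expect_equal(unname(nchar(alignedSeqs(tr))[1]), 6L)

  clean <- new("Alignment", datatype = "codon",
               seqs = c(a = "ATGAAA", b = "ATGAAG"))
  expect_equal(alignedSeqs(trimAlignment(clean)), alignedSeqs(clean))

  set.seed(8)
  rows <- replicate(6, paste(sample(c("A", "C", "-"), 60, TRUE,
                                    prob = c(0.4, 0.3, 0.3)),
                             collapse = ""))
  names(rows) <- paste0("t", 1:6)
  gappy <- new("Alignment", seqs = rows, datatype = "nucleotide")
  out <- trimAlignment(gappy, 0.5)
  mat <- do.call(rbind, strsplit(alignedSeqs(out), ""))
  expect_true(all(colMeans(mat == "-") <= 0.5))
})

test_that("GTR limit reproduces the Jukes-Cantor closed form", {
  set.seed(1)
  n <- 5000L
  v <- sample(c("A", "C", "G", "T"), n, TRUE)
  w <- v
  for (p in sample(n, 400)) w[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   w[p]), 1)
  aln <- new("Alignment", seqs = c(t1 = paste(v, collapse = ""),
                                   t2 = paste(w, collapse = "")),
             datatype = "nucleotide")
  topo <- ape::read.tree(text = "(t1:0.1,t2:0.1);")
  fit <- estimateBranchLengthsNt(aln, topo, gammaCategories = 1L,
                                 invariant = FALSE, model = "JC")
  p <- mean(v != w)
  expect_lt(abs(sum(branchValues(fit)) + 3 / 4 * log(1 - 4 * p / 3)),
            1e-4)
})

test_that("zero-divergence alignments give zero branch lengths", {
  s <- paste(rep("ATGGCTAAAGCT", 40), collapse = "")
  aln <- new("Alignment", seqs = c(a = s, b = s, c = s, d = s),
             datatype = "codon")
  topo <- ape::read.tree(text = "((a,b),(c,d));")
  fit <- estimateBranchLengthsCodon(aln, topo, rateClass = "000000",
                                    maxIter = 2L)
  expect_true(all(branchValues(fit) < 1e-4))
})

test_that("internal stop codons are rejected with row and column", {
  aln <- new("Alignment", seqs = c(a = "ATGTAAAAA", b = "ATGGCTAAA"),
             datatype = "codon")
  topo <- ape::read.tree(text = "(a:0.1,b:0.1);")
  expect_error(estimateBranchLengthsCodon(aln, topo),
               "stop codon.*'a'.*2")
})

test_that("codon branch lengths recover simulated d_S", {
  cfg <- simulationConfig(seed = 12, omega = 0.3, gcBias = 0.42)
  topo <- ape::read.tree(text = "((A:0.12,B:0.3):0.08,(C:0.2,D:0.34):0.06);")
  sim <- evolveSequences(topo, cfg, scCodons = 2500L, repCodons = 10L,
                         ntSites = 10L)
  fit <- estimateBranchLengthsCodon(sim$sc, topo, rateClass = "012232")
  trueTips <- vapply(topo$tip.label, function(tp)
    sim$trueDs[which(topo$edge[, 2] == match(tp, topo$tip.label))], 1)
  estTips <- vapply(topo$tip.label, function(tp)
    terminalBranchValue(fit, tp), 1)
  expect_lt(max(abs(estTips - trueTips) / trueTips), 0.25)
  expect_lt(abs(sum(estTips) - sum(trueTips)) / sum(trueTips), 0.1)
})

test_that("log-likelihood is monotone in rate-class nesting", {
  cfg <- simulationConfig(seed = 13, omega = 0.4, gcBias = 0.4,
                          theta6 = c(1, 3, 0.7, 0.7, 3, 1))
  topo <- ape::read.tree(text = "((A:0.15,B:0.2):0.05,C:0.25);")
  sim <- evolveSequences(topo, cfg, scCodons = 800L, repCodons = 10L,
                         ntSites = 10L)
  ll <- vapply(c("000000", "012232", "012345"), function(cs)
    estimateBranchLengthsCodon(sim$sc, topo, rateClass = cs,
                               maxIter = 4L)@params$logLik, 1)
  expect_lte(ll[["000000"]], ll[["012232"]] + 1e-3)
  expect_lte(ll[["012232"]], ll[["012345"]] + 1e-3)
})

test_that("nucleotide branch lengths recover simulated GTR+G+I divergence", {
  cfg <- simulationConfig(seed = 14, gcBias = 0.42, gammaShape = 0.9,
                          pInv = 0.15)
  topo <- ape::read.tree(text = "((A:0.1,B:0.25):0.07,(C:0.15,D:0.3):0.05);")
  sim <- evolveSequences(topo, cfg, scCodons = 10L, repCodons = 10L,
                         ntSites = 8000L)
  fit <- estimateBranchLengthsNt(sim$nt, topo)
  trueTips <- vapply(topo$tip.label, function(tp)
    sim$trueD[which(topo$edge[, 2] == match(tp, topo$tip.label))], 1)
  estTips <- vapply(topo$tip.label, function(tp)
    terminalBranchValue(fit, tp), 1)
  expect_lt(max(abs(estTips - trueTips) / trueTips), 0.25)
  expect_lt(abs(sum(branchValues(fit)) - sum(sim$trueD)) /
              sum(sim$trueD), 0.15)
})

test_that("rate comparisons form the duplicated/single-copy ratio", {
  topo <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  topo$edge.length <- NULL
  rt <- function(vals) {
    tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
    tr$edge.length <- vals
    new("RateTree", tree = tr, branchValues = vals, model = "test",
        params = list())
  }
  a <- rt(c(0.5, 0.2, 0.4, 0.1))
  b <- rt(c(0.5, 0.4, 0.4, 0.1))
  cmp <- compareRates(a, b, "A")
  expect_equal(cmp$ratio, 0.5)
  expect_equal(compareRates(a, a, "A")$ratio, 1)
  zero <- rt(c(0.5, 0, 0.4, 0.1))
  expect_warning(cmp0 <- compareRates(a, zero, "A"), "undefined")
  expect_true(is.na(cmp0$ratio))
})
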