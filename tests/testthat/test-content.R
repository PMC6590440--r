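mkRecord <- function(seq, feats, id = "toy") {
  new("PlastomeRecord", id = id, sequence = Biostrings::DNAString(seq),
      features = feats, source = "")
}

test_that("gene status scoring applies the frameshift, stop and truncation rules", {
  ## intact: full open frame, terminal stop only
  s <- paste0("ATG", strrep("GCT", 40), "TAA")
  f <- makeFeature("psbA", "protein", 0L, nchar(s), 1L)
  rec <- mkRecord(s, f)
  expect_equal(scoreGeneStatus(f, rec, noUCEditing = TRUE), "intact")

  ## frameshift: exon lengths summing to 301 (mod 3 = 1)
  s2 <- paste0(substr(s, 1, 100), substr(s, 1, 201))
  f2 <- makeFeature("psbA", "protein", 0L, 301L, 1L)
  expect_equal(scoreGeneStatus(f2, mkRecord(paste0(s2, "AA"), f2)),
               "pseudogene")

  ## internal stops are diagnostic only without U-to-C editing
  s3 <- paste0("ATG", strrep("GCT", 10), "TAGTAG", strrep("GCT", 28),
               "TAA")
  f3 <- makeFeature("infA", "protein", 0L, nchar(s3), 1L)
  rec3 <- mkRecord(s3, f3)
  expect_equal(scoreGeneStatus(f3, rec3, noUCEditing = TRUE), "pseudogene")
  expect_equal(scoreGeneStatus(f3, rec3, noUCEditing = FALSE), "intact")

  ## substantial truncation against the reference length
  f4 <- makeFeature("rbcL", "protein", 0L, 126L, 1L)
  rec4 <- mkRecord(paste0("ATG", strrep("GCT", 40), "TAA"), f4)
  expect_equal(scoreGeneStatus(f4, rec4,
                               referenceLengths = c(rbcL = 1400)),
               "pseudogene")

  ## unannotated gene is absent
  expect_equal(scoreGeneStatus(NULL, rec4), "absent")
})

test_that("minus-strand spliced CDS are translated on the feature strand", {
  core <- paste0("ATG", strrep("CAT", 20), "TAA")
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core)))
  seq <- paste0("AAAA", rcs, "TTTT")
  f <- makeFeature("petA", "protein", 4L, 4L + nchar(core), -1L)
  st <- scoreGeneStatus(f, mkRecord(seq, f), noUCEditing = TRUE)
  expect_equal(st, "intact")
})

test_that("content matrix respects the catalog and host-gene linkage", {
  cfg <- simulationConfig(seed = 21, nInversions = 0L, lossRate = 0.1,
                          mutRate = 0)
  sim <- simulateHistory(cfg)
  cm <- buildContentMatrix(sim$records)
  st <- contentStates(cm)
  ## conservation: tips lose exactly what the history lost
  cat <- plastidGeneCatalog()
  rootGenes <- head(cat$element[cat$kind == "protein"], 36L)
  for (tip in rownames(st)) {
    lost <- unique(unlist(lapply(
      pathEvents(sim$truth, cfg$tree, tip, "losses"), identity)))
    expect_true(all(st[tip, setdiff(rootGenes, lost)] != "absent"),
                info = tip)
    if (length(lost))
      expect_true(all(st[tip, lost] == "absent"), info = tip)
  }
  ## empty record scores an all-absent row
  empty <- new("PlastomeRecord", id = "void",
               sequence = Biostrings::DNAString(strrep("ACGT", 100)),
               features = emptyFeatures(), source = "")
  cm2 <- buildContentMatrix(c(sim$records["LycA"], list(empty)))
  expect_true(all(contentStates(cm2)["void", ] %in%
                    c("absent")))
})

test_that("Sankoff DP equals exhaustive enumeration on small trees", {
  costs <- defaultLossCosts()
  set.seed(31)
  for (rep in 1:12) {
    ntip <- sample(4:8, 1)
    tr <- ape::rtree(ntip, rooted = TRUE)
    tr$tip.label <- paste0("t", seq_len(ntip))
    states <- sample(c("intact", "pseudogene", "absent"), ntip, TRUE)
    names(states) <- tr$tip.label
    cm <- new("ContentMatrix",
              states = matrix(states, ntip, 1,
                              dimnames = list(tr$tip.label, "g1")),
              elementKind = c(g1 = "protein"),
              hostGene = c(g1 = NA_character_))
    rec <- reconstructLosses(cm, tr, costs)
    expect_equal(unname(rec$cost["g1"]),
                 bruteSankoffCost(tr, states, costs$gene), info = rep)
  }
})

test_that("replaying reported events reproduces the tip matrix", {
  cm <- lycophyteContentMatrix()
  tr <- lycophyteTree()
  rec <- reconstructLosses(cm, tr)
  tips <- replayLossEvents(rec, tr)
  expect_identical(tips[rownames(contentStates(cm)),
                        colnames(contentStates(cm))],
                   contentStates(cm))
})

test_that("a 4-taxon binary character places one loss on the 0-tip branch", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  st <- c(A = "intact", B = "absent", C = "intact", D = "intact")
  cm <- new("ContentMatrix",
            states = matrix(st[tr$tip.label], 4, 1,
                            dimnames = list(tr$tip.label, "g")),
            elementKind = c(g = "protein"),
            hostGene = c(g = NA_character_))
  rec <- reconstructLosses(cm, tr)
  ev <- rec$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$branch, "B")
  expect_equal(ev$event, "loss")
  expect_true(ev$unambiguous)
})

test_that("all-intact elements produce zero events", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cm <- new("ContentMatrix",
            states = matrix("intact", 4, 1,
                            dimnames = list(tr$tip.label, "g")),
            elementKind = c(g = "protein"),
            hostGene = c(g = NA_character_))
  rec <- reconstructLosses(cm, tr)
  expect_equal(nrow(rec$events), 0L)
  expect_equal(unname(rec$cost["g"]), 0)
})

test_that("quasi-Dollo costs never gain an element twice", {
  set.seed(77)
  for (rep in 1:10) {
    tr <- ape::rtree(7)
    tr$tip.label <- paste0("t", 1:7)
    st <- sample(c("intact", "absent"), 7, TRUE,
                 prob = c(0.6, 0.4))
    names(st) <- tr$tip.label
    cm <- new("ContentMatrix",
              states = matrix(st, 7, 1,
                              dimnames = list(tr$tip.label, "g")),
              elementKind = c(g = "protein"),
              hostGene = c(g = NA_character_))
    rec <- reconstructLosses(cm, tr)
    expect_lte(sum(rec$events$event == "gain"), 1L)
  }
})

test_that("encoded lycophyte matrix reproduces published totals and placements", {
  cm <- lycophyteContentMatrix()
  tot <- contentTotals(cm)
  rownames(tot) <- tot$taxon
  expect_equal(tot[c("Dobs", "Ddig", "Lcla", "Hluc1", "Hluc2", "Hser"),
                   "genes"], rep(122, 6))
  expect_equal(tot[c("Ifla", "Imal", "Ipie"), "genes"], rep(118, 3))
  expect_equal(tot[c("Skra", "Slep", "Smoe", "Stam", "Sunc"), "genes"],
               c(85, 80, 93, 68, 93))
  expect_equal(tot[c("Dobs", "Ifla", "Stam"), "protein"], c(87, 82, 58))
  expect_equal(tot[c("Dobs", "Ifla", "Skra", "Slep", "Smoe", "Stam",
                     "Sunc"), "introns"], c(22, 21, 9, 7, 11, 7, 11))
  expect_equal(tot[c("Stam", "Skra"), "tRNA"], c(6, 10))
  expect_true(all(tot$rRNA[tot$taxon != "outgroup"] == 4))

  rec <- reconstructLosses(cm, lycophyteTree())
  ev <- rec$events
  trnT <- ev[ev$element == "trnT-GGU", ]
  expect_true("Lycopodiaceae" %in% trnT$branch)
  ndh <- ev[grepl("^ndh", ev$element), ]
  expect_true(all(c("Stam", "Slep") %in% ndh$branch))
  expect_false("Selaginella" %in% ndh$branch)
})
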