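## Synthetic plastome generator: quadripartite genomes with a two-copy
## repeat (IR or DR), signed gene orders perturbed by known inversion
## histories (including repeat-spanning inversions that toggle the
## orientation), gene/intron losses placed on a tree, and sequence
## evolution with per-branch rates where repeat-region sites undergo
## copy-correction (gene conversion) with configurable probability.
## All outputs are pure functions of the configuration including its seed.

#' @include AllClasses.R AllGenerics.R plastome-io.R rearrangement.R rates.R
NULL

#' Simulation configuration
#'
#' Collects and validates the knobs of the synthetic-data generator.
#' Defaults describe a desk-scale plastome: 40 genes of which 4 (the
#' rRNAs) sit in a large two-copy repeat in IR orientation, one inversion
#' per branch of which 30% span the repeat, a 2% per-element per-branch
#' loss rate, and full copy-correction (conversionProb = 1) with no
#' repeat rate reduction (rateReduction = 1).
#'
#' @param nBlocks total gene count including repeat genes.
#' @param repeatGenes number of genes inside the large repeat.
#' @param initialOrientation `"IR"` or `"DR"` at the root.
#' @param nInversions inversions per branch (scalar).
#' @param pSpanRepeat probability an inversion spans the repeat.
#' @param lossRate per-gene per-branch loss probability.
#' @param mutRate per-site per-branch point-mutation probability for the
#'   genome simulator.
#' @param tree a `phylo` or newick string; default is a 7-taxon clade.
#' @param rateReduction r, repeat-region substitution-rate multiplier in
#'   (0, 1].
#' @param conversionProb gamma, per-mutation probability that the two
#'   repeat copies are homogenized (direction uniform).
#' @param gcBias equilibrium GC content of simulated sequence.
#' @param omega nonsynonymous/synonymous ratio for codon simulation.
#' @param theta6 exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param gammaShape,pInv Gamma shape and invariant proportion for
#'   nucleotide simulation.
#' @param seed integer seed fixing all randomness.
#' @param plantedEvents optional named list (by child-node label) of
#'   inversion interval lists, overriding random inversions.
#' @return a validated list of class `"plastevolSimConfig"`.
#' @export
simulationConfig <- function(nBlocks = 40L, repeatGenes = 4L,
                             initialOrientation = c("IR", "DR"),
                             nInversions = 1L, pSpanRepeat = 0.3,
                             lossRate = 0.02, mutRate = 0.002,
                             tree = NULL, rateReduction = 1,
                             conversionProb = 1, gcBias = 0.38,
                             omega = 0.3,
                             theta6 = c(1, 2, 1, 1, 2, 1),
                             gammaShape = 0.8, pInv = 0.1,
                             seed = 1L, plantedEvents = NULL) {
  initialOrientation <- match.arg(initialOrientation)
  if (is.null(tree))
    tree <- "((LycA:0.02,LycB:0.02)LycAnc:0.05,((IsoA:0.03,IsoB:0.03)IsoAnc:0.04,(SelK:0.08,(SelL:0.06,SelU:0.09)SelLU:0.03)SelAnc:0.05)ISAnc:0.02);"
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"),
            nBlocks > repeatGenes + 4L, repeatGenes >= 1L,
            pSpanRepeat >= 0, pSpanRepeat <= 1,
            lossRate >= 0, lossRate <= 1,
            rateReduction > 0, rateReduction <= 1,
            conversionProb >= 0, conversionProb <= 1,
            gcBias > 0, gcBias < 1)
  cfg <- list(nBlocks = as.integer(nBlocks),
              repeatGenes = as.integer(repeatGenes),
              initialOrientation = initialOrientation,
              nInversions = nInversions, pSpanRepeat = pSpanRepeat,
              lossRate = lossRate, mutRate = mutRate, tree = tree,
              rateReduction = rateReduction,
              conversionProb = conversionProb, gcBias = gcBias,
              omega = omega, theta6 = theta6, gammaShape = gammaShape,
              pInv = pInv, seed = as.integer(seed),
              plantedEvents = plantedEvents)
  class(cfg) <- "plastevolSimConfig"
  cfg
}

randomSeqGC <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomCodingSeq <- function(nCodons, gc) {
  ## ATG + sense codons (no internal stops) + stop
  freq <- list(pos = matrix(rep(c((1 - gc) / 2, gc / 2, gc / 2,
                                  (1 - gc) / 2), each = 3), 3, 4,
                            dimnames = list(NULL,
                                            c("A", "C", "G", "T"))))
  pis <- vapply(SENSE_CODONS, function(cod) {
    b <- strsplit(cod, "")[[1]]
    freq$pos[1, b[1]] * freq$pos[2, b[2]] * freq$pos[3, b[3]]
  }, 1)
  body <- sample(SENSE_CODONS, nCodons - 2L, replace = TRUE,
                 prob = pis / sum(pis))
  paste(c("ATG", body, "TAA"), collapse = "")
}

mutateSeq <- function(s, rate) {
  L <- nchar(s)
  n <- stats::rbinom(1, L, rate)
  if (n == 0L) return(s)
  pos <- sample.int(L, n)
  v <- strsplit(s, "")[[1]]
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

## ---------------------------------------------------------------------------
## Root genome and genome state

buildRootState <- function(cfg) {
  cat <- plastidGeneCatalog()
  scNames <- head(cat$element[cat$kind == "protein"],
                  cfg$nBlocks - cfg$repeatGenes)
  repNames <- head(cat$element[cat$kind == "rRNA"], cfg$repeatGenes)
  if (length(repNames) < cfg$repeatGenes)
    repNames <- c(repNames, sprintf("rrnX%d", seq_len(cfg$repeatGenes -
                                                        length(repNames))))
  genes <- list()
  for (g in scNames) {
    nCod <- sample(120:300, 1)
    s <- randomCodingSeq(nCod, cfg$gcBias)
    intron <- NULL
    if (runif(1) < 0.2) {             # every ~5th gene carries an intron
      ilen <- sample(80:150, 1)
      at <- 3L * sample(10:(nCod - 10L), 1)
      s <- paste0(substr(s, 1, at), randomSeqGC(ilen, cfg$gcBias),
                  substr(s, at + 1L, nchar(s)))
      intron <- c(at, at + ilen)      # 0-based half-open, gene-relative
    }
    genes[[g]] <- list(seq = s, kind = "protein", intron = intron)
  }
  ## repeat unit: rRNA-style genes with spacers, local forward coords
  rseq <- ""
  rfeat <- emptyFeatures()
  for (g in repNames) {
    rseq <- paste0(rseq, randomSeqGC(sample(60:120, 1), cfg$gcBias + 0.1))
    glen <- sample(900:1600, 1)
    start <- nchar(rseq)
    rseq <- paste0(rseq, randomSeqGC(glen, cfg$gcBias + 0.12))
    rfeat <- rbind(rfeat, makeFeature(g, "rRNA", start, start + glen, 1L))
  }
  rseq <- paste0(rseq, randomSeqGC(sample(60:120, 1), cfg$gcBias + 0.1))

  nSC <- length(scNames)
  nLSC <- ceiling(nSC * 0.62)
  blocksOrd <- c(scNames[seq_len(nLSC)], "REP",
                 scNames[(nLSC + 1L):nSC])
  signsOrd <- ifelse(runif(length(blocksOrd)) < 0.8, 1L, -1L)
  signsOrd[match("REP", blocksOrd)] <- 1L
  spacers <- setNames(vapply(seq_along(blocksOrd), function(i)
    randomSeqGC(sample(100:220, 1), cfg$gcBias), ""), blocksOrd)
  order0 <- new("SignedGeneOrder", blocks = blocksOrd, signs = signsOrd,
                circular = TRUE, repeatBlock = "REP",
                orientationFlag = cfg$initialOrientation)
  list(order = order0, genes = genes, repUnit = list(seq = rseq,
                                                     feats = rfeat),
       spacers = spacers, lost = character(0), pseudo = character(0),
       lostIntrons = character(0))
}

## Apply one branch's events to a genome state; returns new state + truth.
evolveState <- function(state, cfg, branchLabel) {
  truth <- list(inversions = list(), losses = character(0),
                pseudogenized = character(0), intronLosses = character(0))
  ord <- state$order
  ## inversions
  planted <- if (!is.null(cfg$plantedEvents))
    cfg$plantedEvents[[branchLabel]] else NULL
  nInv <- if (!is.null(cfg$plantedEvents)) length(planted)
          else cfg$nInversions
  if (nInv > 0L) for (e in seq_len(nInv)) {
    m <- length(ord@blocks)
    rpos <- match("REP", ord@blocks)
    if (!is.null(planted)) {
      ij <- planted[[e]]
    } else if (runif(1) < cfg$pSpanRepeat && rpos > 2L && rpos < m) {
      i <- sample(2:rpos, 1); j <- sample(rpos:(m - 0L), 1)
      ij <- c(i, max(j, i))
    } else {
      i <- sample(2:m, 1); j <- sample(2:m, 1)
      ij <- sort(c(i, j))
    }
    spans <- rpos >= ij[1] && rpos <= ij[2]
    ord <- replayScenario(ord, new("InversionScenario",
      events = list(list(interval = ij, spansRepeat = spans, label = "")),
      distance = 1L, breakpointsInitial = 0L,
      orientationTrajectory = character(0), optimal = TRUE,
      coOptima = list()))
    truth$inversions[[e]] <- list(interval = ij, spansRepeat = spans)
  }
  state$order <- ord
  ## losses and pseudogenizations
  if (cfg$lossRate > 0) {
    liveSC <- setdiff(ord@blocks, "REP")
    for (g in liveSC) {
      if (runif(1) < cfg$lossRate) {
        if (runif(1) < 0.5) {
          keep <- ord@blocks != g
          state$order <- initialize(ord, blocks = ord@blocks[keep],
                                    signs = ord@signs[keep])
          ord <- state$order
          state$lost <- c(state$lost, g)
          truth$losses <- c(truth$losses, g)
        } else if (!(g %in% state$pseudo)) {
          ## frameshift: delete one base mid-gene
          s <- state$genes[[g]]$seq
          cut <- nchar(s) %/% 2L
          state$genes[[g]]$seq <- paste0(substr(s, 1, cut - 1L),
                                         substr(s, cut + 1L, nchar(s)))
          if (!is.null(state$genes[[g]]$intron)) {
            adj <- state$genes[[g]]$intron
            if (adj[1] >= cut) adj <- adj - 1L
            state$genes[[g]]$intron <- adj
          }
          state$pseudo <- c(state$pseudo, g)
          truth$pseudogenized <- c(truth$pseudogenized, g)
        }
      }
    }
    ## intron losses (retroprocessing-style splice-out)
    for (g in names(state$genes)) {
      gi <- state$genes[[g]]$intron
      if (!is.null(gi) && g %in% state$order@blocks &&
          runif(1) < cfg$lossRate / 2) {
        s <- state$genes[[g]]$seq
        state$genes[[g]]$seq <- paste0(substr(s, 1, gi[1]),
                                       substr(s, gi[2] + 1L, nchar(s)))
        state$genes[[g]]$intron <- NULL
        state$lostIntrons <- c(state$lostIntrons, g)
        truth$intronLosses <- c(truth$intronLosses, g)
      }
    }
  }
  ## point mutations
  if (cfg$mutRate > 0) {
    for (g in names(state$genes))
      state$genes[[g]]$seq <- mutateSeq(state$genes[[g]]$seq, cfg$mutRate)
    state$repUnit$seq <- mutateSeq(state$repUnit$seq, cfg$mutRate)
    for (b in names(state$spacers))
      state$spacers[[b]] <- mutateSeq(state$spacers[[b]], cfg$mutRate)
  }
  list(state = state, truth = truth)
}

## Assemble a PlastomeRecord (plus planted partition) from a genome state.
assembleGenome <- function(state, id) {
  ord <- state$order
  feats <- emptyFeatures()
  seqParts <- character(0)
  pos <- 0L
  addSeq <- function(s) {
    seqParts[[length(seqParts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  repA <- NULL
  for (k in seq_along(ord@blocks)) {
    b <- ord@blocks[k]; sg <- ord@signs[k]
    if (b == "REP") {
      unit <- state$repUnit
      repStr <- if (sg > 0L) unit$seq else revcompChar(unit$seq)
      Lr <- nchar(repStr)
      repA <- c(pos, pos + Lr)
      for (i in seq_len(nrow(unit$feats))) {
        f <- unit$feats[i, ]
        if (sg > 0L) {
          st <- pos + f$start; en <- pos + f$end; strand <- f$strand
        } else {
          st <- pos + Lr - f$end; en <- pos + Lr - f$start
          strand <- -f$strand
        }
        feats <- rbind(feats, makeFeature(f$name, f$kind, st, en, strand))
      }
      addSeq(repStr)
    } else {
      g <- state$genes[[b]]
      gs <- if (sg > 0L) g$seq else revcompChar(g$seq)
      Lg <- nchar(gs)
      gi <- g$intron
      if (!is.null(gi)) {
        rel <- if (sg > 0L) gi else c(Lg - gi[2], Lg - gi[1])
        exons <- rbind(c(pos, pos + rel[1]), c(pos + rel[2], pos + Lg))
        feats <- rbind(feats, makeFeature(b, g$kind, pos, pos + Lg, sg,
                                          exons = exons))
        feats <- rbind(feats, makeFeature(paste0(b, "-i1"), "intron",
                                          pos + rel[1], pos + rel[2], sg,
                                          host_gene = b))
      } else {
        feats <- rbind(feats, makeFeature(b, g$kind, pos, pos + Lg, sg))
      }
      addSeq(gs)
    }
    addSeq(state$spacers[[b]])
  }
  ## second repeat copy closes the circle
  unit <- state$repUnit
  sgRep <- ord@signs[match("REP", ord@blocks)]
  repAstr <- if (sgRep > 0L) unit$seq else revcompChar(unit$seq)
  repBstr <- if (ord@orientationFlag == "IR") revcompChar(repAstr)
             else repAstr
  Lr <- nchar(repBstr)
  repB <- c(pos, pos + Lr)
  flipB <- xor(sgRep < 0L, ord@orientationFlag == "IR")
  for (i in seq_len(nrow(unit$feats))) {
    f <- unit$feats[i, ]
    if (!flipB) {
      st <- pos + f$start; en <- pos + f$end; strand <- f$strand
    } else {
      st <- pos + Lr - f$end; en <- pos + Lr - f$start
      strand <- -f$strand
    }
    feats <- rbind(feats, makeFeature(f$name, f$kind, st, en, strand))
  }
  addSeq(repBstr)

  seqAll <- paste(seqParts, collapse = "")
  feats <- assignCopyIndex(feats)
  feats <- feats[order(feats$start, feats$end, feats$name), , drop = FALSE]
  rownames(feats) <- NULL
  rec <- new("PlastomeRecord", id = id,
             sequence = Biostrings::DNAString(seqAll),
             features = feats, source = "")
  L <- nchar(seqAll)
  rp <- new("RepeatPair", copyA = as.integer(repA),
            copyB = as.integer(repB),
            orientation = if (ord@orientationFlag == "IR") "inverted"
                          else "direct",
            identity = 1)
  arc1 <- c(repA[2], repB[1]); arc2 <- c(repB[2] - L, repA[1]) # arc2 wraps
  len1 <- diff(arc1); len2 <- repA[1]  # repB ends at L, so arc2 = [0, repA1)
  part <- if (len1 >= len2)
    new("RegionPartition", lsc = as.integer(arc1),
        ssc = c(0L, as.integer(repA[1])), repeatPair = rp,
        genomeLength = as.integer(L), degenerate = FALSE)
  else
    new("RegionPartition", lsc = c(0L, as.integer(repA[1])),
        ssc = as.integer(arc1), repeatPair = rp,
        genomeLength = as.integer(L), degenerate = FALSE)
  list(record = rec, partition = part)
}

#' Simulate a plastome history with known ground truth
#'
#' Builds a root quadripartite genome, applies inversions (repeat-spanning
#' ones flip the IR/DR orientation), gene losses/pseudogenizations and
#' intron losses along each branch of the configured tree, instantiates
#' sequences, and assembles fully annotated tip genomes. Reproducible from
#' the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `records` (named [PlastomeRecord-class] per tip) and
#'   `truth`: per-branch event lists, per-tip orders
#'   ([SignedGeneOrder-class]), orientations, planted
#'   [RegionPartition-class]s, the root order, and the tree.
#' @export
simulateHistory <- function(cfg) {
  stopifnot(inherits(cfg, "plastevolSimConfig"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  ntip <- length(tree$tip.label)
  nodeLabel <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (!is.null(tree$node.label) &&
        !is.na(tree$node.label[node - ntip]) &&
        nzchar(tree$node.label[node - ntip]))
      tree$node.label[node - ntip] else paste0("node", node)
  }
  root <- buildRootState(cfg)
  states <- list(); states[[nodeLabel(ntip + 1L)]] <- root
  truthBranches <- list()
  records <- list(); partitions <- list(); tipOrders <- list()
  childrenOf <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  walk <- function(node, state) {
    for (ch in childrenOf(node)) {
      lab <- nodeLabel(ch)
      res <- evolveState(state, cfg, lab)
      truthBranches[[lab]] <<- res$truth
      if (ch <= ntip) {
        asm <- assembleGenome(res$state, lab)
        records[[lab]] <<- asm$record
        partitions[[lab]] <<- asm$partition
        tipOrders[[lab]] <<- res$state$order
      } else walk(ch, res$state)
    }
  }
  walk(ntip + 1L, root)
  list(records = records,
       truth = list(branches = truthBranches, tipOrders = tipOrders,
                    tipOrientation = vapply(tipOrders, orientationFlag,
                                            ""),
                    partitions = partitions, rootOrder = root$order,
                    tree = tree))
}

## ---------------------------------------------------------------------------
## Sequence evolution with copy-correction

#' Simulate codon and nucleotide alignments with copy-correction
#'
#' Codon sites evolve under MG94xF3x4 (plastid code); repeat-resident
#' sites evolve at rate `rateReduction` relative to single-copy sites as a
#' two-copy system in which each mutation is homogenized between copies
#' with probability `conversionProb` (direction uniform — the IR vs DR
#' orientation does not enter). Nucleotide sites evolve under GTR+Gamma+I.
#' Branch lengths of `tree` are expected substitutions per site (per codon
#' site for codon data) for single-copy sequence.
#'
#' @param tree a `phylo` with branch lengths.
#' @param cfg a [simulationConfig()]; uses `omega`, `theta6`, `gcBias`,
#'   `rateReduction`, `conversionProb`, `gammaShape`, `pInv`, `seed`.
#' @param scCodons,repCodons,ntSites numbers of single-copy codon sites,
#'   repeat codon sites, and nucleotide sites.
#' @return list with Alignments `sc`, `rep` (copy A at each tip), `nt`,
#'   and `trueDs` / `trueDsRep` / `trueD` per-edge values (order of
#'   `tree$edge`).
#' @export
evolveSequences <- function(tree, cfg, scCodons = 2000L,
                            repCodons = 1000L, ntSites = 2000L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(deriveSeed(cfg$seed, "evolveSequences"))
  gc <- cfg$gcBias
  nt <- c("A", "C", "G", "T")
  posFreq <- matrix(rep(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
                        each = 3), 3, 4, dimnames = list(NULL, nt))
  freq <- list(pos = posFreq)
  pi <- vapply(SENSE_CODONS, function(cod) {
    b <- strsplit(cod, "")[[1]]
    posFreq[1, b[1]] * posFreq[2, b[2]] * posFreq[3, b[3]]
  }, 1)
  pi <- pi / sum(pi)
  freq$pi <- pi
  Qraw <- mg94QRaw(cfg$theta6, cfg$omega, freq)
  fl <- mg94Flux(Qraw, pi)
  Qn <- Qraw / fl["total"]            # expected subs per codon per unit t
  eg <- reversibleEigen(Qn, pi)
  ## true d_S per unit branch length (per-synonymous-site convention)
  Q1 <- mg94QRaw(cfg$theta6, 1, freq)
  fl1 <- mg94Flux(Q1, pi)
  dsPerT <- (fl["syn"] / fl["total"]) / (fl1["syn"] / fl1["total"])

  ntipn <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  edgeOrder <- rev(seq_len(nrow(po$edge)))   # preorder over po edges

  sampleStates <- function(parentStates, P) {
    out <- integer(length(parentStates))
    for (s in unique(parentStates)) {
      k <- parentStates == s
      out[k] <- sample.int(ncol(P), sum(k), replace = TRUE, prob = P[s, ])
    }
    out
  }

  ## single-copy codon evolution
  nodeSeq <- vector("list", ntipn + tree$Nnode)
  nodeSeq[[ntipn + 1L]] <- sample.int(length(pi), scCodons, replace = TRUE,
                                      prob = pi)
  for (r in edgeOrder) {
    par <- po$edge[r, 1]; ch <- po$edge[r, 2]; t <- po$edge.length[r]
    nodeSeq[[ch]] <- sampleStates(nodeSeq[[par]], probMatrix(eg, t))
  }
  scAln <- vapply(seq_len(ntipn), function(i)
    paste(SENSE_CODONS[nodeSeq[[i]]], collapse = ""), "")
  names(scAln) <- tree$tip.label

  ## repeat-pair codon evolution (Gillespie with conversion)
  r <- cfg$rateReduction; gam <- cfg$conversionProb
  rates <- -diag(Qn)
  Poff <- Qn; diag(Poff) <- 0
  evolvePairBranch <- function(a, b, t) {
    for (site in seq_along(a)) {
      tt <- 0
      repeat {
        ra <- r * rates[a[site]]; rb <- r * rates[b[site]]
        tot <- ra + rb
        if (tot <= 0) break
        tt <- tt + rexp(1, tot)
        if (tt > t) break
        onA <- runif(1) < ra / tot
        old <- if (onA) a[site] else b[site]
        new <- sample.int(length(rates), 1, prob = Poff[old, ])
        if (onA) a[site] <- new else b[site] <- new
        if (runif(1) < gam) {
          if (runif(1) < 0.5) { a[site] <- new; b[site] <- new }
          else { a[site] <- old; b[site] <- old }
        }
      }
    }
    list(a = a, b = b)
  }
  nodePair <- vector("list", ntipn + tree$Nnode)
  rootRep <- sample.int(length(pi), repCodons, replace = TRUE, prob = pi)
  nodePair[[ntipn + 1L]] <- list(a = rootRep, b = rootRep)
  for (rr in edgeOrder) {
    par <- po$edge[rr, 1]; ch <- po$edge[rr, 2]; t <- po$edge.length[rr]
    pp <- nodePair[[par]]
    nodePair[[ch]] <- evolvePairBranch(pp$a, pp$b, t)
  }
  repAln <- vapply(seq_len(ntipn), function(i)
    paste(SENSE_CODONS[nodePair[[i]]$a], collapse = ""), "")
  names(repAln) <- tree$tip.label
  repAlnB <- vapply(seq_len(ntipn), function(i)
    paste(SENSE_CODONS[nodePair[[i]]$b], collapse = ""), "")
  names(repAlnB) <- tree$tip.label

  ## nucleotide evolution under GTR + Gamma + I
  bf <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  Qg <- matrix(0, 4, 4, dimnames = list(nt, nt))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Qg[i, j] <- cfg$theta6[k] * bf[j]
    Qg[j, i] <- cfg$theta6[k] * bf[i]
  }
  diag(Qg) <- -rowSums(Qg)
  Qg <- Qg / sum(-bf * diag(Qg))
  egN <- reversibleEigen(Qg, bf)
  siteRate <- ifelse(runif(ntSites) < cfg$pInv, 0,
                     stats::rgamma(ntSites, cfg$gammaShape,
                                   cfg$gammaShape) / (1 - cfg$pInv))
  nodeNt <- vector("list", ntipn + tree$Nnode)
  nodeNt[[ntipn + 1L]] <- sample.int(4, ntSites, replace = TRUE, prob = bf)
  for (rr in edgeOrder) {
    par <- po$edge[rr, 1]; ch <- po$edge[rr, 2]; t <- po$edge.length[rr]
    child <- integer(ntSites)
    ## group sites into rate bins for speed
    bins <- cut(siteRate, breaks = c(-Inf, 0,
                                     stats::quantile(siteRate[siteRate > 0],
                                                     seq(0.1, 1, 0.1))),
                labels = FALSE, include.lowest = TRUE)
    for (bb in unique(bins)) {
      k <- which(bins == bb)
      mr <- mean(siteRate[k])
      if (mr == 0) { child[k] <- nodeNt[[par]][k]; next }
      P <- probMatrix(egN, t * mr)
      child[k] <- sampleStates(nodeNt[[par]][k], P)
    }
    nodeNt[[ch]] <- child
  }
  ntAln <- vapply(seq_len(ntipn), function(i)
    paste(nt[nodeNt[[i]]], collapse = ""), "")
  names(ntAln) <- tree$tip.label

  ## map true values back to tree$edge order
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  pokey <- paste(po$edge[, 1], po$edge[, 2])
  el <- po$edge.length[match(key, pokey)]
  list(sc = new("Alignment", seqs = scAln, datatype = "codon"),
       rep = new("Alignment", seqs = repAln, datatype = "codon"),
       repB = new("Alignment", seqs = repAlnB, datatype = "codon"),
       nt = new("Alignment", seqs = ntAln, datatype = "nucleotide"),
       trueDs = el * dsPerT,
       trueDsRep = el * dsPerT * r,
       trueD = el)
}

## ---------------------------------------------------------------------------
## Fixture set

#' Write a deterministic fixture directory
#'
#' Generates a small clade with planted structural history — a static
#' (Lycopodiaceae-style) lineage, a two-overlapping-inversion relocation
#' lineage with an IR->DR->IR trajectory, a single-inversion IR->DR
#' lineage, and a five-inversion lineage — and writes GenBank genomes, the
#' newick tree, the true gene orders (exchange format), the encoded
#' lycophyte content matrix, and the encoded published-style gene orders.
#' Byte-identical for the same seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return `dir`, invisibly; side effect: files written.
#' @export
makeFixtureSet <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fixtureConfig(seed)
  sim <- simulateHistory(cfg)
  for (id in names(sim$records))
    writeGenBank(sim$records[[id]], file.path(dir,
                                              paste0(id, ".gb")))
  ape::write.tree(cfg$tree, file.path(dir, "clade.nwk"))
  writeGeneOrders(sim$truth$tipOrders, file.path(dir, "tip_orders.txt"))
  ## encoded lycophyte references
  cm <- lycophyteContentMatrix()
  write.table(contentStates(cm),
              file.path(dir, "content_matrix_lycophytes_synthetic.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  ape::write.tree(lycophyteTree(),
                  file.path(dir, "lycophyte_tree.nwk"))
  pub <- system.file("extdata", "gene_orders_published.txt",
                     package = "plastevol")
  if (nzchar(pub))
    file.copy(pub, file.path(dir, "gene_orders_published.txt"),
              overwrite = TRUE)
  invisible(dir)
}

#' Planted-event fixture configuration
#'
#' The 7-taxon configuration behind [makeFixtureSet()]: LycA/LycB static;
#' IsoA/IsoB share two overlapping repeat-spanning inversions
#' (IR->DR->IR); SelK carries the single spanning inversion of the
#' Selaginella stem (IR->DR); SelL adds a second spanning inversion
#' (back to IR); SelU adds four more (three spanning, one not).
#'
#' @param seed integer seed.
#' @return a [simulationConfig()].
#' @export
fixtureConfig <- function(seed = 1L) {
  planted <- list(
    SelAnc = list(c(20L, 25L)),                  # spans REP at 25
    SelL = list(c(19L, 26L)),                    # spans REP (now at 20)
    SelU = list(c(16L, 21L),                     # spans REP at 20
                c(30L, 33L),                     # SSC-internal
                c(14L, 22L),                     # spans REP at 17
                c(19L, 24L)),                    # spans REP at 19
    IsoAnc = list(c(22L, 25L),                   # spans REP at 25
                  c(22L, 24L)))                  # spans REP at 22
  simulationConfig(nBlocks = 40L, repeatGenes = 4L,
                   initialOrientation = "IR", nInversions = 0L,
                   lossRate = 0, mutRate = 0.001, seed = seed,
                   plantedEvents = planted)
}
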