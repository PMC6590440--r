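## Signed gene-order rearrangement: breakpoint counts, exact reversal
## distances, explicit minimal inversion scenarios with IR/DR orientation
## bookkeeping, and parsimony placement of inversions on a tree.
##
## Engine: the target order is renamed so the source becomes a signed
## permutation, which is sorted by iterative-deepening A* over reversals.
## The admissible heuristic is the breakpoint-graph cycle bound
## max(ceil(b/2), n+1-c), tight for hurdle-free permutations (the
## overwhelming majority at these sizes); the search is exact regardless.
## Circular orders are linearized by fixing the source's leading block, the
## standard circular-to-linear reduction: for a circular genome, any
## reversal spanning the fixed block is equivalent to the reversal of the
## complementary interval, so no optimal scenario is lost.

#' @include AllClasses.R AllGenerics.R plastome-io.R
NULL

## ---------------------------------------------------------------------------
## Signed permutation primitives

applyReversalInt <- function(p, i, j) {
  p[i:j] <- -rev(p[i:j])
  p
}

## Unsigned doubling: +x -> (2x-1, 2x); -x -> (2x, 2x-1); flanked by 0 and
## 2n+1.
signedToU <- function(p) {
  n <- length(p)
  a <- abs(p)
  lo <- ifelse(p > 0, 2L * a - 1L, 2L * a)
  hi <- ifelse(p > 0, 2L * a, 2L * a - 1L)
  u <- integer(2L * n)
  u[seq(1L, 2L * n, 2L)] <- lo
  u[seq(2L, 2L * n, 2L)] <- hi
  c(0L, u, 2L * n + 1L)
}

## Breakpoint count of a linear signed permutation vs identity (frame
## adjacencies at both ends included).
breakpointsInt <- function(p) {
  u <- signedToU(p)
  n <- length(p)
  left <- u[seq(1L, 2L * n + 1L, 2L)]
  right <- u[seq(2L, 2L * n + 2L, 2L)]
  ## an adjacency slot is conserved iff its values are consecutive with the
  ## even value first in rank: {2k, 2k+1} read in either direction
  sum(!(abs(left - right) == 1L & pmin(left, right) %% 2L == 0L))
}

## Number of cycles in the breakpoint graph (identity has n+1).
cycleCountInt <- function(p) {
  u <- signedToU(p)
  m <- length(u)                       # 2n + 2
  posOfVal <- integer(m)
  posOfVal[u + 1L] <- seq_len(m)
  visited <- logical(m)
  cycles <- 0L
  for (s in seq_len(m)) {
    if (visited[s]) next
    cycles <- cycles + 1L
    pos <- s
    repeat {
      visited[pos] <- TRUE
      bp <- if (pos %% 2L == 1L) pos + 1L else pos - 1L   # black edge
      visited[bp] <- TRUE
      v <- u[bp]
      gv <- if (v %% 2L == 0L) v + 1L else v - 1L          # gray edge
      pos <- posOfVal[gv + 1L]
      if (visited[pos]) break
    }
  }
  cycles
}

## Admissible lower bound on reversal distance to the identity.
reversalLowerBound <- function(p) {
  n <- length(p)
  if (n == 0L || (all(p == seq_len(n)))) return(0L)
  max(as.integer(ceiling(breakpointsInt(p) / 2)),
      n + 1L - cycleCountInt(p))
}

## ---------------------------------------------------------------------------
## IDA* search for minimal reversal scenarios

## Returns list(distance, scenarios = list of k x 2 interval matrices),
## enumerating co-optimal scenarios up to `cap` in lexicographic order of
## (leftmost endpoint, interval length) at each step. Exact; errors if the
## distance exceeds maxEvents.
sortByReversals <- function(p, maxEvents = 12L, cap = 64L) {
  n <- length(p)
  idp <- seq_len(n)
  if (n == 0L || all(p == idp))
    return(list(distance = 0L, scenarios = list(matrix(integer(), 0, 2))))
  ## candidate reversal intervals (i, j), i <= j, ordered by (i, j - i)
  ivs <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, seq(i, n))))
  ivs <- ivs[order(ivs[, 1], ivs[, 2] - ivs[, 1]), , drop = FALSE]

  found <- new.env(parent = emptyenv())
  dfs <- function(p, g, bound, path, lastIv) {
    if (all(p == idp)) {
      if (length(found$sc) < cap)
        found$sc[[length(found$sc) + 1L]] <-
          matrix(path, ncol = 2, byrow = TRUE)
      return(invisible())
    }
    if (g >= bound || length(found$sc) >= cap) return(invisible())
    hs <- rep(NA_integer_, nrow(ivs))
    children <- vector("list", nrow(ivs))
    for (r in seq_len(nrow(ivs))) {
      if (!is.null(lastIv) && lastIv[1] == ivs[r, 1] &&
          lastIv[2] == ivs[r, 2]) next
      q <- applyReversalInt(p, ivs[r, 1], ivs[r, 2])
      h <- reversalLowerBound(q)
      if (g + 1L + h <= bound) { hs[r] <- h; children[[r]] <- q }
    }
    keep <- which(!is.na(hs))
    if (!length(keep)) return(invisible())
    for (r in keep[order(hs[keep])]) {
      dfs(children[[r]], g + 1L, bound,
          c(path, ivs[r, 1], ivs[r, 2]), ivs[r, ])
      if (length(found$sc) >= cap) return(invisible())
    }
    invisible()
  }

  bound <- reversalLowerBound(p)
  repeat {
    if (bound > maxEvents)
      stop("no scenario within maxEvents = ", maxEvents,
           " (best lower bound ", reversalLowerBound(p), ")")
    found$sc <- list()
    dfs(p, 0L, bound, integer(), NULL)
    if (length(found$sc)) break
    bound <- bound + 1L
  }
  list(distance = bound, scenarios = found$sc)
}

## ---------------------------------------------------------------------------
## Order alignment: shared alphabet, anchoring, strip collapse

stripCopySuffix <- function(x) sub("#[0-9]+$", "", x)

## Express `source` as a signed permutation over `target`'s blocks. For
## circular orders the target is rotated (and reflected if necessary) so
## that the source's leading block leads it with the source's sign; the
## permutation then starts with +1 and position k of the permutation is
## position k of the source as given. Returns the permutation plus the
## target frame (block names in renumbering order with their frame signs).
orderToPerm <- function(source, target) {
  stopifnot(setequal(source@blocks, target@blocks),
            length(source@blocks) == length(target@blocks))
  tb <- target@blocks; ts <- target@signs
  if (source@circular && target@circular) {
    anchor <- source@blocks[1]; wantSign <- source@signs[1]
    k <- match(anchor, tb)
    n <- length(tb)
    idx <- c(seq(k, n), if (k > 1L) seq(1L, k - 1L))
    tb <- tb[idx]; ts <- ts[idx]
    if (ts[1] != wantSign) {
      tb <- c(tb[1], rev(tb[-1]))
      ts <- c(wantSign, -rev(ts[-1]))
    }
  }
  pos <- match(source@blocks, tb)
  perm <- as.integer(pos * source@signs * ts[pos])
  list(perm = perm, frameBlocks = tb, frameSigns = ts)
}

## Reduce the permutation for search: for circular orders the leading +1 is
## fixed; the rest is renumbered to 1..n-1. Returns the reduced permutation
## and the position offset to map search intervals back to source positions.
reduceForSearch <- function(pr, circular) {
  p <- pr$perm
  if (circular) {
    if (p[1] != 1L)
      stop("internal error: anchored permutation must start with +1")
    q <- p[-1L]
    list(p = as.integer(sign(q) * (abs(q) - 1L)), offset = 1L)
  } else list(p = p, offset = 0L)
}

#' Collapse two gene orders to a common block alphabet
#'
#' Extracts tandem duplications (a block, or short run of blocks, appearing
#' twice adjacently in one order) as duplication events, drops blocks
#' private to one genome (with a warning), and merges maximal runs of
#' elements that are consecutive and equally oriented in both genomes into
#' single signed blocks named after the member earliest in the target.
#' The collapsed repeat block never merges into a strip, so orientation
#' bookkeeping stays block-accurate.
#'
#' @param source,target [SignedGeneOrder-class] objects.
#' @return list with elements `source`, `target` (collapsed orders over an
#'   identical alphabet) and `duplications` (data.frame: block, genome,
#'   placement).
#' @export
collapseToBlocks <- function(source, target) {
  dups <- data.frame(block = character(), genome = character(),
                     placement = character(), stringsAsFactors = FALSE)
  dedup <- function(ord, label) {
    base <- stripCopySuffix(ord@blocks)
    dupnames <- unique(base[duplicated(base)])
    drop <- logical(length(base))
    for (g in dupnames) {
      pos <- which(base == g)
      extra <- pos[-1L]
      tandem <- all(vapply(extra, function(e)
        any(abs(e - pos[pos != e]) <= length(dupnames) + 1L), TRUE))
      if (!tandem)
        stop("non-tandem duplicate block '", g, "' in ", label,
             ": manual curation required")
      drop[extra] <- TRUE
      dups <<- rbind(dups, data.frame(block = g, genome = label,
                                      placement = "tandem",
                                      stringsAsFactors = FALSE))
    }
    initialize(ord, blocks = base[!drop], signs = ord@signs[!drop])
  }
  source <- dedup(source, "source")
  target <- dedup(target, "target")

  common <- intersect(source@blocks, target@blocks)
  if (!length(common)) stop("orders share no blocks")
  prune <- function(ord) {
    keep <- ord@blocks %in% common
    if (!all(keep))
      warning("dropping private blocks: ",
              paste(ord@blocks[!keep], collapse = ", "))
    initialize(ord, blocks = ord@blocks[keep], signs = ord@signs[keep])
  }
  source <- prune(source); target <- prune(target)

  pr <- orderToPerm(source, target)
  p <- pr$perm
  n <- length(p)
  repNum <- if (!is.na(source@repeatBlock))
    match(source@repeatBlock, pr$frameBlocks) else NA_integer_
  strip_id <- integer(n); sid <- 1L; strip_id[1] <- 1L
  if (n > 1L) for (k in 2:n) {
    joined <- (p[k] == p[k - 1L] + 1L) &&
      !(abs(p[k]) %in% repNum) && !(abs(p[k - 1L]) %in% repNum)
    if (!joined) sid <- sid + 1L
    strip_id[k] <- sid
  }
  grps <- split(seq_len(n), strip_id)
  srcBlocks <- character(length(grps)); srcSigns <- integer(length(grps))
  tgtIdx <- integer(length(grps))
  for (t in seq_along(grps)) {
    sgrp <- grps[[t]]
    first <- min(abs(p[sgrp]))
    srcBlocks[t] <- pr$frameBlocks[first]
    srcSigns[t] <- as.integer(sign(p[sgrp[1]]))
    tgtIdx[t] <- first
  }
  ## collapsed orders are expressed in the frame alphabet: every target
  ## block reads +, source signs are relative to the frame
  ordT <- order(tgtIdx)
  tgt <- initialize(target, blocks = srcBlocks[ordT],
                    signs = rep(1L, length(grps)))
  src <- initialize(source, blocks = srcBlocks, signs = srcSigns)
  list(source = src, target = tgt, duplications = dups)
}

## ---------------------------------------------------------------------------
## Public operations

#' Breakpoint count between two signed gene orders
#'
#' Number of adjacencies of `source` (circular, signed) absent from
#' `target`; 0 iff the orders are equivalent up to rotation and reflection.
#'
#' @param source,target [SignedGeneOrder-class] objects over the same
#'   block alphabet.
#' @return integer.
#' @export
breakpointCount <- function(source, target) {
  stopifnot(setequal(source@blocks, target@blocks))
  adjSet <- function(ord) {
    bl <- ord@blocks; sg <- ord@signs; n <- length(bl)
    nxt <- if (ord@circular) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
    i <- seq_along(nxt)
    a <- paste0(ifelse(sg > 0, "+", "-"), bl)
    arev <- paste0(ifelse(sg > 0, "-", "+"), bl)
    c(paste(a[i], a[nxt], sep = "|"),
      paste(arev[nxt], arev[i], sep = "|"))
  }
  sA <- adjSet(source); sB <- adjSet(target)
  ## each adjacency appears twice in adjSet (both readings); count once
  n <- length(source@blocks)
  nAdj <- if (source@circular) n else n - 1L
  sum(!(sA[seq_len(nAdj)] %in% sB))
}

#' Exact signed reversal distance
#'
#' Minimal number of reversals transforming `source` into `target`.
#' Circular orders are linearized by fixing the source's leading block;
#' the count is exact.
#'
#' @param source,target [SignedGeneOrder-class] objects over the same
#'   alphabet.
#' @param maxEvents search cap (default 12); exceeding it raises an error
#'   advising a bounded scenario search.
#' @return integer distance.
#' @export
reversalDistance <- function(source, target, maxEvents = 12L) {
  if (length(source@blocks) > 40L)
    stop("order too long for exact search (cap 40 blocks); ",
         "run collapseToBlocks() first")
  pr <- orderToPerm(source, target)
  rd <- reduceForSearch(pr, source@circular && target@circular)
  sortByReversals(rd$p, maxEvents = maxEvents, cap = 1L)$distance
}

#' Infer a minimal inversion scenario between two gene orders
#'
#' Finds one minimum-length sequence of reversals transforming `source`
#' into `target` and enumerates all co-optimal scenarios up to a cap.
#' Events are annotated `spansRepeat` when their interval contains the
#' collapsed repeat block (such events toggle IR<->DR); the orientation
#' trajectory starts at the source's flag. Among co-optimal scenarios
#' (ordered lexicographically by leftmost endpoint then interval length at
#' each step) the reported one is the first whose repeat-spanning parity is
#' consistent with the source and target orientation flags, when both are
#' known.
#'
#' @param source,target [SignedGeneOrder-class] objects over the same
#'   alphabet (run [collapseToBlocks()] first for raw orders).
#' @param maxEvents maximum scenario length searched (default 12).
#' @param cap maximum number of co-optimal scenarios enumerated.
#' @return an [InversionScenario-class]. Event intervals are inclusive
#'   1-based positions in the source order as given, current at the time
#'   each event is applied (for circular orders position 1 is the fixed
#'   anchor and never moves).
#' @export
inferInversionScenario <- function(source, target, maxEvents = 12L,
                                   cap = 64L) {
  pr <- orderToPerm(source, target)
  circ <- source@circular && target@circular
  rd <- reduceForSearch(pr, circ)
  bp <- breakpointCount(source, target)
  res <- sortByReversals(rd$p, maxEvents = maxEvents, cap = cap)

  repName <- source@repeatBlock
  repNum <- if (!is.na(repName)) match(repName, pr$frameBlocks)
            else NA_integer_
  mkEvents <- function(mat) {
    cur <- pr$perm
    if (!nrow(mat)) return(list())
    evs <- vector("list", nrow(mat))
    for (e in seq_len(nrow(mat))) {
      i <- mat[e, 1] + rd$offset; j <- mat[e, 2] + rd$offset
      spans <- FALSE
      if (!is.na(repNum)) {
        rpos <- which(abs(cur) == repNum)
        spans <- length(rpos) == 1L && rpos >= i && rpos <= j
      }
      evs[[e]] <- list(interval = c(i, j), spansRepeat = spans,
                       label = sprintf("E%d", e))
      cur[i:j] <- -rev(cur[i:j])
    }
    evs
  }
  allEv <- lapply(res$scenarios, mkEvents)

  srcFlag <- source@orientationFlag; tgtFlag <- target@orientationFlag
  pick <- 1L
  if (srcFlag %in% c("IR", "DR") && tgtFlag %in% c("IR", "DR") &&
      length(allEv) > 0L) {
    needOdd <- srcFlag != tgtFlag
    par <- vapply(allEv, function(evs)
      sum(vapply(evs, `[[`, TRUE, "spansRepeat")) %% 2L == 1L, TRUE)
    if (any(par == needOdd)) pick <- which(par == needOdd)[1]
    else if (res$distance > 0L)
      warning("no enumerated co-optimal scenario matches the IR/DR parity ",
              "of the source and target orientation flags")
  }
  events <- allEv[[pick]]
  traj <- character(0)
  if (srcFlag %in% c("IR", "DR")) {
    traj <- srcFlag
    for (e in events)
      traj <- c(traj, if (isTRUE(e$spansRepeat))
        setdiff(c("IR", "DR"), tail(traj, 1)) else tail(traj, 1))
  }
  new("InversionScenario", events = events,
      distance = as.integer(res$distance),
      breakpointsInitial = as.integer(bp),
      orientationTrajectory = traj, optimal = TRUE, coOptima = allEv)
}

#' Replay a scenario's events on its source order
#'
#' Applies the events of `scenario` to `source` in order; the result must
#' equal the inference target (up to rotation/reflection for circular
#' orders), which is the scenario-replay invariant the package tests.
#'
#' @param source the [SignedGeneOrder-class] the scenario was inferred
#'   from.
#' @param scenario an [InversionScenario-class].
#' @return the [SignedGeneOrder-class] after all events.
#' @export
replayScenario <- function(source, scenario) {
  bl <- source@blocks; sg <- source@signs
  flag <- source@orientationFlag
  for (e in scenario@events) {
    i <- e$interval[1]; j <- e$interval[2]
    bl[i:j] <- rev(bl[i:j]); sg[i:j] <- -rev(sg[i:j])
    if (isTRUE(e$spansRepeat) && flag %in% c("IR", "DR"))
      flag <- setdiff(c("IR", "DR"), flag)
  }
  new("SignedGeneOrder", blocks = bl, signs = sg,
      circular = source@circular, repeatBlock = source@repeatBlock,
      orientationFlag = flag)
}

## Orders equivalent as (circular) signed genomes?
sameOrder <- function(a, b) {
  setequal(a@blocks, b@blocks) &&
    length(a@blocks) == length(b@blocks) && breakpointCount(a, b) == 0L
}

#' Place inversion events on a phylogeny by parsimony
#'
#' Given the ancestral (root) gene order and one order per tip, events are
#' assigned to branches minimizing the total event count: at each internal
#' node, a candidate first event (identical interval in the current
#' ancestral frame) supported by some co-optimal minimal scenario for every
#' descendant tip is pushed onto the branch entering that node — the
#' deepest consistent branch — after which the ancestral order is updated
#' and the procedure recurses. Remaining events fall on terminal branches.
#'
#' @param rootOrder [SignedGeneOrder-class] at the root.
#' @param tipOrders named list of [SignedGeneOrder-class], names matching
#'   `tree$tip.label`.
#' @param tree a rooted `phylo`.
#' @param maxEvents,cap passed to [inferInversionScenario()].
#' @return data.frame with columns `branch` (label of the child node the
#'   branch leads to), `interval_start`, `interval_end`, `spansRepeat`.
#' @export
placeEventsOnTree <- function(rootOrder, tipOrders, tree,
                              maxEvents = 12L, cap = 64L) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(names(tipOrders), tree$tip.label))
    stop("tipOrders names must match tree tip labels")
  ntip <- length(tree$tip.label)
  childrenOf <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tipsUnder <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(childrenOf(node), tipsUnder))
  }
  nodeLabel <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (!is.null(tree$node.label) &&
        !is.na(tree$node.label[node - ntip]) &&
        nzchar(tree$node.label[node - ntip]))
      tree$node.label[node - ntip] else paste0("node", node)
  }
  out <- data.frame(branch = character(), interval_start = integer(),
                    interval_end = integer(), spansRepeat = logical(),
                    stringsAsFactors = FALSE)
  addEvent <- function(branch, interval, spans) {
    out <<- rbind(out, data.frame(branch = branch,
                                  interval_start = interval[1],
                                  interval_end = interval[2],
                                  spansRepeat = spans,
                                  stringsAsFactors = FALSE))
  }
  firstEventSigs <- function(anc, tipOrd) {
    if (sameOrder(anc, tipOrd)) return(character(0))
    sc <- inferInversionScenario(anc, tipOrd, maxEvents, cap)
    unique(vapply(sc@coOptima, function(evs)
      paste(evs[[1]]$interval, collapse = ":"), ""))
  }
  applySig <- function(anc, sig) {
    ij <- as.integer(strsplit(sig, ":")[[1]])
    bl <- anc@blocks; sg <- anc@signs
    spans <- !is.na(anc@repeatBlock) && {
      rpos <- match(anc@repeatBlock, bl)
      rpos >= ij[1] && rpos <= ij[2]
    }
    bl[ij[1]:ij[2]] <- rev(bl[ij[1]:ij[2]])
    sg[ij[1]:ij[2]] <- -rev(sg[ij[1]:ij[2]])
    flag <- anc@orientationFlag
    if (spans && flag %in% c("IR", "DR"))
      flag <- setdiff(c("IR", "DR"), flag)
    list(order = new("SignedGeneOrder", blocks = bl, signs = sg,
                     circular = anc@circular,
                     repeatBlock = anc@repeatBlock,
                     orientationFlag = flag),
         interval = ij, spans = spans)
  }
  walk <- function(node, anc) {
    tips <- tipsUnder(node)
    if (length(tips) == 1L) {
      tipOrd <- tipOrders[[tips]]
      if (!sameOrder(anc, tipOrd)) {
        sc <- inferInversionScenario(anc, tipOrd, maxEvents, cap)
        for (e in sc@events)
          addEvent(nodeLabel(node), e$interval, isTRUE(e$spansRepeat))
      }
      return(invisible())
    }
    repeat {
      sets <- lapply(tips, function(tp) firstEventSigs(anc, tipOrders[[tp]]))
      if (any(vapply(sets, length, 1L) == 0L)) break
      shared <- Reduce(intersect, sets)
      if (!length(shared)) break
      sig <- sort(shared)[1]
      res <- applySig(anc, sig)
      addEvent(nodeLabel(node), res$interval, res$spans)
      anc <- res$order
    }
    for (ch in childrenOf(node)) walk(ch, anc)
    invisible()
  }
  root <- ntip + 1L
  for (ch in childrenOf(root)) walk(ch, rootOrder)
  out
}
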