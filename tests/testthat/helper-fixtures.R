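# Shared helpers: order constructors and independent oracles.

# Build a SignedGeneOrder from "+name"/"-name" tokens.
sgo <- function(toks, circular = FALSE, flag = "none",
                rep = if ("REP" %in% sub("^[+-]", "", toks)) "REP"
                      else NA_character_) {
  sg <- ifelse(substr(toks, 1, 1) == "-", -1L, 1L)
  bl <- sub("^[+-]", "", toks)
  new("SignedGeneOrder", blocks = bl, signs = sg, circular = circular,
      repeatBlock = rep, orientationFlag = flag)
}

# Signed permutation -> order vs identity target, linear frame.
permOrders <- function(p) {
  n <- length(p)
  list(src = sgo(paste0(ifelse(p > 0, "+", "-"), abs(p))),
       tgt = sgo(paste0("+", seq_len(n))))
}

# Independent BFS oracle for reversal distance of a signed permutation to
# the identity (linear). Breadth-first over all reversal moves.
bfsReversalDistance <- function(p) {
  n <- length(p)
  tgt <- paste(seq_len(n), collapse = ",")
  key <- function(q) paste(q, collapse = ",")
  if (key(p) == tgt) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(key(p), TRUE, envir = seen)
  frontier <- list(p)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (q in frontier) for (i in seq_len(n)) for (j in i:n) {
      r <- q
      r[i:j] <- -rev(r[i:j])
      k <- key(r)
      if (k == tgt) return(d)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- r
      }
    }
    frontier <- nxt
  }
}

# Full BFS distance table from the identity over all signed permutations
# of n elements (vectorized frontier expansion). Returns an environment
# mapping encoded states to distances; encode() maps a permutation.
bfsDistanceTable <- function(n) {
  encode <- function(M) {
    # M: states in rows, values in -n..n excluding 0 -> base (2n+1)
    as.vector((M + n) %*% ((2 * n + 1)^(0:(n - 1))))
  }
  id <- matrix(seq_len(n), 1)
  dist <- new.env(parent = emptyenv())
  assign(as.character(encode(id)), 0L, envir = dist)
  frontier <- id
  seenKeys <- encode(id)
  d <- 0L
  ivs <- do.call(rbind, lapply(seq_len(n), function(i) cbind(i, i:n)))
  while (nrow(frontier)) {
    d <- d + 1L
    pieces <- vector("list", nrow(ivs))
    for (r in seq_len(nrow(ivs))) {
      i <- ivs[r, 1]; j <- ivs[r, 2]
      M <- frontier
      M[, i:j] <- -M[, j:i, drop = FALSE]
      pieces[[r]] <- M
    }
    cand <- do.call(rbind, pieces)
    keys <- encode(cand)
    newIdx <- which(!duplicated(keys) & !(keys %in% seenKeys))
    if (!length(newIdx)) break
    frontier <- cand[newIdx, , drop = FALSE]
    newKeys <- keys[newIdx]
    for (k in newKeys) assign(as.character(k), d, envir = dist)
    seenKeys <- c(seenKeys, newKeys)
  }
  list(lookup = function(p) {
    enc <- as.vector((matrix(p, 1) + n) %*% ((2 * n + 1)^(0:(n - 1))))
    get(as.character(enc), envir = dist)
  })
}

# Brute-force largest-repeat oracle for short sequences: scans all pairs
# of start positions for maximal exact matches (forward and reverse
# complement), returning the longest.
bruteLargestRepeat <- function(s, minLen) {
  ch <- strsplit(s, "")[[1]]
  rc <- rev(chartr("ACGTN", "TGCAN", ch))
  L <- length(ch)
  best <- NULL
  for (i in seq_len(L - minLen)) {
    for (j in seq(i + minLen, L - minLen + 1L)) {
      # forward/forward
      k <- 0L
      while (j + k <= L && i + k < j && ch[i + k] == ch[j + k]) k <- k + 1L
      if (k >= minLen && (is.null(best) || k > best$len))
        best <- list(i = i, j = j, len = k, orient = "direct")
    }
  }
  # inverted: match s[i..] against revcomp(s)[x..]
  rcs <- paste(rc, collapse = "")
  chr <- strsplit(rcs, "")[[1]]
  for (i in seq_len(L - minLen)) {
    for (x in seq_len(L - minLen)) {
      jEnd <- L - x + 1L            # rc position x aligns to s position L-x+1
      if (jEnd <= i + minLen) next
      k <- 0L
      while (i + k <= L && x + k <= L && ch[i + k] == chr[x + k] &&
             (jEnd - k) > (i + k)) k <- k + 1L
      if (k >= minLen && (is.null(best) || k > best$len))
        best <- list(i = i, j = jEnd - k + 1L, len = k, orient = "inverted")
    }
  }
  best
}

# Exhaustive Sankoff oracle: minimum total cost over all internal-state
# assignments of a rooted tree (<= 8 tips).
bruteSankoffCost <- function(tree, tipStates, costs) {
  states <- rownames(costs)
  ntip <- length(tree$tip.label)
  nInternal <- tree$Nnode
  combos <- expand.grid(rep(list(seq_along(states)), nInternal))
  best <- Inf
  tipIdx <- match(tipStates[tree$tip.label], states)
  for (r in seq_len(nrow(combos))) {
    a <- c(tipIdx, as.integer(combos[r, ]))
    cost <- sum(costs[cbind(a[tree$edge[, 1]], a[tree$edge[, 2]])])
    if (cost < best) best <- cost
  }
  best
}

# A tiny codon alignment from explicit sequences.
codonAln <- function(...) {
  new("Alignment", seqs = c(...), datatype = "codon")
}

fixtureDirCache <- local({
  dir <- NULL
  function(seed = 1L) {
    if (is.null(dir)) {
      d <- file.path(tempdir(), paste0("plastevol_fix_", seed))
      makeFixtureSet(d, seed = seed)
      dir <<- d
    }
    dir
  }
})

# Collect per-branch truth events along the root-to-tip path.
pathEvents <- function(truth, tree, tip, what) {
  ntip <- length(tree$tip.label)
  lab <- function(node) {
    if (node <= ntip) tree$tip.label[node]
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[node -
                                                                 ntip]))
      tree$node.label[node - ntip] else paste0("node", node)
  }
  node <- match(tip, tree$tip.label)
  out <- list()
  while (TRUE) {
    out[[length(out) + 1L]] <- truth$branches[[lab(node)]][[what]]
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (!length(parent)) break
    node <- parent
  }
  out
}

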