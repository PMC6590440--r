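## Per-branch divergence estimation on a fixed topology:
##   - synonymous divergence d_S under a local MG94xF3x4 codon model
##     (61 sense codons, plastid genetic code, single-nucleotide changes,
##     per-branch omega, custom exchangeability sharing via a 6-digit
##     class string), fitted by maximum likelihood with the pruning
##     algorithm; and
##   - total divergence d under GTR+Gamma+I, delegated to phangorn.
##
## d_S convention (the one printed value that depends on it): per branch,
## d_S = (expected synonymous substitutions per codon) / (proportion of
## neutral flux that is synonymous), i.e. synonymous substitutions per
## synonymous site under MG94 site counting. A "raw" switch returns the
## per-codon synonymous component instead.

#' @include AllClasses.R AllGenerics.R plastome-io.R
NULL

#' Parse a 6-digit exchangeability class string
#'
#' The six digits assign the exchangeabilities (AC, AG, AT, CG, CT, GT in
#' that order) to shared parameters; e.g. `"012232"` fits four free
#' classes, `"000000"` one, `"012345"` a full GTR set.
#'
#' @param classString 6 characters, digits 0-5.
#' @return list with `classes` (named integer vector, dense from 0) and
#'   `freeCount`.
#' @export
parseRateClass <- function(classString) {
  if (!is.character(classString) || length(classString) != 1L ||
      nchar(classString) != 6L || grepl("[^0-9]", classString))
    stop("class string must be exactly 6 digits: got '", classString, "'")
  digits <- as.integer(strsplit(classString, "")[[1]])
  dense <- match(digits, unique(digits)) - 1L
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  list(classes = setNames(dense, pairs),
       freeCount = length(unique(dense)))
}

#' Drop alignment columns exceeding a gap fraction
#'
#' A simplified stand-in for block-based trimming: codon alignments drop
#' whole codon columns, nucleotide alignments single columns, whenever the
#' fraction of rows with a gap exceeds `maxGapFraction`. Pre-trimmed
#' matrices pass through unchanged.
#'
#' @param aln an [Alignment-class].
#' @param maxGapFraction maximum tolerated gap fraction per column.
#' @return a trimmed [Alignment-class].
#' @export
trimAlignment <- function(aln, maxGapFraction = 0.5) {
  seqs <- aln@seqs
  mat <- do.call(rbind, strsplit(seqs, ""))
  isGap <- mat %in% c("-", ".", "?")
  dim(isGap) <- dim(mat)
  if (aln@datatype == "codon") {
    nc <- ncol(mat) %/% 3L
    keep <- vapply(seq_len(nc), function(j) {
      cols <- (3L * j - 2L):(3L * j)
      mean(apply(isGap[, cols, drop = FALSE], 1, any)) <= maxGapFraction
    }, TRUE)
    keepCols <- as.vector(vapply(which(keep), function(j)
      (3L * j - 2L):(3L * j), integer(3)))
  } else {
    keepCols <- which(colMeans(isGap) <= maxGapFraction)
  }
  if (!length(keepCols)) stop("no columns left after trimming")
  out <- apply(mat[, keepCols, drop = FALSE], 1, paste, collapse = "")
  new("Alignment", seqs = setNames(out, names(seqs)),
      datatype = aln@datatype)
}

## ---------------------------------------------------------------------------
## MG94xF3x4 machinery

## Position-specific nucleotide frequencies (F3x4) and the implied sense-
## codon frequencies.
f3x4Frequencies <- function(seqs) {
  nt <- c("A", "C", "G", "T")
  pos <- matrix(0, 3, 4, dimnames = list(NULL, nt))
  for (s in seqs) {
    v <- strsplit(s, "")[[1]]
    n <- length(v) %/% 3L
    for (p in 1:3) {
      tab <- table(factor(v[seq(p, 3L * n, 3L)], levels = nt))
      pos[p, ] <- pos[p, ] + as.numeric(tab)
    }
  }
  pos <- pos / rowSums(pos)
  ## floor so unobserved nucleotides never zero out codon frequencies
  pos <- pmax(pos, 1e-4)
  pos <- pos / rowSums(pos)
  piCodon <- vapply(SENSE_CODONS, function(cod) {
    b <- strsplit(cod, "")[[1]]
    pos[1, b[1]] * pos[2, b[2]] * pos[3, b[3]]
  }, 1)
  piCodon <- piCodon / sum(piCodon)
  list(pos = pos, pi = piCodon)
}

## Static single-step structure of the 61-codon chain: for each ordered
## pair differing at one position, the exchangeability pair index (1..6 for
## AC, AG, AT, CG, CT, GT), the changed position, target nucleotide, and
## synonymous flag.
codonStepStructure <- function() {
  nt <- c("A", "C", "G", "T")
  pairIdx <- matrix(0L, 4, 4, dimnames = list(nt, nt))
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  for (k in seq_along(pairs)) {
    a <- substr(pairs[k], 1, 1); b <- substr(pairs[k], 2, 2)
    pairIdx[a, b] <- k; pairIdx[b, a] <- k
  }
  n <- length(SENSE_CODONS)
  from <- integer(0); to <- integer(0); cls <- integer(0)
  posv <- integer(0); tgt <- character(0); syn <- logical(0)
  chars <- strsplit(SENSE_CODONS, "")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(chars[[i]] != chars[[j]])
    if (length(d) != 1L) next
    from <- c(from, i); to <- c(to, j)
    cls <- c(cls, pairIdx[chars[[i]][d], chars[[j]][d]])
    posv <- c(posv, d); tgt <- c(tgt, chars[[j]][d])
    syn <- c(syn, PLASTID_CODE[SENSE_CODONS[i]] ==
               PLASTID_CODE[SENSE_CODONS[j]])
  }
  list(from = from, to = to, cls = cls, pos = posv, tgt = tgt, syn = syn)
}

.mg94_env <- new.env(parent = emptyenv())
getStepStructure <- function() {
  if (is.null(.mg94_env$steps)) .mg94_env$steps <- codonStepStructure()
  .mg94_env$steps
}

## Unnormalized MG94 rate matrix: q_ij = theta_pair * pi_pos(target)
## (* omega if nonsynonymous). theta6 is the full 6-vector after class
## expansion.
mg94QRaw <- function(theta6, omega, freq) {
  st <- getStepStructure()
  n <- length(SENSE_CODONS)
  rate <- theta6[st$cls] *
    freq$pos[cbind(st$pos, match(st$tgt, c("A", "C", "G", "T")))]
  rate[!st$syn] <- rate[!st$syn] * omega
  Q <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  Q[cbind(st$from, st$to)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

## Total flux (expected substitutions per codon per unit time) and its
## synonymous component, under stationary frequencies pi.
mg94Flux <- function(Q, pi) {
  st <- getStepStructure()
  off <- Q[cbind(st$from, st$to)]
  total <- sum(pi[st$from] * off)
  synf <- sum(pi[st$from[st$syn]] * off[st$syn])
  c(total = total, syn = synf)
}

## Eigen machinery for a reversible Q with stationary pi: P(t) in one
## matrix product chain.
reversibleEigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2                 # symmetrize numerical noise
  e <- eigen(B, symmetric = TRUE)
  list(V = e$vectors, vals = e$values, d = d)
}

probMatrix <- function(eg, t) {
  ## P(t) = diag(1/d) V exp(L t) V' diag(d)
  E <- eg$V %*% (exp(eg$vals * t) * t(eg$V))
  P <- (1 / eg$d) * E * rep(eg$d, each = length(eg$d))
  P[P < 0] <- 0
  P
}

## ---------------------------------------------------------------------------
## Pruning likelihood over an arbitrary state space

## Compress an integer state matrix (taxa x sites, NA = missing) into
## patterns.
compressPatterns <- function(idx) {
  key <- apply(idx, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(idx = idx[, first, drop = FALSE], weights = as.numeric(tab))
}

## Precomputed pruning scaffolding: postorder edge walk, edge index map,
## and tip partial-likelihood matrices (built once, reused every
## likelihood evaluation).
pruningContext <- function(tree, tipIdx, ns) {
  ntip <- length(tree$tip.label)
  npat <- ncol(tipIdx)
  po <- ape::reorder.phylo(tree, "postorder")
  edgeKey <- paste(tree$edge[, 1], tree$edge[, 2])
  poMap <- match(paste(po$edge[, 1], po$edge[, 2]), edgeKey)
  tipRow <- match(tree$tip.label, rownames(tipIdx))
  tipPartials <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    M <- matrix(0, ns, npat)
    st <- tipIdx[tipRow[i], ]
    miss <- is.na(st)
    M[cbind(st[!miss], which(!miss))] <- 1
    if (any(miss)) M[, miss] <- 1
    tipPartials[[i]] <- M
  }
  list(tree = tree, po = po, poMap = poMap, ntip = ntip, npat = npat,
       ns = ns, tipPartials = tipPartials)
}

pruningLogLikCtx <- function(ctx, Plist, weights, pi) {
  ntip <- ctx$ntip
  nnode <- ntip + ctx$tree$Nnode
  partial <- vector("list", nnode)
  partial[seq_len(ntip)] <- ctx$tipPartials
  logscale <- 0
  for (r in seq_len(nrow(ctx$po$edge))) {
    parent <- ctx$po$edge[r, 1]; child <- ctx$po$edge[r, 2]
    contrib <- Plist[[ctx$poMap[r]]] %*% partial[[child]]
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else {
      partial[[parent]] <- partial[[parent]] * contrib
      mx <- apply(partial[[parent]], 2, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
      logscale <- logscale + sum(weights * log(mx))
    }
  }
  root <- ntip + 1L
  site <- colSums(pi * partial[[root]])
  sum(weights * log(site)) + logscale
}

## Log-likelihood by Felsenstein pruning. tree: rooted or unrooted phylo;
## Plist: per-edge probability matrices (rows of tree$edge); tipIdx:
## taxa x npat integer states (NA = missing); pi: root frequencies.
pruningLogLik <- function(tree, Plist, tipIdx, weights, pi) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(tipIdx)
  ns <- length(pi)
  partial <- vector("list", nnode)
  logscale <- 0
  tipRow <- match(tree$tip.label, rownames(tipIdx))
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    child <- po$edge[r, 2]
    if (child <= ntip && is.null(partial[[child]])) {
      M <- matrix(0, ns, npat)
      st <- tipIdx[tipRow[child], ]
      miss <- is.na(st)
      M[cbind(st[!miss], which(!miss))] <- 1
      if (any(miss)) M[, miss] <- 1
      partial[[child]] <- M
    }
  }
  ## edge order in Plist follows tree$edge; map postorder rows back
  edgeKey <- paste(tree$edge[, 1], tree$edge[, 2])
  for (r in seq_len(nrow(po$edge))) {
    parent <- po$edge[r, 1]; child <- po$edge[r, 2]
    P <- Plist[[match(paste(parent, child), edgeKey)]]
    contrib <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else partial[[parent]] <- partial[[parent]] * contrib
    ## rescale to avoid underflow
    mx <- apply(partial[[parent]], 2, max)
    mx[mx == 0] <- 1
    partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
    logscale <- logscale + sum(weights * log(mx))
  }
  root <- ntip + 1L
  site <- colSums(pi * partial[[root]])
  sum(weights * log(site)) + logscale
}

## ---------------------------------------------------------------------------
## Codon branch-length estimation

codonIndexMatrix <- function(aln) {
  seqs <- aln@seqs
  rows <- lapply(seqs, splitCodons)
  n <- length(rows[[1]])
  idx <- matrix(NA_integer_, length(seqs), n,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(rows)) {
    cods <- rows[[i]]
    hit <- match(cods, SENSE_CODONS)
    isStop <- cods %in% STOP_CODONS
    if (any(isStop))
      stop(sprintf("internal stop codon in row '%s', codon column %d",
                   names(seqs)[i], which(isStop)[1]))
    idx[i, ] <- hit                   # NA for gap/ambiguous codons
  }
  idx
}

#' Estimate per-branch synonymous divergence under MG94xF3x4
#'
#' Maximum-likelihood branch lengths and per-branch omega on a fixed
#' topology under the 61-sense-codon MG94 model with F3x4 frequencies
#' (computed empirically, never optimized), exchangeabilities shared
#' according to a class string, and the plastid genetic code. Optimization
#' alternates global exchangeabilities (L-BFGS-B on log scale) with
#' per-branch (t, omega) profiles (Brent), until the log-likelihood
#' improves by less than `tol`.
#'
#' @param aln a codon [Alignment-class] without internal stop codons.
#' @param topology a `phylo` whose tips equal the alignment taxa; only the
#'   topology is used.
#' @param rateClass a class string (e.g. `"012232"`) or the result of
#'   [parseRateClass()].
#' @param dsConvention `"persite"` (default): synonymous substitutions per
#'   synonymous site; `"raw"`: per-codon synonymous component.
#' @param tol convergence tolerance on the log-likelihood.
#' @param maxIter maximum outer iterations.
#' @param restarts additional deterministic jittered starts (0 = single
#'   start).
#' @return a [RateTree-class] of d_S values.
#' @export
estimateBranchLengthsCodon <- function(aln, topology,
                                       rateClass = "012345",
                                       dsConvention = c("persite", "raw"),
                                       tol = 1e-4, maxIter = 8L,
                                       restarts = 0L) {
  dsConvention <- match.arg(dsConvention)
  if (is.character(rateClass)) rateClass <- parseRateClass(rateClass)
  stopifnot(inherits(topology, "phylo"))
  if (!setequal(topology$tip.label, names(aln@seqs)))
    stop("alignment taxa and tree tips differ")
  if (aln@datatype != "codon") stop("codon alignment required")

  ## the model is reversible: only the unrooted branch set is identifiable
  tree <- if (length(topology$tip.label) > 2L) ape::unroot(topology)
          else topology
  if (!is.null(tree$edge.length)) tree$edge.length <- NULL
  idx <- codonIndexMatrix(aln)
  cp <- compressPatterns(idx)
  freq <- f3x4Frequencies(aln@seqs)
  pi <- freq$pi
  nb <- nrow(tree$edge)
  classes <- rateClass$classes
  nfree <- rateClass$freeCount

  expandTheta <- function(free) {
    full <- c(1, free)[classes + 1L]    # class 0 pinned to 1
    setNames(full, names(classes))
  }
  branchEigen <- function(theta6, omega) {
    Q <- mg94QRaw(theta6, omega, freq)
    fl <- mg94Flux(Q, pi)
    list(eg = reversibleEigen(Q / fl["total"], pi), flux = fl)
  }
  ctx <- pruningContext(tree, cp$idx, length(pi))
  logLik <- function(theta6, omegas, tvec) {
    egs <- lapply(unique(omegas), function(w) branchEigen(theta6, w))
    names(egs) <- as.character(unique(omegas))
    Plist <- lapply(seq_len(nb), function(b)
      probMatrix(egs[[as.character(omegas[b])]]$eg, tvec[b]))
    pruningLogLikCtx(ctx, Plist, cp$weights, pi)
  }

  fitOnce <- function(thetaFree0, omega0, t0) {
    thetaFree <- thetaFree0
    omegas <- rep(omega0, nb); tvec <- rep(t0, nb)
    ll <- logLik(expandTheta(thetaFree), omegas, tvec)
    for (iter in seq_len(maxIter)) {
      llPrev <- ll
      ## global exchangeabilities
      if (nfree > 1L) {
        obj <- function(lf) -logLik(expandTheta(exp(lf)), omegas, tvec)
        opt <- optim(log(thetaFree), obj, method = "Nelder-Mead",
                     control = list(maxit = 40, reltol = 1e-7))
        thetaFree <- exp(opt$par)
      }
      theta6 <- expandTheta(thetaFree)
      ## per-branch profiles
      for (b in seq_len(nb)) {
        fo <- function(w) {
          om <- omegas; om[b] <- w
          -logLik(theta6, om, tvec)
        }
        ow <- optimize(fo, c(1e-4, 10), tol = 1e-2)
        omegas[b] <- ow$minimum
        ft <- function(lt) {
          tv <- tvec; tv[b] <- exp(lt)
          -logLik(theta6, omegas, tv)
        }
        ot <- optimize(ft, log(c(1e-9, 20)), tol = 1e-4)
        tvec[b] <- exp(ot$minimum)
      }
      ll <- logLik(theta6, omegas, tvec)
      if (abs(ll - llPrev) < tol) break
    }
    list(thetaFree = thetaFree, omegas = omegas, tvec = tvec, ll = ll)
  }

  starts <- list(list(theta = rep(1, max(nfree - 1L, 0L)), omega = 0.5,
                      t = 0.2))
  if (restarts > 0L) for (r in seq_len(restarts))
    starts[[r + 1L]] <- list(theta = rep(0.5 * r, max(nfree - 1L, 0L)),
                             omega = 0.2 * r + 0.1, t = 0.05 * r + 0.1)
  fits <- lapply(starts, function(s0)
    fitOnce(s0$theta, s0$omega, s0$t))
  fit <- fits[[which.max(vapply(fits, `[[`, 1, "ll"))]]

  theta6 <- expandTheta(fit$thetaFree)
  ## d_S per branch
  dS <- vapply(seq_len(nb), function(b) {
    Q <- mg94QRaw(theta6, fit$omegas[b], freq)
    fl <- mg94Flux(Q, pi)
    Q1 <- mg94QRaw(theta6, 1, freq)
    fl1 <- mg94Flux(Q1, pi)
    synPerCodon <- fit$tvec[b] * fl["syn"] / fl["total"]
    if (dsConvention == "raw") unname(synPerCodon)
    else unname(synPerCodon / (fl1["syn"] / fl1["total"]))
  }, 1)
  outTree <- tree
  outTree$edge.length <- fit$tvec
  new("RateTree", tree = outTree, branchValues = dS,
      model = paste0("MG94xF3x4/",
                     paste(classes, collapse = "")),
      params = list(theta = theta6, omega = fit$omegas,
                    branch_t = fit$tvec, pi = pi, logLik = fit$ll,
                    dsConvention = dsConvention))
}

## ---------------------------------------------------------------------------
## Nucleotide branch lengths (GTR + Gamma + I), via phangorn

#' Estimate per-branch total divergence under GTR+Gamma+I
#'
#' Maximum-likelihood branch lengths on a fixed topology under GTR with
#' `gammaCategories` discrete mean-one Gamma categories and an invariant-
#' site proportion, using phangorn's pruning implementation. With
#' `model = "JC"`, one category and no invariant sites this reduces to the
#' Jukes-Cantor limit.
#'
#' @param aln a nucleotide [Alignment-class].
#' @param topology a `phylo` with tips equal to the alignment taxa.
#' @param gammaCategories number of discrete Gamma categories (default 4).
#' @param invariant optimize a proportion of invariant sites.
#' @param model `"GTR"` (default) or `"JC"`.
#' @return a [RateTree-class] of d values.
#' @export
estimateBranchLengthsNt <- function(aln, topology, gammaCategories = 4L,
                                    invariant = TRUE,
                                    model = c("GTR", "JC")) {
  model <- match.arg(model)
  stopifnot(inherits(topology, "phylo"))
  if (!setequal(topology$tip.label, names(aln@seqs)))
    stop("alignment taxa and tree tips differ")
  if (length(topology$tip.label) == 2L)
    return(pairwiseNtML(aln, topology, gammaCategories, invariant, model))
  mat <- do.call(rbind, strsplit(tolower(aln@seqs), ""))
  rownames(mat) <- names(aln@seqs)
  dat <- phangorn::phyDat(mat, type = "DNA")
  tree <- ape::unroot(topology)
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  fit <- phangorn::pml(tree, dat, k = gammaCategories,
                       inv = if (invariant) 0.05 else 0,
                       shape = 1)
  fit <- phangorn::optim.pml(
    fit, model = model, optEdge = TRUE,
    optBf = model == "GTR", optQ = model == "GTR",
    optGamma = gammaCategories > 1L, optInv = invariant,
    control = phangorn::pml.control(trace = 0))
  ft <- fit$tree
  new("RateTree", tree = ft, branchValues = ft$edge.length,
      model = if (model == "GTR")
        sprintf("GTR+G(%d)+I", gammaCategories) else "JC",
      params = list(bf = fit$bf, Q = fit$Q, alpha = fit$shape,
                    p_inv = fit$inv, logLik = fit$logLik))
}

## Two-taxon special case: direct ML on the pairwise distance (tree-based
## engines need >= 3 tips). Same model family, same conventions.
pairwiseNtML <- function(aln, topology, k, invariant, model) {
  nt <- c("A", "C", "G", "T")
  v1 <- strsplit(aln@seqs[[topology$tip.label[1]]], "")[[1]]
  v2 <- strsplit(aln@seqs[[topology$tip.label[2]]], "")[[1]]
  ok <- v1 %in% nt & v2 %in% nt
  a <- match(v1[ok], nt); b <- match(v2[ok], nt)
  tab <- table(factor(a, 1:4), factor(b, 1:4))
  bf <- if (model == "JC") rep(0.25, 4) else {
    f <- (rowSums(tab) + colSums(tab)); f / sum(f)
  }
  gtrQ <- function(theta6) {
    Q <- matrix(0, 4, 4)
    pr <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (m in 1:6) {
      i <- pr[m, 1]; j <- pr[m, 2]
      Q[i, j] <- theta6[m] * bf[j]; Q[j, i] <- theta6[m] * bf[i]
    }
    diag(Q) <- -rowSums(Q)
    Q / sum(-bf * diag(Q))
  }
  negll <- function(t, theta6, alpha, pinv) {
    eg <- reversibleEigen(gtrQ(theta6), bf)
    g <- if (k > 1L) phangorn::discrete.gamma(alpha, k) else 1
    if (pinv > 0) g <- g / (1 - pinv)
    lik <- matrix(0, 4, 4)
    for (r in g) lik <- lik + probMatrix(eg, t * r) / length(g)
    lik <- (1 - pinv) * lik + pinv * diag(4)
    lik <- bf * lik
    -sum(tab * log(pmax(lik, 1e-300)))
  }
  theta6 <- rep(1, 6); alpha <- 1; pinv <- 0
  tHat <- optimize(function(t) negll(t, theta6, alpha, pinv),
                   c(1e-6, 10), tol = 1e-7)$minimum
  if (model == "GTR" || invariant || k > 1L) {
    par0 <- c(log(tHat),
              if (model == "GTR") rep(0, 5),
              if (k > 1L) 0,
              if (invariant) -2)
    unpack <- function(p) {
      i <- 1L; t <- exp(p[i]); i <- i + 1L
      th <- rep(1, 6)
      if (model == "GTR") { th[2:6] <- exp(p[i:(i + 4)]); i <- i + 5L }
      al <- 1; if (k > 1L) { al <- exp(p[i]); i <- i + 1L }
      pv <- 0; if (invariant) pv <- 1 / (1 + exp(-p[i]))
      list(t = t, th = th, al = al, pv = min(pv, 0.95))
    }
    op <- optim(par0, function(p) {
      q <- unpack(p); negll(q$t, q$th, q$al, q$pv)
    }, method = "Nelder-Mead", control = list(maxit = 2000,
                                              reltol = 1e-10))
    q <- unpack(op$par)
    tHat <- q$t; theta6 <- q$th; alpha <- q$al; pinv <- q$pv
  }
  tr <- topology
  tr$edge.length <- rep(tHat / 2, nrow(tr$edge))
  new("RateTree", tree = tr, branchValues = tr$edge.length,
      model = if (model == "GTR")
        sprintf("GTR+G(%d)+I (pairwise)", k) else "JC (pairwise)",
      params = list(bf = bf, Q = theta6, alpha = alpha, p_inv = pinv))
}

## ---------------------------------------------------------------------------
## Rate comparisons

#' Terminal branch value for a species
#'
#' @param rateTree a [RateTree-class].
#' @param species tip label.
#' @return the branch value on the edge subtending the tip.
#' @export
terminalBranchValue <- function(rateTree, species) {
  tr <- rateTree@tree
  tip <- match(species, tr$tip.label)
  if (is.na(tip)) stop("species not in tree: ", species)
  edge <- which(tr$edge[, 2] == tip)
  rateTree@branchValues[edge]
}

#' Compare duplicated-region vs single-copy branch values
#'
#' Ratio of a species' terminal branch value in the duplicated-gene tree
#' to that in the single-copy tree — the repeat-localized vs single-copy
#' rate contrast.
#'
#' @param treeDup [RateTree-class] estimated from repeat-resident genes.
#' @param treeSc [RateTree-class] estimated from single-copy genes.
#' @param species tip label present in both trees.
#' @return data.frame with `species`, `duplicated`, `single_copy`,
#'   `ratio` (NA with a warning when the single-copy value is 0).
#' @export
compareRates <- function(treeDup, treeSc, species) {
  dup <- terminalBranchValue(treeDup, species)
  sc <- terminalBranchValue(treeSc, species)
  ratio <- if (sc > 0) dup / sc else {
    warning("single-copy branch value is 0: ratio undefined")
    NA_real_
  }
  data.frame(species = species, duplicated = dup, single_copy = sc,
             ratio = ratio, stringsAsFactors = FALSE)
}
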