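## Gene and intron content: scoring each element per genome as
## intact / pseudogene / absent (introns: present / absent), assembling the
## species x element matrix, and mapping losses onto a fixed phylogeny by
## weighted (Sankoff) parsimony.

#' @include AllClasses.R AllGenerics.R plastome-io.R
NULL

GENE_STATES <- c("intact", "pseudogene", "absent")
INTRON_STATES <- c("present", "absent")

#' Default state-change cost scheme (quasi-Dollo)
#'
#' Losses are cheap and ordered (intact -> pseudogene -> absent costs 1
#' each, intact -> absent costs 2), gains are near-prohibited (cost 10):
#' regain of a plastid gene is implausible, so reconstructions are
#' effectively Dollo while remaining finite for degenerate inputs.
#'
#' @param gain cost of any gain transition.
#' @return list with `gene` and `intron` cost matrices (rows: parent
#'   state, columns: child state).
#' @export
defaultLossCosts <- function(gain = 10) {
  g <- matrix(gain, 3, 3, dimnames = list(GENE_STATES, GENE_STATES))
  diag(g) <- 0
  g["intact", "pseudogene"] <- 1
  g["intact", "absent"] <- 2
  g["pseudogene", "absent"] <- 1
  i <- matrix(gain, 2, 2, dimnames = list(INTRON_STATES, INTRON_STATES))
  diag(i) <- 0
  i["present", "absent"] <- 1
  list(gene = g, intron = i)
}

## Spliced CDS sequence of a feature, 5'->3' on the feature strand.
splicedSeq <- function(feature, record) {
  s <- as.character(genomeSeq(record))
  ex <- feature$exons[[1]]
  parts <- vapply(seq_len(nrow(ex)), function(i)
    substr(s, ex[i, 1] + 1L, ex[i, 2]), "")
  joined <- paste(parts, collapse = "")
  if (feature$strand < 0L) revcompChar(joined) else joined
}

#' Score one gene as intact, pseudogene or absent
#'
#' Pseudogene calls follow three rules: a frameshift (summed exon length
#' not divisible by 3), a substantial truncation (spliced length below
#' `truncation` times the cross-taxon reference length), or — only in taxa
#' flagged `noUCEditing`, where premature stops cannot be rescued by
#' U-to-C RNA editing — an internal stop codon under the plastid genetic
#' code. RNA genes are subject to the truncation rule only.
#'
#' @param feature one row of a record's feature table (a gene, not an
#'   intron), or `NULL` for an unannotated gene (returns `"absent"`).
#' @param record the [PlastomeRecord-class] the feature belongs to.
#' @param referenceLengths named numeric vector of per-gene median spliced
#'   lengths (bp); genes missing from it skip the truncation rule.
#' @param noUCEditing logical: taxon lacks U-to-C editing, so internal
#'   stops are diagnostic.
#' @param truncation truncation threshold as a fraction of the reference
#'   length (default 0.5).
#' @return one of `"intact"`, `"pseudogene"`, `"absent"`.
#' @export
scoreGeneStatus <- function(feature, record, referenceLengths = NULL,
                            noUCEditing = FALSE, truncation = 0.5) {
  if (is.null(feature) || (is.data.frame(feature) && !nrow(feature)))
    return("absent")
  stopifnot(is.data.frame(feature), nrow(feature) == 1L)
  ex <- feature$exons[[1]]
  len <- sum(ex[, 2] - ex[, 1])
  ref <- if (!is.null(referenceLengths))
    referenceLengths[feature$name] else NA_real_
  if (!is.na(ref) && len < truncation * ref) return("pseudogene")
  if (feature$kind %in% c("rRNA", "tRNA")) return("intact")
  if (len %% 3L != 0L) return("pseudogene")
  if (noUCEditing) {
    aa <- translatePlastid(splicedSeq(feature, record))
    if (length(aa) > 1L && any(aa[-length(aa)] == "*"))
      return("pseudogene")
  }
  "intact"
}

#' Build the species-by-element content matrix
#'
#' Every record is scored against the fixed catalog. Intron presence
#' additionally requires the host gene to be present (intact or
#' pseudogene): an intron feature inside a fully deleted gene cannot be
#' scored present.
#'
#' @param records list of [PlastomeRecord-class] objects.
#' @param catalog data.frame as returned by [plastidGeneCatalog()].
#' @param referenceLengths optional named vector of per-gene reference
#'   lengths (bp); when `NULL` it is computed as the cross-record median
#'   spliced length per gene.
#' @param noUCEditing named logical vector per record id (default all
#'   `FALSE`).
#' @param truncation truncation threshold (see [scoreGeneStatus()]).
#' @return a [ContentMatrix-class].
#' @export
buildContentMatrix <- function(records, catalog = plastidGeneCatalog(),
                               referenceLengths = NULL,
                               noUCEditing = NULL, truncation = 0.5) {
  ids <- vapply(records, recordId, "")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  names(records) <- ids
  if (is.null(noUCEditing))
    noUCEditing <- setNames(rep(FALSE, length(ids)), ids)

  featOf <- function(record, name, kinds) {
    f <- features(record)
    f[f$name == name & f$kind %in% kinds & f$copy_index == 0L, ,
      drop = FALSE]
  }
  if (is.null(referenceLengths)) {
    genes <- catalog$element[catalog$kind != "intron"]
    referenceLengths <- vapply(genes, function(g) {
      lens <- unlist(lapply(records, function(r) {
        f <- featOf(r, g, c("protein", "ORF", "rRNA", "tRNA"))
        if (nrow(f)) sum(f$exons[[1]][, 2] - f$exons[[1]][, 1]) else NULL
      }))
      if (length(lens)) stats::median(lens) else NA_real_
    }, 1)
  }

  states <- matrix(NA_character_, length(ids), nrow(catalog),
                   dimnames = list(ids, catalog$element))
  for (id in ids) {
    rec <- records[[id]]
    for (j in seq_len(nrow(catalog))) {
      el <- catalog$element[j]; kind <- catalog$kind[j]
      if (kind == "intron") {
        host <- catalog$host_gene[j]
        f <- features(rec)
        hit <- f[f$kind == "intron" & f$name == el & f$copy_index == 0L, ,
                 drop = FALSE]
        hostState <- states[id, host]
        if (is.na(hostState))
          stop("catalog must list host genes before their introns: ", el)
        states[id, j] <- if (nrow(hit) && hostState != "absent")
          "present" else "absent"
      } else {
        f <- featOf(rec, el, c("protein", "ORF", "rRNA", "tRNA"))
        states[id, j] <- if (!nrow(f)) "absent" else
          scoreGeneStatus(f[1, , drop = FALSE], rec, referenceLengths,
                          isTRUE(noUCEditing[[id]]), truncation)
      }
    }
  }
  new("ContentMatrix", states = states,
      elementKind = setNames(catalog$kind, catalog$element),
      hostGene = setNames(catalog$host_gene, catalog$element))
}

#' Per-taxon totals of intact elements
#'
#' @param x a [ContentMatrix-class].
#' @return data.frame of counts (intact genes per category; present
#'   introns) per taxon.
#' @export
contentTotals <- function(x) {
  st <- x@states
  kinds <- x@elementKind[colnames(st)]
  cnt <- function(kind, good)
    rowSums(matrix(st[, kinds == kind, drop = FALSE] %in% good,
                   nrow = nrow(st)))
  data.frame(taxon = rownames(st),
             protein = cnt("protein", "intact") + cnt("ORF", "intact"),
             rRNA = cnt("rRNA", "intact"),
             tRNA = cnt("tRNA", "intact"),
             introns = cnt("intron", "present"),
             genes = cnt("protein", "intact") + cnt("ORF", "intact") +
               cnt("rRNA", "intact") + cnt("tRNA", "intact"),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Sankoff parsimony

## Generic Sankoff DP over a rooted tree (polytomies allowed) for one
## character. Returns min cost, all optimal assignments (up to cap), and
## the root-state vector of costs.
sankoffDP <- function(tree, tipStates, costs, cap = 64L) {
  states <- rownames(costs)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- matrix(Inf, nnode, length(states),
              dimnames = list(NULL, states))
  for (i in seq_len(ntip))
    S[i, tipStates[tree$tip.label[i]]] <- 0
  childrenOf <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  ## internal nodes deepest-first so children are always resolved first
  depth <- integer(nnode); depth[ntip + 1L] <- 0L
  for (r in seq_len(nrow(tree$edge)))
    depth[tree$edge[r, 2]] <- depth[tree$edge[r, 1]] + 1L
  ord <- order(depth[(ntip + 1L):nnode], decreasing = TRUE) + ntip
  for (v in ord) {
    kids <- childrenOf(v)
    for (s in seq_along(states)) {
      tot <- 0
      for (k in kids)
        tot <- tot + min(costs[s, ] + S[k, ])
      S[v, s] <- tot
    }
  }
  root <- ntip + 1L
  best <- min(S[root, ])
  ## enumerate optimal assignments by DFS; prefer earlier states
  ## (states are ordered functional-first, so ties resolve to the
  ## ancestral-presence interpretation)
  assigns <- list()
  collectSub <- function(node, s, acc) {
    ## returns list of assignment vectors for subtree at node given state s
    acc[node] <- s
    kids <- childrenOf(node)
    res <- list(acc)
    for (k in kids) {
      newres <- list()
      for (a in res) {
        if (k <= ntip) {
          a[k] <- match(tipStates[tree$tip.label[k]], states)
          newres[[length(newres) + 1L]] <- a
        } else {
          opts <- which(costs[s, ] + S[k, ] == min(costs[s, ] + S[k, ]))
          for (t in opts) {
            subs <- collectSub(k, t, a)
            newres <- c(newres, subs)
            if (length(newres) > cap) break
          }
        }
      }
      res <- newres[seq_len(min(length(newres), cap))]
    }
    res
  }
  rootOpts <- which(S[root, ] == best)
  for (s in rootOpts) {
    subs <- collectSub(root, s, integer(nnode))
    assigns <- c(assigns, subs)
    if (length(assigns) >= cap) break
  }
  assigns <- assigns[seq_len(min(length(assigns), cap))]
  list(cost = best, assignments = assigns, states = states)
}

#' Reconstruct gene and intron losses by weighted parsimony
#'
#' Per-element Sankoff dynamic program over a rooted topology with a
#' directed state-change cost table. All minimum-cost assignments are
#' enumerated up to a cap; events present in every optimum are marked
#' unambiguous. Replaying the events of any reported optimum down the tree
#' from its root state reproduces every tip's observed state.
#'
#' @param matrix a [ContentMatrix-class].
#' @param topology rooted `phylo`; tip labels must equal the matrix taxa.
#' @param costs cost scheme as from [defaultLossCosts()].
#' @param cap maximum optima enumerated per element.
#' @return list with `events` (data.frame: element, branch, from, to,
#'   event, unambiguous), `cost` (named numeric per element), and
#'   `rootStates` (named character, the preferred optimum's root state).
#' @export
reconstructLosses <- function(matrix, topology,
                              costs = defaultLossCosts(), cap = 64L) {
  stopifnot(inherits(topology, "phylo"))
  if (!setequal(topology$tip.label, rownames(matrix@states)))
    stop("matrix taxa and tree tips differ: missing ",
         paste(setdiff(topology$tip.label, rownames(matrix@states)),
               collapse = ", "))
  ntip <- length(topology$tip.label)
  nodeLabel <- function(node) {
    if (node <= ntip) return(topology$tip.label[node])
    if (!is.null(topology$node.label) &&
        !is.na(topology$node.label[node - ntip]) &&
        nzchar(topology$node.label[node - ntip]))
      topology$node.label[node - ntip] else paste0("node", node)
  }
  evs <- list()
  costOut <- numeric(0)
  rootStates <- character(0)
  for (el in colnames(matrix@states)) {
    kind <- matrix@elementKind[[el]]
    cm <- if (kind == "intron") costs$intron else costs$gene
    tipStates <- matrix@states[, el]
    dp <- sankoffDP(topology, tipStates, cm, cap = cap)
    costOut[el] <- dp$cost
    ## events per optimum
    evPerOpt <- lapply(dp$assignments, function(a) {
      ch <- topology$edge[, 2]; pa <- topology$edge[, 1]
      diffs <- which(a[ch] != a[pa])
      if (!length(diffs)) return(character(0))
      vapply(diffs, function(d) {
        from <- dp$states[a[pa[d]]]; to <- dp$states[a[ch[d]]]
        paste(nodeLabel(ch[d]), from, to, sep = "\r")
      }, "")
    })
    rootStates[el] <- dp$states[dp$assignments[[1]][ntip + 1L]]
    allEv <- unique(unlist(evPerOpt))
    if (length(allEv)) {
      inAll <- vapply(allEv, function(e)
        all(vapply(evPerOpt, function(x) e %in% x, TRUE)), TRUE)
      ## report the first (preferred) optimum's events
      for (e in evPerOpt[[1]]) {
        parts <- strsplit(e, "\r")[[1]]
        evType <- classifyTransition(parts[2], parts[3])
        evs[[length(evs) + 1L]] <- data.frame(
          element = el, branch = parts[1], from = parts[2], to = parts[3],
          event = evType, unambiguous = inAll[[e]],
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(element = character(), branch = character(),
               from = character(), to = character(), event = character(),
               unambiguous = logical(), stringsAsFactors = FALSE)
  list(events = events, cost = costOut, rootStates = rootStates)
}

classifyTransition <- function(from, to) {
  if (from %in% c("intact", "present") && to == "pseudogene")
    "pseudogenization"
  else if (to == "absent") "loss"
  else "gain"
}

#' Replay loss events down a tree
#'
#' Applies per-branch events from a reconstruction to the root states and
#' returns the implied tip states — the round-trip check that a
#' reconstruction is self-consistent.
#'
#' @param recon result of [reconstructLosses()].
#' @param topology the same rooted `phylo`.
#' @return character matrix of implied tip states (taxa x elements).
#' @export
replayLossEvents <- function(recon, topology) {
  ntip <- length(topology$tip.label)
  nodeLabel <- function(node) {
    if (node <= ntip) return(topology$tip.label[node])
    if (!is.null(topology$node.label) &&
        !is.na(topology$node.label[node - ntip]) &&
        nzchar(topology$node.label[node - ntip]))
      topology$node.label[node - ntip] else paste0("node", node)
  }
  childrenOf <- function(node) topology$edge[topology$edge[, 1] == node, 2]
  elements <- names(recon$rootStates)
  out <- matrix(NA_character_, ntip, length(elements),
                dimnames = list(topology$tip.label, elements))
  for (el in elements) {
    ev <- recon$events[recon$events$element == el, , drop = FALSE]
    walk <- function(node, state) {
      hit <- ev[ev$branch == nodeLabel(node), , drop = FALSE]
      if (nrow(hit)) state <- hit$to[1]
      if (node <= ntip) { out[node, el] <<- state; return(invisible()) }
      for (k in childrenOf(node)) walk(k, state)
    }
    for (k in childrenOf(ntip + 1L)) walk(k, recon$rootStates[[el]])
  }
  out
}
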