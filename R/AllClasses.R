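#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom stats optim optimize setNames runif rexp
#' @importFrom utils head tail write.table read.delim combn
NULL

## Internal coordinate convention, used by every module: 0-based, half-open,
## forward strand. Circular features are normalized by rotating the sequence
## upstream of record construction, never by splitting the feature.

#' An annotated plastid genome
#'
#' Container for one circular plastome: the sequence plus typed features
#' (protein/rRNA/tRNA genes, introns, ORFs) with 0-based half-open
#' forward-strand coordinates.
#'
#' @slot id accession or sample identifier.
#' @slot sequence a [Biostrings::DNAString] (alphabet A,C,G,T,N).
#' @slot features a `data.frame` with columns `name`, `kind` (one of
#'   `"protein"`, `"rRNA"`, `"tRNA"`, `"intron"`, `"ORF"`), `start`, `end`,
#'   `strand` (+1/-1), `copy_index` (0 for the first copy of a duplicated
#'   gene), `host_gene` (for introns), and a list-column `exons` of
#'   two-column matrices (start, end) for compound locations.
#' @slot source path of the file the record was read from, or `""`.
#' @export
setClass("PlastomeRecord",
  slots = c(id = "character", sequence = "DNAString",
            features = "data.frame", source = "character"))

setValidity("PlastomeRecord", function(object) {
  msg <- character()
  L <- length(object@sequence)
  f <- object@features
  need <- c("name", "kind", "start", "end", "strand", "copy_index")
  if (!all(need %in% names(f)))
    msg <- c(msg, paste("features must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(f)) {
    if (any(!nzchar(f$name))) msg <- c(msg, "feature names must be non-empty")
    if (any(f$start < 0L | f$end > L | f$start >= f$end))
      msg <- c(msg, "feature intervals must lie within [0, length)")
    if (!all(f$strand %in% c(1L, -1L)))
      msg <- c(msg, "strand must be +1 or -1")
    if (!all(f$kind %in% c("protein", "rRNA", "tRNA", "intron", "ORF")))
      msg <- c(msg, "unknown feature kind")
  }
  if (length(msg)) msg else TRUE
})

#' A pair of large repeat copies
#'
#' @slot copyA,copyB integer (start, end), 0-based half-open; copyA starts
#'   first on the linearized sequence.
#' @slot orientation `"inverted"` or `"direct"`.
#' @slot identity fraction of matching positions between the copies.
#' @export
setClass("RepeatPair",
  slots = c(copyA = "integer", copyB = "integer",
            orientation = "character", identity = "numeric"))

setValidity("RepeatPair", function(object) {
  msg <- character()
  if (length(object@copyA) != 2L || length(object@copyB) != 2L)
    msg <- c(msg, "copyA/copyB must be (start, end) pairs")
  else {
    if (diff(object@copyA) != diff(object@copyB))
      msg <- c(msg, "repeat copies must have equal length")
    if (object@copyA[2] > object@copyB[1])
      msg <- c(msg, "repeat copies must not overlap")
  }
  if (!object@orientation %in% c("inverted", "direct"))
    msg <- c(msg, "orientation must be 'inverted' or 'direct'")
  if (length(msg)) msg else TRUE
})

#' Quadripartite partition of a plastome
#'
#' The LSC, SSC and the two large-repeat copies tile the circle exactly once.
#' Genomes without a large repeat degenerate to a single "LSC" spanning the
#' whole circle, with `degenerate = TRUE`.
#'
#' @slot lsc,ssc integer (start, end), 0-based half-open (ssc may wrap
#'   conceptually; stored coordinates never wrap because records are
#'   normalized by rotation).
#' @slot repeatPair a [RepeatPair-class], or a zero-length placeholder when
#'   degenerate.
#' @slot genomeLength total length in bp.
#' @slot degenerate flag: no large repeat found.
#' @export
setClass("RegionPartition",
  slots = c(lsc = "integer", ssc = "integer", repeatPair = "RepeatPair",
            genomeLength = "integer", degenerate = "logical"))

setValidity("RegionPartition", function(object) {
  if (object@degenerate) return(TRUE)
  rp <- object@repeatPair
  total <- diff(object@lsc) + diff(object@ssc) + 2L * diff(rp@copyA)
  if (total != object@genomeLength)
    return("lsc + ssc + 2*repeat must tile the genome exactly")
  if (diff(object@lsc) < diff(object@ssc))
    return("lsc must be at least as long as ssc")
  TRUE
})

#' A genome as an ordered list of signed blocks
#'
#' @slot blocks block (gene) names in genome order.
#' @slot signs +1/-1 orientation per block.
#' @slot circular flag.
#' @slot repeatBlock name of the collapsed large-repeat block, or `NA`.
#' @slot orientationFlag `"IR"`, `"DR"` or `"none"`.
#' @export
setClass("SignedGeneOrder",
  slots = c(blocks = "character", signs = "integer", circular = "logical",
            repeatBlock = "character", orientationFlag = "character"))

setValidity("SignedGeneOrder", function(object) {
  msg <- character()
  if (length(object@blocks) != length(object@signs))
    msg <- c(msg, "blocks and signs must have equal length")
  if (anyDuplicated(object@blocks))
    msg <- c(msg, "each block identifier must appear exactly once")
  if (!all(object@signs %in% c(1L, -1L)))
    msg <- c(msg, "signs must be +1 or -1")
  if (!object@orientationFlag %in% c("IR", "DR", "none"))
    msg <- c(msg, "orientationFlag must be IR, DR or none")
  if (length(msg)) msg else TRUE
})

#' Result of inversion-scenario inference
#'
#' @slot events list of events; each has `interval` (inclusive 1-based
#'   indices in the order current at the time of application), `spansRepeat`
#'   and `label`.
#' @slot distance number of events (equals the exact reversal distance when
#'   `optimal` is `TRUE`).
#' @slot breakpointsInitial breakpoint count between source and target.
#' @slot orientationTrajectory IR/DR states visited, starting at the source
#'   state (length `distance + 1` when orientation is tracked).
#' @slot optimal flag: scenario proven minimal.
#' @slot coOptima list of co-optimal event sequences (each a list of events),
#'   enumerated up to a cap.
#' @export
setClass("InversionScenario",
  slots = c(events = "list", distance = "integer",
            breakpointsInitial = "integer",
            orientationTrajectory = "character",
            optimal = "logical", coOptima = "list"))

#' Species-by-element content matrix
#'
#' States are `"intact"`, `"pseudogene"`, `"absent"` for genes and
#' `"present"`, `"absent"` for introns.
#'
#' @slot states character matrix, taxa in rows, elements in columns.
#' @slot elementKind named character vector: `"protein"`, `"rRNA"`,
#'   `"tRNA"` or `"intron"` per element.
#' @slot hostGene named character vector giving the host gene of each
#'   intron element (`NA` for genes).
#' @export
setClass("ContentMatrix",
  slots = c(states = "matrix", elementKind = "character",
            hostGene = "character"))

setValidity("ContentMatrix", function(object) {
  ok_gene <- c("intact", "pseudogene", "absent")
  ok_intr <- c("present", "absent")
  kinds <- object@elementKind[colnames(object@states)]
  for (j in seq_len(ncol(object@states))) {
    ok <- if (kinds[j] == "intron") ok_intr else ok_gene
    if (!all(object@states[, j] %in% ok))
      return(sprintf("invalid state in element '%s'",
                     colnames(object@states)[j]))
  }
  TRUE
})

#' A fixed topology with per-branch divergence estimates
#'
#' @slot tree an [ape] `phylo` object (topology is an input, never searched).
#' @slot branchValues numeric vector parallel to `tree$edge` rows: d_S for
#'   codon fits, d for nucleotide fits.
#' @slot model provenance string, e.g. `"MG94xF3x4/012232"` or `"GTR+G+I"`.
#' @slot params fitted global parameters (exchangeabilities, frequencies,
#'   alpha, p_inv, log-likelihood, ...).
#' @export
setClass("RateTree",
  slots = c(tree = "ANY", branchValues = "numeric", model = "character",
            params = "list"))

setValidity("RateTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (length(object@branchValues) != nrow(object@tree$edge))
    return("branchValues must be parallel to tree$edge")
  if (any(object@branchValues < -1e-12)) return("branch values must be >= 0")
  TRUE
})
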