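#' @include AllClasses.R
NULL

#' Accessors for plastevol objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x, ...) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x, ...) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("features", function(x, ...) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("recordId", function(x, ...) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setGeneric("blocks", function(x, ...) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setGeneric("signs", function(x, ...) standardGeneric("signs"))
#' @rdname accessors
#' @export
setGeneric("orientationFlag", function(x, ...)
  standardGeneric("orientationFlag"))
#' @rdname accessors
#' @export
setGeneric("repeatOrientation", function(x, ...)
  standardGeneric("repeatOrientation"))
#' @rdname accessors
#' @export
setGeneric("contentStates", function(x, ...) standardGeneric("contentStates"))
#' @rdname accessors
#' @export
setGeneric("branchValues", function(x, ...) standardGeneric("branchValues"))
#' @rdname accessors
#' @export
setGeneric("scenarioEvents", function(x, ...)
  standardGeneric("scenarioEvents"))

#' @rdname accessors
#' @export
setMethod("genomeSeq", "PlastomeRecord", function(x, ...) x@sequence)
#' @rdname accessors
#' @export
setMethod("genomeLength", "PlastomeRecord",
          function(x, ...) length(x@sequence))
#' @rdname accessors
#' @export
setMethod("features", "PlastomeRecord", function(x, ...) x@features)
#' @rdname accessors
#' @export
setMethod("recordId", "PlastomeRecord", function(x, ...) x@id)
#' @rdname accessors
#' @export
setMethod("blocks", "SignedGeneOrder", function(x, ...) x@blocks)
#' @rdname accessors
#' @export
setMethod("signs", "SignedGeneOrder", function(x, ...) x@signs)
#' @rdname accessors
#' @export
setMethod("orientationFlag", "SignedGeneOrder",
          function(x, ...) x@orientationFlag)
#' @rdname accessors
#' @export
setMethod("repeatOrientation", "RepeatPair", function(x, ...) x@orientation)
#' @rdname accessors
#' @export
setMethod("repeatOrientation", "RegionPartition", function(x, ...) {
  if (x@degenerate) "none" else x@repeatPair@orientation
})
#' @rdname accessors
#' @export
setMethod("contentStates", "ContentMatrix", function(x, ...) x@states)
#' @rdname accessors
#' @export
setMethod("branchValues", "RateTree", function(x, ...) x@branchValues)
#' @rdname accessors
#' @export
setMethod("scenarioEvents", "InversionScenario", function(x, ...) x@events)

setMethod("show", "PlastomeRecord", function(object) {
  cat(sprintf("PlastomeRecord '%s': %d bp, %d features\n",
              object@id, length(object@sequence), nrow(object@features)))
  if (nrow(object@features)) {
    tab <- table(object@features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
})

setMethod("show", "RegionPartition", function(object) {
  if (object@degenerate) {
    cat(sprintf("RegionPartition (no large repeat): %d bp single region\n",
                object@genomeLength))
  } else {
    rp <- object@repeatPair
    cat(sprintf(
      "RegionPartition: LSC %d bp, SSC %d bp, repeat 2 x %d bp (%s, id %.3f)\n",
      diff(object@lsc), diff(object@ssc), diff(rp@copyA),
      rp@orientation, rp@identity))
  }
})

setMethod("show", "SignedGeneOrder", function(object) {
  s <- paste0(ifelse(object@signs > 0, "+", "-"), object@blocks)
  cat(sprintf("SignedGeneOrder (%s, %s): %s\n",
              if (object@circular) "circular" else "linear",
              object@orientationFlag,
              paste(s, collapse = " ")))
})

setMethod("show", "InversionScenario", function(object) {
  cat(sprintf(
    "InversionScenario: %d event(s)%s, %d initial breakpoint(s)\n",
    object@distance, if (object@optimal) " (minimal)" else "",
    object@breakpointsInitial))
  for (i in seq_along(object@events)) {
    e <- object@events[[i]]
    cat(sprintf("  %d. invert [%d..%d]%s\n", i, e$interval[1], e$interval[2],
                if (isTRUE(e$spansRepeat)) " (spans repeat)" else ""))
  }
  if (length(object@orientationTrajectory))
    cat("  orientation:",
        paste(object@orientationTrajectory, collapse = " -> "), "\n")
})

setMethod("show", "ContentMatrix", function(object) {
  cat(sprintf("ContentMatrix: %d taxa x %d elements (%s)\n",
              nrow(object@states), ncol(object@states),
              paste(sprintf("%s: %d", names(table(object@elementKind)),
                            table(object@elementKind)), collapse = ", ")))
})

setMethod("show", "RateTree", function(object) {
  cat(sprintf("RateTree (%s): %d tips, %d branches, total length %.4f\n",
              object@model, length(object@tree$tip.label),
              nrow(object@tree$edge), sum(object@branchValues)))
})
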