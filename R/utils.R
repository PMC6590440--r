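## Small shared helpers.

#' Reverse complement of a character DNA string
#' @param s character scalar over A,C,G,T,N.
#' @return character scalar.
#' @keywords internal
revcompChar <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## chartr-based complement for vectors of single bases (fast path used by
## the simulator and repeat extension).
complementBases <- function(v) {
  chartr("ACGTN", "TGCAN", v)
}

#' Rotate a circular sequence so position `offset` (0-based) becomes first
#' @keywords internal
rotateSeq <- function(s, offset) {
  L <- nchar(s)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0) return(s)
  paste0(substr(s, offset + 1L, L), substr(s, 1L, offset))
}

## Rotate feature coordinates to match rotateSeq. Features are assumed not
## to wrap after rotation (callers pick offsets at region boundaries).
rotateFeatures <- function(feat, offset, L) {
  if (!nrow(feat)) return(feat)
  shift <- function(x) ((x - offset) %% L)
  s <- shift(feat$start); e <- shift(feat$end - 1L) + 1L
  if (any(e <= s)) stop("feature would wrap the origin after rotation")
  feat$start <- as.integer(s); feat$end <- as.integer(e)
  feat$exons <- lapply(seq_len(nrow(feat)), function(i) {
    ex <- feat$exons[[i]]
    if (is.null(ex)) return(NULL)
    ex[, 1] <- shift(ex[, 1]); ex[, 2] <- shift(ex[, 2] - 1L) + 1L
    ex[order(ex[, 1]), , drop = FALSE]
  })
  feat[order(feat$start), , drop = FALSE]
}

## An empty features data.frame with the canonical columns.
emptyFeatures <- function() {
  data.frame(name = character(), kind = character(), start = integer(),
             end = integer(), strand = integer(), copy_index = integer(),
             host_gene = character(), exons = I(list()),
             stringsAsFactors = FALSE)
}

makeFeature <- function(name, kind, start, end, strand,
                        copy_index = 0L, host_gene = NA_character_,
                        exons = NULL) {
  if (is.null(exons)) exons <- cbind(start, end)
  data.frame(name = name, kind = kind, start = as.integer(start),
             end = as.integer(end), strand = as.integer(strand),
             copy_index = as.integer(copy_index), host_gene = host_gene,
             exons = I(list(exons)), stringsAsFactors = FALSE)
}

## Plastid (bacterial) genetic code, NCBI translation table 11.
PLASTID_CODE <- local({
  b <- c("T", "C", "A", "G")
  ## TCAG table order: first base slowest, third base fastest
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                   rep(b, 16L))
  ## standard-code amino acids in TCAG order (table 11 shares the standard
  ## codon assignments; only initiation codons differ)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

SENSE_CODONS <- names(PLASTID_CODE)[PLASTID_CODE != "*"]
STOP_CODONS <- names(PLASTID_CODE)[PLASTID_CODE == "*"]

#' Translate a nucleotide string under the plastid code (table 11)
#' @param s character scalar, length divisible by 3 not required (trailing
#'   partial codon is dropped).
#' @return character vector of amino acids ("*" for stops, "X" for codons
#'   containing N).
#' @keywords internal
translatePlastid <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character())
  cod <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- PLASTID_CODE[cod]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

## Split a string into codons.
splitCodons <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## Deterministic per-purpose seed derived from a master seed (kept < 2^31).
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646) + 1L
}
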