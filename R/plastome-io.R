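## Reading and normalizing annotated plastomes and alignments.
##
## Everything downstream consumes the PlastomeRecord produced here:
## coordinates are 0-based half-open on the forward strand, compound
## (join/complement) locations are kept as exon lists, and duplicate gene
## names receive distinct copy_index values in order of appearance.

#' @include AllClasses.R AllGenerics.R
NULL

#' A validated multiple sequence alignment
#'
#' @slot seqs named character vector of equal-length gapped sequences.
#' @slot datatype `"codon"` or `"nucleotide"`.
#' @export
setClass("Alignment", slots = c(seqs = "character", datatype = "character"))

setValidity("Alignment", function(object) {
  if (!length(object@seqs)) return("alignment has no sequences")
  if (length(unique(nchar(object@seqs))) != 1L)
    return("alignment rows must have equal length")
  if (object@datatype == "codon" && nchar(object@seqs[1]) %% 3L != 0L)
    return("codon alignment length must be divisible by 3")
  TRUE
})

#' @rdname accessors
#' @export
setGeneric("alignedSeqs", function(x, ...) standardGeneric("alignedSeqs"))
#' @rdname accessors
#' @export
setMethod("alignedSeqs", "Alignment", function(x, ...) x@seqs)

setMethod("show", "Alignment", function(object) {
  cat(sprintf("Alignment (%s): %d taxa x %d columns\n", object@datatype,
              length(object@seqs), nchar(object@seqs[1])))
})

## ---------------------------------------------------------------------------
## Gene-name normalization

.synonym_cache <- new.env(parent = emptyenv())

geneNameTable <- function() {
  if (!is.null(.synonym_cache$tab)) return(.synonym_cache$tab)
  path <- system.file("extdata", "gene_name_synonyms.tsv",
                      package = "plastevol")
  tab <- if (nzchar(path))
    read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  else data.frame(alias = character(), canonical = character())
  .synonym_cache$tab <- tab
  tab
}

#' Normalize a gene symbol to the catalog convention
#'
#' GenBank records use inconsistent symbols (e.g. `trnT(ggu)` vs
#' `trnT-GGU`); a versioned mapping file plus a few deterministic rewrite
#' rules brings them to one convention.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalizeGeneName <- function(x) {
  x <- trimws(x)
  ## trnX(abc) / trnX_abc -> trnX-ABC
  m <- grepl("^trn", x)
  x[m] <- gsub("^((trn)[A-Za-z]{1,2})[\\(_-]([A-Za-z]{3})\\)?$",
               "\\1-\\3", x[m])
  x[m] <- sub("^(trn[A-Za-z]{1,2}-)([a-z]{3})$", "\\1\\U\\2", x[m],
              perl = TRUE)
  x <- sub("^16S.*", "rrn16", x)
  x <- sub("^23S.*", "rrn23", x)
  x <- sub("^4\\.5S.*", "rrn4.5", x)
  x <- sub("^5S.*", "rrn5", x)
  tab <- geneNameTable()
  hit <- match(x, tab$alias)
  x[!is.na(hit)] <- tab$canonical[hit[!is.na(hit)]]
  x
}

## ---------------------------------------------------------------------------
## GenBank flat-file parsing

## Parse a GenBank location string into (strand, exon matrix). Coordinates
## come in 1-based inclusive and leave 0-based half-open.
parseLocation <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join|order", loc))
    stop("unsupported nested location: ", loc)
  parts <- strsplit(loc, ",")[[1]]
  ex <- t(vapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (anyNA(xs)) stop("malformed location segment: ", p)
    if (length(xs) == 1L) xs <- c(xs, xs)
    c(xs[1] - 1L, xs[2])
  }, integer(2)))
  dimnames(ex) <- NULL
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  list(strand = strand, exons = ex)
}

.gbQualifier <- function(quals, key) {
  hit <- grep(paste0("^/", key, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^/[^=]+="?|"$', "", hit[1])
}

#' Read an annotated plastome
#'
#' Parses a GenBank flat file (or a plain FASTA, which yields a record with
#' an empty feature table and a warning) into a [PlastomeRecord-class].
#' CDS features become kind `"protein"` (or `"ORF"` for `orf*` symbols);
#' tRNA, rRNA and intron features keep their kind. Coordinates are converted
#' to the 0-based half-open internal convention; joined locations are
#' preserved as exon lists; duplicated gene names receive distinct
#' `copy_index` values in coordinate order.
#'
#' @param path file path.
#' @param format `"genbank"` or `"fasta"`; `"auto"` sniffs the first line.
#' @return a [PlastomeRecord-class].
#' @export
readPlastome <- function(path, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  if (format == "auto")
    format <- if (grepl("^LOCUS", lines[1])) "genbank" else "fasta"

  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L)
      stop("expected a single sequence in ", path)
    warning("FASTA input carries no feature table; record has no features")
    seq <- toupper(as.character(ss[[1]]))
    seq <- cleanAlphabet(seq, path)
    return(new("PlastomeRecord", id = names(ss)[1],
               sequence = Biostrings::DNAString(seq),
               features = emptyFeatures(), source = path))
  }

  id <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "[[:space:]]+")[[1]][1]
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("no ORIGIN section in ", path)

  ## sequence
  seqlines <- lines[(ostart[1] + 1L):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  seq <- cleanAlphabet(seq, path)

  feats <- emptyFeatures()
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
    flines <- lines[(fstart[1] + 1L):fend]
    ## a new feature starts at column 6 with a non-blank key
    is_key <- grepl("^ {2,8}[A-Za-z''_0-9-]+ +\\S", flines) &
      !grepl("^ {21}", flines)
    idx <- which(is_key)
    rows <- list()
    for (k in seq_along(idx)) {
      block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1] - 1L
                              else length(flines))]
      key <- sub("^ +(\\S+).*", "\\1", block[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "intron", "gene", "ORF"))
        next
      ## location may continue over lines until the first qualifier
      qstart <- grep("^ +/", block)
      locend <- if (length(qstart)) qstart[1] - 1L else length(block)
      loc <- paste(c(sub("^ +\\S+ +", "", block[1]),
                     trimws(block[seq_len(locend)[-1]])), collapse = "")
      quals <- trimws(block[seq_len(length(block)) >= min(c(qstart,
                                                            Inf))])
      pl <- tryCatch(parseLocation(loc), error = function(e)
        stop("cannot parse feature ", key, " in ", path, ": ",
             conditionMessage(e)))
      gene <- .gbQualifier(quals, "gene")
      std <- .gbQualifier(quals, "standard_name")
      name <- if (!is.na(std)) std else gene
      if (is.na(name)) name <- .gbQualifier(quals, "product")
      if (is.na(name) || !nzchar(name)) next
      kind <- switch(key, CDS = "protein", tRNA = "tRNA", rRNA = "rRNA",
                     intron = "intron", gene = NA_character_, ORF = "ORF")
      if (is.na(kind)) next       # bare 'gene' features duplicate typed ones
      name <- normalizeGeneName(name)
      if (kind == "protein" && grepl("^orf", name, ignore.case = TRUE))
        kind <- "ORF"
      host <- if (kind == "intron") normalizeGeneName(gene) else NA_character_
      ex <- pl$exons
      rows[[length(rows) + 1L]] <- makeFeature(
        name, kind, min(ex[, 1]), max(ex[, 2]), pl$strand,
        host_gene = host, exons = ex)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  if (!nrow(feats))
    warning("no features parsed from ", path)
  feats <- assignCopyIndex(feats)
  feats <- feats[order(feats$start, feats$end, feats$name), , drop = FALSE]
  rownames(feats) <- NULL
  new("PlastomeRecord", id = id, sequence = Biostrings::DNAString(seq),
      features = feats, source = path)
}

## Non-ACGTN ambiguity codes are converted to N with a warning: downstream
## GC and model code assumes the 4+1 alphabet.
cleanAlphabet <- function(seq, path) {
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    warning(sprintf("%d ambiguity character(s) converted to N in %s",
                    nchar(bad), path))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

## Distinct copy_index per duplicate (name, kind), in coordinate order.
assignCopyIndex <- function(feats) {
  if (!nrow(feats)) return(feats)
  feats <- feats[order(feats$start), , drop = FALSE]
  key <- paste(feats$name, feats$kind)
  feats$copy_index <- as.integer(stats::ave(seq_along(key), key,
                                            FUN = seq_along) - 1L)
  feats
}

#' Write a PlastomeRecord as a GenBank flat file
#'
#' Inverse of [readPlastome()]: write-then-read reproduces identical
#' features and sequence.
#'
#' @param record a [PlastomeRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(record, path) {
  L <- genomeLength(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     circular PLN %s",
    recordId(record), L, "01-JAN-2000"), con)
  writeLines(sprintf("DEFINITION  %s plastid genome.", recordId(record)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- features(record)
  if (nrow(f)) f <- f[order(f$start, f$end, f$name), , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    ex <- f$exons[[i]]
    segs <- sprintf("%d..%d", ex[, 1] + 1L, ex[, 2])
    loc <- if (nrow(ex) > 1L)
      sprintf("join(%s)", paste(segs, collapse = ",")) else segs
    if (f$strand[i] < 0L) loc <- sprintf("complement(%s)", loc)
    key <- switch(f$kind[i], protein = "CDS", ORF = "CDS", f$kind[i])
    writeLines(sprintf("     %-15s %s", key, loc), con)
    gene <- if (f$kind[i] == "intron") f$host_gene[i] else f$name[i]
    if (!is.na(gene))
      writeLines(sprintf('                     /gene="%s"', gene), con)
    if (f$kind[i] == "intron")
      writeLines(sprintf('                     /standard_name="%s"',
                         f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(as.character(genomeSeq(record)))
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Alignments

#' Read a FASTA alignment
#'
#' @param path FASTA file with equal-length gapped rows.
#' @param datatype `"codon"` or `"nucleotide"`; codon alignments must have
#'   a length divisible by 3.
#' @return an [Alignment-class].
#' @export
readAlignment <- function(path, datatype = c("nucleotide", "codon")) {
  datatype <- match.arg(datatype)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(setNames(as.character(ss), names(ss)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(lens),
                                                 collapse = ", "))
  bad <- gsub("[ACGTUNRYSWKMBDHV.?-]", "", paste(seqs, collapse = ""))
  if (nzchar(bad))
    stop("non-IUPAC characters in alignment: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  seqs <- gsub("U", "T", seqs)
  new("Alignment", seqs = seqs, datatype = datatype)
}

## ---------------------------------------------------------------------------
## Signed gene orders

#' Extract the signed gene order of a plastome
#'
#' Genes (protein, rRNA, tRNA, ORF; introns excluded) are ordered by start
#' coordinate around the circle with sign equal to strand. The linearization
#' is rotated (and reflected if needed) to a canonical anchor so that any
#' circular rotation or full reverse complement of the same genome yields an
#' identical order. With `collapseRepeat = TRUE` the second repeat copy's
#' genes are dropped and the repeat is represented as one signed block
#' (`"REP"`) plus the partition's IR/DR orientation flag.
#'
#' @param record a [PlastomeRecord-class].
#' @param collapseRepeat collapse the large repeat to one block.
#' @param partition a [RegionPartition-class]; required when
#'   `collapseRepeat = TRUE`, optional otherwise (used for LSC-anchored
#'   canonicalization when present).
#' @return a [SignedGeneOrder-class].
#' @export
extractGeneOrder <- function(record, collapseRepeat = FALSE,
                             partition = NULL) {
  f <- features(record)
  f <- f[f$kind != "intron", , drop = FALSE]
  if (!nrow(f)) stop("record has no gene features")
  dup <- duplicated(paste(f$name, f$copy_index))
  if (any(dup))
    stop("duplicate features without distinct copy_index: ",
         paste(unique(f$name[dup]), collapse = ", "))
  f <- f[order(f$start), , drop = FALSE]

  flag <- "none"
  if (collapseRepeat) {
    if (is.null(partition))
      stop("collapseRepeat requires a RegionPartition")
    if (partition@degenerate)
      stop("cannot collapse repeat: partition is degenerate")
    rp <- partition@repeatPair
    flag <- if (rp@orientation == "inverted") "IR" else "DR"
    inB <- f$start >= rp@copyB[1] & f$end <= rp@copyB[2]
    f <- f[!inB, , drop = FALSE]
    inA <- f$start >= rp@copyA[1] & f$end <= rp@copyA[2]
    keep <- !inA
    ## the repeat block's sign follows the majority strand of the genes
    ## annotated inside copy A (+1 when the copy carries no genes)
    repSign <- if (any(inA)) {
      if (sum(f$strand[inA] > 0) >= sum(f$strand[inA] < 0)) 1L else -1L
    } else 1L
    repRow <- makeFeature("REP", "ORF", rp@copyA[1], rp@copyA[2], repSign)
    f <- rbind(f[keep, , drop = FALSE], repRow)
    f <- f[order(f$start), , drop = FALSE]
    if (anyDuplicated(f$name))
      stop("duplicate single-copy gene names after repeat collapse: ",
           paste(unique(f$name[duplicated(f$name)]), collapse = ", "))
  } else if (anyDuplicated(f$name)) {
    ## keep duplicate copies distinguishable
    k <- f$copy_index > 0L
    f$name[k] <- paste0(f$name[k], "#", f$copy_index[k])
  }

  ord <- new("SignedGeneOrder", blocks = f$name, signs = f$strand,
             circular = TRUE, repeatBlock =
               if (collapseRepeat) "REP" else NA_character_,
             orientationFlag = flag)
  canonicalizeOrder(ord)
}

## Canonical linearization of a circular signed order: among all rotations
## of the order and of its reflection (reverse + sign flip), pick the
## lexicographically smallest (by block name — duplicate-copy suffixes
## ignored — then sign). Duplicated blocks are then relabeled in order of
## appearance, so the result is invariant to rotation and to the reverse
## complement of the input genome even when duplicates are present.
canonicalizeOrder <- function(ord) {
  if (!ord@circular) return(ord)
  n <- length(ord@blocks)
  base <- sub("#[0-9]+$", "", ord@blocks)
  cand <- list()
  addRot <- function(bl, sg) {
    for (r in seq_len(n)) {
      idx <- c(seq(r, n), if (r > 1L) seq(1L, r - 1L))
      cand[[length(cand) + 1L]] <<- list(bl = bl[idx], sg = sg[idx])
    }
  }
  addRot(base, ord@signs)
  addRot(rev(base), -rev(ord@signs))
  keys <- vapply(cand, function(x)
    paste(x$bl, ifelse(x$sg > 0, "+", "-"), collapse = "\r"), "")
  best <- cand[[which.min(rank(keys, ties.method = "first"))]]
  bl <- best$bl
  if (anyDuplicated(bl)) {
    k <- as.integer(stats::ave(seq_along(bl), bl, FUN = seq_along)) - 1L
    bl[k > 0L] <- paste0(bl[k > 0L], "#", k[k > 0L])
  }
  new("SignedGeneOrder", blocks = bl, signs = best$sg,
      circular = TRUE, repeatBlock = ord@repeatBlock,
      orientationFlag = ord@orientationFlag)
}

#' Write/read signed gene orders in a GRIMM-style exchange format
#'
#' One line per genome: `>id [flag]` then signed space-separated block
#' names, e.g. `+psbA -trnF +REP`.
#'
#' @param orders named list of [SignedGeneOrder-class] objects.
#' @param path output path.
#' @return `path` invisibly (writer); named list of orders (reader).
#' @export
writeGeneOrders <- function(orders, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(orders)) {
    o <- orders[[nm]]
    writeLines(sprintf(">%s %s", nm, o@orientationFlag), con)
    writeLines(paste(paste0(ifelse(o@signs > 0, "+", "-"), o@blocks),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname writeGeneOrders
#' @export
readGeneOrders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  out <- list()
  for (h in seq_along(heads)) {
    hd <- strsplit(sub("^>", "", lines[heads[h]]), "[[:space:]]+")[[1]]
    toks <- strsplit(trimws(lines[heads[h] + 1L]), "[[:space:]]+")[[1]]
    sg <- ifelse(substr(toks, 1, 1) == "-", -1L, 1L)
    bl <- sub("^[+-]", "", toks)
    if (anyDuplicated(bl)) {       # duplicates get distinct copy suffixes
      k <- as.integer(stats::ave(seq_along(bl), bl, FUN = seq_along)) - 1L
      bl[k > 0L] <- paste0(bl[k > 0L], "#", k[k > 0L])
    }
    flag <- if (length(hd) > 1L && hd[2] %in% c("IR", "DR")) hd[2] else "none"
    out[[hd[1]]] <- new("SignedGeneOrder", blocks = bl, signs = sg,
                        circular = TRUE,
                        repeatBlock = if ("REP" %in% bl) "REP"
                                      else NA_character_,
                        orientationFlag = flag)
  }
  out
}
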