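## Quadripartite structure: detection of the large two-copy repeat,
## IR/DR orientation, LSC/SSC partition, and per-region statistics.
##
## Detection is seed-and-extend over exact k-mer matches (k = 21) of the
## sequence against itself and its reverse complement: collinear seeds are
## merged into candidate diagonals, the best candidate is extended outward
## tolerating mismatches with a drop-off window. Deterministic, desk-scale.
## An all-pairs dynamic-programming oracle lives in the test suite only.

#' @include AllClasses.R AllGenerics.R
NULL

#' Find the large two-copy repeat of a plastome
#'
#' Returns the highest-scoring pair of maximal near-exact repeats of at
#' least `minLen` bp, extended to maximal identity-preserving boundaries.
#' Orientation is `"direct"` if both matches lie on the same strand and
#' `"inverted"` otherwise. N bases count as mismatches.
#'
#' @param record a [PlastomeRecord-class] (or a plain character sequence).
#' @param minLen minimum repeat length in bp (default 1000; the plastome
#'   repeats this targets are all >= 7.3 kb, so the threshold excludes
#'   tRNA-scale repeats with a wide margin).
#' @param minIdentity minimum fraction of matching positions (default 0.98).
#' @param k seed k-mer length.
#' @param dropOff mismatch-tolerant extension stops when the last `dropOff`
#'   bp window is more than half mismatches (default 50 bp).
#' @return a [RepeatPair-class], or `NULL` (with class `"noLargeRepeat"`
#'   attribute semantics handled by [partitionRegions()]) when no repeat of
#'   `minLen` is found.
#' @export
findLargeRepeat <- function(record, minLen = 1000L, minIdentity = 0.98,
                            k = 21L, dropOff = 50L) {
  s <- if (is(record, "PlastomeRecord"))
    as.character(genomeSeq(record)) else toupper(as.character(record))
  L <- nchar(s)
  if (L <= 2L * minLen)
    stop("sequence length must exceed 2*minLen")
  ch <- strsplit(s, "")[[1]]

  n <- L - k + 1L
  km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  rcs <- revcompChar(s)
  kmr <- rev(substring(rcs, seq_len(n), seq_len(n) + k - 1L))
  ## kmr[i] is now the reverse complement of the k-mer starting at i

  cands <- list()

  ## Direct repeats: identical forward k-mers at two positions.
  dupk <- unique(km[duplicated(km)])
  if (length(dupk)) {
    idx <- which(km %in% dupk)
    grp <- split(idx, km[idx])
    grp <- grp[vapply(grp, length, 1L) <= 6L]  # skip low-complexity seeds
    if (length(grp)) {
      pairs <- do.call(rbind, lapply(grp, function(g) {
        if (length(g) < 2L) return(NULL)
        t(combn(sort(g), 2L))
      }))
      if (!is.null(pairs) && nrow(pairs)) {
        diag <- pairs[, 2] - pairs[, 1]
        for (d in unique(diag)) {
          ii <- sort(pairs[diag == d, 1])
          runs <- seedRuns(ii, k)
          for (r in runs) {
            if (r[2] - r[1] + k >= max(minLen %/% 2L, 2L * k))
              cands[[length(cands) + 1L]] <-
                list(i = r[1], j = r[1] + d, len = r[2] - r[1] + k,
                     orient = "direct")
          }
        }
      }
    }
  }

  ## Inverted repeats: forward k-mer at i equals reverse complement of the
  ## k-mer at j; the anti-diagonal i + j is constant along a run.
  common <- intersect(km, kmr)
  common <- setdiff(common, km[km %in% kmr & km == kmr])  # palindromic noise
  if (length(common)) {
    fi <- split(which(km %in% common), km[which(km %in% common)])
    ri <- split(which(kmr %in% common), kmr[which(kmr %in% common)])
    keys <- intersect(names(fi), names(ri))
    pairs <- do.call(rbind, lapply(keys, function(kk) {
      a <- fi[[kk]]; b <- ri[[kk]]
      if (length(a) * length(b) > 12L) return(NULL)
      as.matrix(expand.grid(i = a, j = b))
    }))
    if (!is.null(pairs) && nrow(pairs)) {
      pairs <- pairs[pairs[, 2] > pairs[, 1] + k, , drop = FALSE]
      anti <- pairs[, 1] + pairs[, 2]
      for (d in unique(anti)) {
        ii <- sort(pairs[anti == d, 1])
        runs <- seedRuns(ii, k)
        for (r in runs) {
          if (r[2] - r[1] + k >= max(minLen %/% 2L, 2L * k))
            cands[[length(cands) + 1L]] <-
              list(i = r[1], j = d - r[2], len = r[2] - r[1] + k,
                   orient = "inverted")
        }
      }
    }
  }

  if (!length(cands)) return(NULL)
  lens <- vapply(cands, `[[`, 1L, "len")
  best <- cands[[which.max(lens)]]

  rp <- extendRepeat(ch, best, dropOff)
  len <- rp$aEnd - rp$aStart + 1L
  if (len < minLen || rp$identity < minIdentity) return(NULL)
  new("RepeatPair",
      copyA = c(rp$aStart - 1L, rp$aEnd),
      copyB = c(rp$bStart - 1L, rp$bEnd),
      orientation = best$orient, identity = rp$identity)
}

## Maximal runs of consecutive seed starts (step 1 collapses to intervals).
seedRuns <- function(ii, k) {
  if (!length(ii)) return(list())
  brk <- c(0L, which(diff(ii) > k), length(ii))
  lapply(seq_len(length(brk) - 1L), function(t)
    c(ii[brk[t] + 1L], ii[brk[t + 1L]]))
}

## Extend a seeded match outward base by base, stopping when the trailing
## dropOff-bp window falls below 50% identity; then trim back to the last
## matching base. 1-based inclusive coordinates internally.
extendRepeat <- function(ch, cand, dropOff) {
  L <- length(ch)
  inv <- cand$orient == "inverted"
  a1 <- cand$i; a2 <- cand$i + cand$len - 1L
  if (inv) { b2 <- cand$j + cand$len - 1L; b1 <- cand$j }
  else { b1 <- cand$j; b2 <- cand$j + cand$len - 1L }

  matchAt <- function(pa, pb) {
    if (pa < 1L || pa > L || pb < 1L || pb > L) return(NA)
    x <- ch[pa]; y <- ch[pb]
    if (x == "N" || y == "N") return(FALSE)
    if (inv) x == complementBases(y) else x == y
  }
  xdrop <- max(6L, dropOff %/% 4L)
  stepOut <- function(dirA) {
    ## dirA = -1: extend left end of copy A; +1: extend right end.
    ## X-drop extension: +1 per match, -3 per mismatch; stop when the
    ## score falls `xdrop` below its running maximum, then trim back to
    ## the best-scoring endpoint.
    score <- 0L; best <- 0L; gained <- 0L; bestGain <- 0L
    repeat {
      if (dirA < 0) { pa <- a1 - 1L; pb <- if (inv) b2 + 1L else b1 - 1L }
      else          { pa <- a2 + 1L; pb <- if (inv) b1 - 1L else b2 + 1L }
      ## keep copies disjoint and on the linear sequence
      if (pa < 1L || pa > L || pb < 1L || pb > L) break
      if (dirA < 0 && !inv && pb <= a2) break
      if (dirA > 0 && pa >= min(b1, b2)) break
      if (dirA > 0 && inv && pb <= a2) break
      m <- matchAt(pa, pb)
      if (is.na(m)) break
      score <- score + if (m) 1L else -3L
      if (dirA < 0) { a1 <<- pa; if (inv) b2 <<- pb else b1 <<- pb }
      else          { a2 <<- pa; if (inv) b1 <<- pb else b2 <<- pb }
      gained <- gained + 1L
      if (score > best) { best <- score; bestGain <- gained }
      if (best - score >= xdrop) break
    }
    ntrim <- gained - bestGain
    if (ntrim > 0L) {
      if (dirA < 0) { a1 <<- a1 + ntrim
        if (inv) b2 <<- b2 - ntrim else b1 <<- b1 + ntrim }
      else { a2 <<- a2 - ntrim
        if (inv) b1 <<- b1 + ntrim else b2 <<- b2 - ntrim }
    }
  }
  stepOut(-1L); stepOut(1L)

  seqA <- ch[a1:a2]
  seqB <- if (inv) rev(complementBases(ch[b1:b2])) else ch[b1:b2]
  ok <- seqA == seqB & seqA != "N" & seqB != "N"
  list(aStart = a1, aEnd = a2, bStart = b1, bEnd = b2,
       identity = mean(ok))
}

#' Classify repeat orientation
#'
#' @param rp a [RepeatPair-class].
#' @return `"IR"` (copies on opposite strands) or `"DR"` (same strand).
#' @export
classifyOrientation <- function(rp) {
  stopifnot(is(rp, "RepeatPair"))
  if (rp@orientation == "direct") "DR" else "IR"
}

#' Partition a plastome into LSC, SSC and repeat copies
#'
#' The two arcs between the repeat copies are assigned LSC (longer) and SSC
#' (shorter); the four regions tile the circle exactly. With `rp = NULL`
#' (no large repeat) a degenerate partition is returned: the whole circle
#' as a single region with `degenerate = TRUE`.
#'
#' @param record a [PlastomeRecord-class].
#' @param rp a [RepeatPair-class] from [findLargeRepeat()], or `NULL`.
#' @return a [RegionPartition-class].
#' @export
partitionRegions <- function(record, rp) {
  L <- genomeLength(record)
  if (is.null(rp))
    return(new("RegionPartition", lsc = c(0L, L), ssc = c(0L, 0L),
               repeatPair = new("RepeatPair", copyA = c(0L, 0L),
                                copyB = c(0L, 0L), orientation = "inverted",
                                identity = 1),
               genomeLength = L, degenerate = TRUE))
  arc1 <- c(rp@copyA[2], rp@copyB[1])          # between A end and B start
  arc2 <- c(rp@copyB[2], rp@copyA[1] + L)      # wraps the origin
  len1 <- diff(arc1); len2 <- diff(arc2)
  if (len1 == 0L || len2 == 0L)
    stop("repeat copies are adjacent: zero-length single-copy arc")
  if (len1 >= len2) { lsc <- arc1; ssc <- arc2 } else {
    lsc <- arc2; ssc <- arc1 }
  new("RegionPartition", lsc = as.integer(lsc), ssc = as.integer(ssc),
      repeatPair = rp, genomeLength = L, degenerate = FALSE)
}

## Substring on the circle, 0-based half-open, end may exceed L (wraps).
circSubstr <- function(s, start, end) {
  L <- nchar(s)
  if (end <= L) return(substr(s, start + 1L, end))
  paste0(substr(s, start + 1L, L), substr(s, 1L, end - L))
}

## GC percent with N excluded from numerator and denominator.
gcPercent <- function(s) {
  tab <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T",
                                                       "N")))
  denom <- sum(tab[c("A", "C", "G", "T")])
  if (denom == 0) return(NA_real_)
  100 * sum(tab[c("C", "G")]) / denom
}

#' Per-region lengths, GC content and unique gene counts
#'
#' Mirrors the usual per-genome summary table: total/repeat/LSC/SSC lengths
#' and GC percentages, plus unique counts of protein, rRNA and tRNA genes
#' and introns (second repeat copies, `copy_index > 0`, are not counted).
#'
#' @param record a [PlastomeRecord-class].
#' @param partition a [RegionPartition-class].
#' @return a one-row `data.frame`.
#' @export
regionStats <- function(record, partition) {
  s <- as.character(genomeSeq(record))
  L <- nchar(s)
  f <- features(record)
  uniq <- f[f$copy_index == 0L, , drop = FALSE]
  counts <- c(
    protein = sum(uniq$kind %in% c("protein", "ORF")),
    rRNA = sum(uniq$kind == "rRNA"),
    tRNA = sum(uniq$kind == "tRNA"),
    introns = sum(uniq$kind == "intron"))
  if (partition@degenerate) {
    return(data.frame(id = recordId(record), length = L,
                      repeat_len = 0L, lsc_len = L, ssc_len = 0L,
                      gc_total = gcPercent(s), gc_repeat = NA_real_,
                      gc_lsc = gcPercent(s), gc_ssc = NA_real_,
                      n_protein = counts[["protein"]],
                      n_rrna = counts[["rRNA"]], n_trna = counts[["tRNA"]],
                      n_introns = counts[["introns"]],
                      stringsAsFactors = FALSE))
  }
  rp <- partition@repeatPair
  repSeq <- paste0(circSubstr(s, rp@copyA[1], rp@copyA[2]),
                   circSubstr(s, rp@copyB[1], rp@copyB[2]))
  data.frame(id = recordId(record), length = L,
             repeat_len = diff(rp@copyA),
             lsc_len = diff(partition@lsc), ssc_len = diff(partition@ssc),
             gc_total = gcPercent(s),
             gc_repeat = gcPercent(repSeq),
             gc_lsc = gcPercent(circSubstr(s, partition@lsc[1],
                                           partition@lsc[2])),
             gc_ssc = gcPercent(circSubstr(s, partition@ssc[1],
                                           partition@ssc[2])),
             n_protein = counts[["protein"]], n_rrna = counts[["rRNA"]],
             n_trna = counts[["tRNA"]], n_introns = counts[["introns"]],
             stringsAsFactors = FALSE)
}
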