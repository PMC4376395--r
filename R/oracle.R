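# Exhaustive structure-enumeration oracle for the simplified energy model.
# Pure R, independent of the dynamic-programming engine in src/: the two are
# compared in the test-suite and must agree exactly on the shared model.

.pairTypeCode <- function(a, b) {
  # codes 0=A 1=C 2=G 3=U; returns 0 when (a,b) cannot pair
  if (a == 1L && b == 2L) return(1L)
  if (a == 2L && b == 1L) return(2L)
  if (a == 2L && b == 3L) return(3L)
  if (a == 3L && b == 2L) return(4L)
  if (a == 0L && b == 3L) return(5L)
  if (a == 3L && b == 0L) return(6L)
  0L
}

#' Exhaustively enumerate secondary structures under the simplified model
#'
#' Lists every pseudoknot-free pairing (Watson-Crick + wobble, minimum hairpin
#' loop of 3 bases within a strand) of one strand, or of the bimolecular
#' complex of two strands, and scores each with the stacking-only energy model
#' shared with the internal engine. Intended as a test oracle; the total
#' length is capped.
#'
#' @param seqA nucleotide string (DNA or RNA alphabet).
#' @param seqB optional second strand (bimolecular complex).
#' @param minLoop minimum hairpin loop size.
#' @param maxTotal guard on total length (default 50).
#' @return data.frame with columns `structure` (dot-bracket; `&` marks the
#'   strand break), `energy` (kcal/mol) and `npairs`.
#' @examples
#' enumerateStructuresOracle("GGGAAAACCC")
#' @export
enumerateStructuresOracle <- function(seqA, seqB = NULL, minLoop = 3L,
                                      maxTotal = 50L) {
  a <- .encodeRNA(seqA, "strand A")
  b <- if (is.null(seqB)) integer() else .encodeRNA(seqB, "strand B")
  codes <- c(a, b)
  nick <- if (length(b)) length(a) else 0L
  n <- length(codes)
  if (n > maxTotal)
    stop("oracle length cap exceeded (", n, " > ", maxTotal, ")",
         call. = FALSE)
  canpair <- function(i, j) {
    if (.pairTypeCode(codes[i], codes[j]) == 0L) return(FALSE)
    across <- nick > 0L && i <= nick && j > nick
    across || (j - i - 1L) >= minLoop
  }
  # recursive enumeration over [i, j]; returns list of pair lists
  recur <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- lapply(recur(i + 1L, j), identity)  # i unpaired
    for (k in (i + 1L):j) {
      if (!canpair(i, k)) next
      lefts <- recur(i + 1L, k - 1L)
      rights <- recur(k + 1L, j)
      for (l in lefts) for (r in rights)
        out[[length(out) + 1L]] <- c(list(c(i, k)), l, r)
    }
    out
  }
  structs <- recur(1L, n)
  st <- stackTable()
  energyOf <- function(pairs) {
    if (!length(pairs)) return(0)
    p <- rep(0L, n)
    for (pr in pairs) { p[pr[1]] <- pr[2]; p[pr[2]] <- pr[1] }
    e <- 0
    for (pr in pairs) {
      i <- pr[1]; j <- pr[2]
      # stack with inner adjacent pair, unless the nick interrupts adjacency
      if (j - i >= 3L && p[i + 1L] == j - 1L &&
          !(nick > 0L && (i == nick || j - 1L == nick))) {
        p1 <- .pairTypeCode(codes[i], codes[j])
        p2 <- .pairTypeCode(codes[j - 1L], codes[i + 1L])
        if (p1 > 0L && p2 > 0L) e <- e + st[p1, p2]
      }
    }
    e
  }
  dotBracket <- function(pairs) {
    ch <- rep(".", n)
    for (pr in pairs) { ch[pr[1]] <- "("; ch[pr[2]] <- ")" }
    s <- paste(ch, collapse = "")
    if (nick > 0L) s <- paste0(substr(s, 1, nick), "&",
                               substr(s, nick + 1L, n))
    s
  }
  data.frame(structure = vapply(structs, dotBracket, ""),
             energy = vapply(structs, energyOf, 0),
             npairs = vapply(structs, length, 0L))
}

#' @describeIn enumerateStructuresOracle minimum energy over the enumerated
#'   spectrum.
#' @export
oracleMinEnergy <- function(seqA, seqB = NULL, minLoop = 3L) {
  min(enumerateStructuresOracle(seqA, seqB, minLoop)$energy)
}

#' @describeIn enumerateStructuresOracle Boltzmann-weighted per-base unpaired
#'   probabilities over the full enumerated spectrum (37 C).
#' @export
oracleUnpairedProbs <- function(seqA, minLoop = 3L) {
  sp <- enumerateStructuresOracle(seqA, NULL, minLoop)
  w <- exp(-sp$energy / .kT37)
  n <- nchar(gsub("&", "", sp$structure[1]))
  chars <- do.call(rbind, strsplit(sp$structure, ""))
  unpaired <- chars == "."
  colSums(unpaired * w) / sum(w)
}

#' Count secondary structures by recursion (independent of enumeration)
#'
#' Memoized interval recursion counting all pseudoknot-free pairings under the
#' same pairing rules as [enumerateStructuresOracle()]; used to cross-check
#' the enumeration's completeness.
#'
#' @param seq nucleotide string.
#' @param minLoop minimum hairpin loop size.
#' @return structure count (numeric).
#' @export
countStructures <- function(seq, minLoop = 3L) {
  codes <- .encodeRNA(seq)
  n <- length(codes)
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (k in (i + 1L):j) {
      if (.pairTypeCode(codes[i], codes[k]) == 0L ||
          (k - i - 1L) < minLoop) next
      total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1L, n)
}
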