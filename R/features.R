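# Sequence-motif and GC-architecture descriptors, and assembly of the full
# per-oligo descriptor vector.

#' Read a hexamer score table
#'
#' Two-column delimited text (`hexamer<TAB>score`) mapping all 4096 DNA
#' hexamers to a neighborhood-inference (NI) score, an estimate of splice
#' factor binding propensity derived from the similarity of a hexamer to known
#' splice-factor motifs in sequence space.
#'
#' @param path file path.
#' @return named numeric vector of length 4096.
#' @export
readHexamerTable <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("hexamer table must have two columns (hexamer, score)",
         call. = FALSE)
  scores <- stats::setNames(as.numeric(tab[[2L]]), toupper(tab[[1L]]))
  .validateHexamerTable(scores)
}

.validateHexamerTable <- function(scores) {
  if (length(scores) != 4096L || anyDuplicated(names(scores)) ||
      !all(grepl("^[ACGT]{6}$", names(scores))))
    stop("hexamer table must contain exactly the 4096 ACGT hexamers",
         call. = FALSE)
  if (anyNA(scores)) stop("hexamer table contains NA scores", call. = FALSE)
  scores
}

.hexWindows <- function(targetSeq) {
  .assertDNA(targetSeq, "target sequence")
  L <- nchar(targetSeq)
  if (L < 6L)
    stop("target must be at least 6 bases for hexamer scoring", call. = FALSE)
  vapply(seq_len(L - 5L), function(i) substr(targetSeq, i, i + 5L), "")
}

#' Cumulative and per-base NI scores of a target site
#'
#' The cumulative score is the sum of the table scores of all `L - 5`
#' overlapping hexamers of the target; the per-base score divides by the
#' target length.
#'
#' @param targetSeq target (sense, DNA) sequence of length >= 6.
#' @param table named numeric hexamer table (see [readHexamerTable()]).
#' @return named numeric: `ni_cumulative`, `ni_per_base`.
#' @examples
#' tab <- synthHexamerTable(1)
#' niScores(strrep("ACGT", 5), tab)
#' @export
niScores <- function(targetSeq, table) {
  table <- .validateHexamerTable(table)
  hexes <- .hexWindows(targetSeq)
  if (anyNA(match(hexes, names(table))))
    stop("hexamer absent from table: ",
         hexes[which(is.na(match(hexes, names(table))))[1]], call. = FALSE)
  cum <- sum(table[hexes])
  c(ni_cumulative = cum, ni_per_base = cum / nchar(targetSeq))
}

#' Count overlapping hexamer windows matching a motif set
#'
#' @param targetSeq target (sense, DNA) sequence of length >= 6.
#' @param motifSet character vector of hexamer motifs (e.g. predicted exonic
#'   splicing enhancers).
#' @return integer count of overlapping hits.
#' @export
countMotifHexamers <- function(targetSeq, motifSet) {
  if (!length(motifSet)) return(0L)
  sum(.hexWindows(targetSeq) %in% toupper(motifSet))
}

#' GC percentage of a sequence
#'
#' @param seq non-empty DNA string (N counts as non-GC).
#' @return 100 * (#G + #C) / length.
#' @examples
#' gcPercent("ACGT")
#' @export
gcPercent <- function(seq) {
  .assertDNA(seq, "sequence", allowN = TRUE)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  100 * lengths(regmatches(seq, gregexpr("[GC]", seq))) / nchar(seq)
}

#' Exon/intron GC architecture descriptors for a target site
#'
#' DMD-type exons sit in GC-poor introns; the exon-minus-intron GC
#' differential (delta GC, computed against the 150 bases immediately upstream
#' of the splice acceptor) is believed to matter for exon definition. Beyond
#' the plain differential this computes the differential when the target bases
#' are ignored (supposing a blocking effect of the bound oligo) and the change
#' caused by that blocking.
#'
#' @param ctx an [ExonContext-class] (upstream flank ideally >= 150 bases;
#'   shorter flanks are used in full and flagged via the `"partial_intron"`
#'   attribute).
#' @param site a [TargetSite-class] on the exon.
#' @param intronWindow upstream intron window (bases, default 150).
#' @return named numeric: `exon_gc`, `intron_gc`, `delta_gc`,
#'   `delta_gc_ignoring_target`, `delta_gc_change`.
#' @export
gcArchitecture <- function(ctx, site, intronWindow = 150L) {
  stopifnot(is(ctx, "ExonContext"), is(site, "TargetSite"))
  ex <- exonSeq(ctx)
  f5 <- flank5(ctx)
  if (nchar(f5) < 1L)
    stop("gcArchitecture requires an upstream intronic flank", call. = FALSE)
  w <- min(intronWindow, nchar(f5))
  intron <- substr(f5, nchar(f5) - w + 1L, nchar(f5))
  exonGC <- gcPercent(ex)
  intronGC <- gcPercent(intron)
  rest <- paste0(.slice0(ex, 0L, site@dfa),
                 .slice0(ex, site@dfa + site@length, nchar(ex)))
  if (nchar(rest) == 0L)
    stop("target covers the whole exon; target-ignored GC undefined",
         call. = FALSE)
  restGC <- gcPercent(rest)
  out <- c(exon_gc = exonGC, intron_gc = intronGC,
           delta_gc = exonGC - intronGC,
           delta_gc_ignoring_target = restGC - intronGC,
           delta_gc_change = (restGC - intronGC) - (exonGC - intronGC))
  attr(out, "partial_intron") <- w < intronWindow
  out
}

#' Assemble the full descriptor vector for one target site
#'
#' Computes every calculable descriptor (coordinates, oligo GC, the five
#' binding energies, the five accessibility scores, NI scores, GC
#' architecture, Malueka category) and copies externally supplied columns
#' (e.g. co-transcriptional folding L1/L3, splicing-factor matrix scores)
#' verbatim. Per-field provenance (`"computed"`, `"imported"`, `"missing"`) is
#' recorded in the `"provenance"` attribute.
#'
#' @param ctx an [ExonContext-class].
#' @param site a [TargetSite-class].
#' @param backend a [ThermoBackend-class].
#' @param hexamerTable optional named numeric hexamer table (NI scores are
#'   `NA`/missing without it).
#' @param motifSet optional hexamer motif set for `ese_count`.
#' @param imported optional named list of externally supplied descriptor
#'   values.
#' @param computeAccessibility set `FALSE` to skip the accessibility profile
#'   (the expensive step for the internal backend).
#' @param accessibilityContext bases of context on each side of the target for
#'   the accessibility fold (clipped to available sequence).
#' @param window accessibility folding window.
#' @return one-row data.frame of descriptors.
#' @export
assembleDescriptors <- function(ctx, site, backend = SimpleNNBackend(),
                                hexamerTable = NULL, motifSet = NULL,
                                imported = NULL,
                                computeAccessibility = TRUE,
                                accessibilityContext = 45L, window = 150L) {
  stopifnot(is(ctx, "ExonContext"), is(site, "TargetSite"))
  prov <- character()
  fail <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("descriptor '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dgs <- fail("dg_suite", dgSuite(ctx, site, backend))
  out <- data.frame(
    exon_id = exonId(ctx), dfa = site@dfa, dfd = site@dfd, acp = site@acp,
    length = site@length, length_gt22 = site@length >= 23L,
    gc_oligo = gcPercent(site@targetSeq),
    dg_target = dG(dgs$dg_target), dg50 = dG(dgs$dg50),
    dg100 = dG(dgs$dg100), dg200 = dG(dgs$dg200),
    dg_et10 = dG(dgs$dg_et10),
    malueka = maluekaCategory(ctx),
    stringsAsFactors = FALSE)
  prov[names(out)] <- "computed"
  if (computeAccessibility) {
    acc <- fail("accessibility", {
      reg <- .accessibilityRegion(ctx, site, accessibilityContext)
      prof <- unpairedProbabilities(reg$sequence, window = window,
                                    backend = backend, exonId = exonId(ctx))
      accessibilityScores(prof, reg$targetOffset, site@length)
    })
    out[names(acc)] <- as.list(acc)
    prov[names(acc)] <- "computed"
  } else {
    accNames <- c("acc_target", "acc_target_norm", "acc_last15", "acc_last8",
                  "acc_max8")
    out[accNames] <- NA_real_
    prov[accNames] <- "missing"
  }
  if (!is.null(hexamerTable)) {
    ni <- fail("ni_scores", niScores(site@targetSeq, hexamerTable))
    out[names(ni)] <- as.list(ni)
    prov[names(ni)] <- "computed"
  } else {
    out[c("ni_cumulative", "ni_per_base")] <- NA_real_
    prov[c("ni_cumulative", "ni_per_base")] <- "missing"
  }
  out$ese_count <- if (!is.null(motifSet))
    countMotifHexamers(site@targetSeq, motifSet) else NA_integer_
  prov["ese_count"] <- if (is.null(motifSet)) "missing" else "computed"
  gcArch <- fail("gc_architecture", gcArchitecture(ctx, site))
  out[names(gcArch)] <- as.list(gcArch)
  prov[names(gcArch)] <- "computed"
  for (nm in names(imported)) {
    out[[nm]] <- imported[[nm]]
    prov[nm] <- "imported"
  }
  attr(out, "provenance") <- prov
  out
}

.accessibilityRegion <- function(ctx, site, context) {
  full <- paste0(flank5(ctx), exonSeq(ctx), flank3(ctx))
  tStart <- nchar(flank5(ctx)) + site@dfa
  start <- max(0L, tStart - as.integer(context))
  end <- min(nchar(full), tStart + site@length + as.integer(context))
  list(sequence = .slice0(full, start, end),
       targetOffset = as.integer(tStart - start))
}
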