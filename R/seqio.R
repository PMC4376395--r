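# Sequence and coordinate handling: FASTA IO, exon+flank modelling, target
# enumeration, antisense generation.

#' Load exon records from a FASTA of exon + intronic flank sequences
#'
#' Each FASTA record is expected to be the concatenation
#' `upstream intron flank | exon | downstream intron flank` with fixed flank
#' lengths (200 bases in the reference DMD exon 44-55 file). The central slice
#' after removing the declared flanks is taken as the exon.
#'
#' @param fastaPath path to a (multi-record) FASTA file.
#' @param flank5Len,flank3Len declared flank lengths in bases.
#' @param annotations optional Malueka categories: either a named character
#'   vector (`exonId -> category`) or the path of a two-column tab-delimited
#'   file `exon_id<TAB>category`.
#' @return a named list of [ExonContext-class] objects.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeExonFasta(list(ExonContext("e1", "ACGTACGT", "TTTT", "AAAA")), fa)
#' ctxs <- loadExonRecords(fa, 4, 4)
#' exonSeq(ctxs[["e1"]])
#' @export
loadExonRecords <- function(fastaPath, flank5Len = 200L, flank3Len = 200L,
                            annotations = NULL) {
  if (!file.exists(fastaPath))
    stop("FASTA file not found: ", fastaPath, call. = FALSE)
  recs <- tryCatch(Biostrings::readDNAStringSet(fastaPath),
                   error = function(e)
                     stop("malformed FASTA '", fastaPath, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L)
    stop("no records in FASTA: ", fastaPath, call. = FALSE)
  ann <- .readAnnotations(annotations)
  ids <- sub("\\s.*$", "", names(recs))
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    full <- as.character(recs[[i]])
    n <- nchar(full)
    if (n <= flank5Len + flank3Len)
      stop("record '", ids[i], "' (", n, " nt) is not longer than its ",
           "declared flanks (", flank5Len, " + ", flank3Len, ")",
           call. = FALSE)
    cat5 <- if (!is.null(ann) && ids[i] %in% names(ann)) ann[[ids[i]]]
            else "unknown"
    out[[i]] <- ExonContext(
      exonId = ids[i],
      exonSeq = .slice0(full, flank5Len, n - flank3Len),
      flank5 = .slice0(full, 0L, flank5Len),
      flank3 = .slice0(full, n - flank3Len, n),
      maluekaCategory = cat5)
  }
  names(out) <- ids
  out
}

.readAnnotations <- function(annotations) {
  if (is.null(annotations)) return(NULL)
  if (is.character(annotations) && length(annotations) == 1L &&
      file.exists(annotations)) {
    tab <- read.delim(annotations, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("annotation file must have two tab-separated columns",
           call. = FALSE)
    annotations <- stats::setNames(as.character(tab[[2L]]),
                                   as.character(tab[[1L]]))
  }
  bad <- setdiff(unique(annotations), c("A", "B", "C", "unknown"))
  if (length(bad))
    stop("unknown Malueka categories in annotations: ",
         paste(bad, collapse = ", "), call. = FALSE)
  annotations
}

#' Write exon contexts back to FASTA (flank5 + exon + flank3 per record)
#'
#' Inverse of [loadExonRecords()] for matching flank lengths.
#'
#' @param contexts list of [ExonContext-class] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeExonFasta <- function(contexts, path) {
  if (is(contexts, "ExonContext")) contexts <- list(contexts)
  seqs <- Biostrings::DNAStringSet(vapply(contexts, function(ctx)
    paste0(flank5(ctx), exonSeq(ctx), flank3(ctx)), ""))
  names(seqs) <- vapply(contexts, exonId, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Enumerate every exonic target site of a given oligo length
#'
#' Targets are exonic-only by default: `dfa` runs 0, 1, ... so that
#' `dfa + length <= exon_length`, giving `exon_length - length + 1` sites.
#' The first site (`dfa = 0`) starts at the first exon base, adjacent to the
#' splice acceptor.
#'
#' @param ctx an [ExonContext-class].
#' @param oligoLength target/oligo length in bases.
#' @return list of [TargetSite-class] objects.
#' @examples
#' ctx <- ExonContext("e1", strrep("ACGT", 10))
#' length(enumerateTargetSites(ctx, 30))  # 40 - 30 + 1
#' @export
enumerateTargetSites <- function(ctx, oligoLength) {
  stopifnot(is(ctx, "ExonContext"))
  oligoLength <- as.integer(oligoLength)
  exLen <- nchar(exonSeq(ctx))
  if (oligoLength < 1L || oligoLength > exLen)
    stop("oligo length ", oligoLength, " does not fit exon '", exonId(ctx),
         "' of length ", exLen, " (empty enumeration)", call. = FALSE)
  lapply(0:(exLen - oligoLength), function(dfa) {
    new("TargetSite", exonId = exonId(ctx), dfa = as.integer(dfa),
        length = oligoLength,
        targetSeq = .slice0(exonSeq(ctx), dfa, dfa + oligoLength),
        dfd = as.integer(exLen - dfa - oligoLength),
        acp = dfa + (oligoLength - 1) / 2)
  })
}

#' Antisense oligo for a target site
#'
#' The oligo is the reverse complement of the target sequence, written
#' 5' to 3'. Use [rnaSequence()] for the RNA-alphabet rendering consumed by
#' the thermodynamic calculations (all thermodynamics use RNA:RNA parameters
#' regardless of chemistry).
#'
#' @param site a [TargetSite-class].
#' @param chemistry `"PMO"` or `"2OMe"`.
#' @param lengthBounds warn when the oligo length falls outside this range
#'   (typical splice-switching oligos are 15-32 nt); `NULL` disables the
#'   check.
#' @return an [Oligo-class].
#' @examples
#' site <- enumerateTargetSites(ExonContext("e", strrep("GATTACAT", 4)), 20)[[1]]
#' antisenseOligo(site)
#' @export
antisenseOligo <- function(site, chemistry = c("PMO", "2OMe"),
                           lengthBounds = c(15L, 32L)) {
  chemistry <- match.arg(chemistry)
  stopifnot(is(site, "TargetSite"))
  .assertDNA(site@targetSeq, "target sequence")
  if (!is.null(lengthBounds) &&
      (site@length < lengthBounds[1] || site@length > lengthBounds[2]))
    warning("oligo length ", site@length, " is outside the usual ",
            lengthBounds[1], "-", lengthBounds[2], " nt range",
            call. = FALSE)
  new("Oligo", sequence = .revcompDNA(site@targetSeq), chemistry = chemistry,
      length = site@length)
}

#' @describeIn antisenseOligo RNA-alphabet rendering of an oligo or string
#'   (T is replaced by U).
#' @param x an [Oligo-class] or character string.
#' @export
rnaSequence <- function(x) {
  if (is(x, "Oligo")) x <- x@sequence
  .toRNA(x)
}

#' Extract a target region with flanking sequence
#'
#' Builds the genomic window around a target site used for binding-energy
#' calculations. Modes `f50`/`f100`/`f200` take up to N bases on each side of
#' the target, drawing from the intronic flanks where the window crosses the
#' exon boundary; `exon_start_plus10` runs from the first exon base to 10
#' bases downstream of the target 3' end; `none` is the bare target. Windows
#' are silently clipped at the ends of available sequence and the clipping is
#' recorded in the `clipped` slot.
#'
#' @param ctx an [ExonContext-class] containing the site.
#' @param site a [TargetSite-class].
#' @param mode flank mode (see above).
#' @return a [FlankedRegion-class].
#' @export
flankedRegion <- function(ctx, site,
                          mode = c("f50", "f100", "f200",
                                   "exon_start_plus10", "none")) {
  mode <- match.arg(mode)
  stopifnot(is(ctx, "ExonContext"), is(site, "TargetSite"))
  full <- paste0(flank5(ctx), exonSeq(ctx), flank3(ctx))
  nF <- nchar(full)
  f5 <- nchar(flank5(ctx))
  tStart <- f5 + site@dfa            # 0-based in full coords
  tEnd <- tStart + site@length       # half-open
  if (.slice0(full, tStart, tEnd) != site@targetSeq)
    stop("site does not belong to this exon context", call. = FALSE)
  if (mode == "none") {
    want <- c(tStart, tEnd)
  } else if (mode == "exon_start_plus10") {
    want <- c(f5, tEnd + 10L)
  } else {
    n <- c(f50 = 50L, f100 = 100L, f200 = 200L)[[mode]]
    want <- c(tStart - n, tEnd + n)
  }
  got <- c(max(0L, want[1]), min(nF, want[2]))
  new("FlankedRegion", sequence = .slice0(full, got[1], got[2]),
      targetOffset = as.integer(tStart - got[1]),
      targetLength = site@length, flankMode = mode,
      clipped = !identical(as.integer(want), as.integer(got)))
}

#' @describeIn flankedRegion target slice of the region sequence.
#' @param region a [FlankedRegion-class].
#' @export
regionTarget <- function(region) {
  .slice0(region@sequence, region@targetOffset,
          region@targetOffset + region@targetLength)
}
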