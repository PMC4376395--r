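# Target-site accessibility: per-base unpaired probabilities and the five
# aggregate accessibility scores.

#' Per-base unpaired probabilities of a region
#'
#' With the built-in [SimpleNNBackend-class] the probabilities are exact
#' Boltzmann probabilities under the simplified stacking-only model, computed
#' by dynamic programming with base pairs restricted to spans of at most
#' `window` bases (windowed local folding; the computation is quartic in the
#' region length, so keep internal-backend regions to a few hundred bases).
#' With a [ViennaRNABackend-class] the probabilities come from `RNAplfold`
#' (`-W window -u 1`), the production route.
#'
#' @param region nucleotide string (no N bases).
#' @param window folding window length in bases (default 150).
#' @param backend a [ThermoBackend-class].
#' @param exonId label stored on the profile.
#' @return an [AccessibilityProfile-class].
#' @examples
#' unpairedProbabilities(strrep("A", 30), backend = SimpleNNBackend())@probs
#' @export
unpairedProbabilities <- function(region, window = 150L,
                                  backend = SimpleNNBackend(),
                                  exonId = "region") {
  window <- as.integer(window)
  if (window < 10L) stop("window must be >= 10 bases", call. = FALSE)
  if (grepl("N", toupper(region), fixed = TRUE))
    stop("region contains N bases; accessibility undefined", call. = FALSE)
  if (is(backend, "SimpleNNBackend")) {
    codes <- .encodeRNA(region)
    probs <- c_nn_unpaired(codes, backend@minLoop, stackTable(), .kT37,
                           window)
  } else if (is(backend, "ViennaRNABackend")) {
    probs <- .plfoldUnpaired(.toRNA(region), window)
  } else stop("unsupported backend", call. = FALSE)
  new("AccessibilityProfile", exonId = exonId,
      probs = pmin(pmax(probs, 0), 1), window = window)
}

.plfoldUnpaired <- function(rna, window) {
  n <- nchar(rna)
  owd <- getwd()
  dir <- tempfile("plfold")
  dir.create(dir)
  on.exit({ setwd(owd); unlink(dir, recursive = TRUE) }, add = TRUE)
  setwd(dir)
  .vienna("RNAplfold", c("-W", min(window, n), "-u", "1"),
          paste0(">region\n", rna))
  lunp <- list.files(dir, pattern = "_lunp$", full.names = TRUE)
  if (length(lunp) != 1L)
    stop("RNAplfold produced no unpaired-probability output", call. = FALSE)
  tab <- read.delim(lunp, comment.char = "#", header = FALSE)
  tab <- tab[!is.na(tab[[1L]]), , drop = FALSE]  # partially commented header
  probs <- as.numeric(tab[[2L]])
  if (length(probs) != n)
    stop("RNAplfold output length mismatch", call. = FALSE)
  probs
}

#' The five accessibility scores over a target site
#'
#' Sums of per-base unpaired probabilities over: the whole target; the whole
#' target normalized to oligo length; the last 15 bases; the last 8 bases; and
#' the most accessible 8 contiguous bases of the target (maximum over all
#' 8-base windows). "Last N bases" counts inwards from the target's 3' end on
#' the pre-mRNA sense strand by default; `endConvention = "oligo"` flips to
#' the oligo's 3' end (which pairs the target's 5' end), since the siRNA
#' literature the scores derive from concerns the guide strand.
#'
#' @param profile an [AccessibilityProfile-class] covering the region.
#' @param targetOffset 0-based target start within the profiled region (for a
#'   [FlankedRegion-class] this is its `targetOffset`).
#' @param targetLength target length (>= 15).
#' @param endConvention `"target"` (default) or `"oligo"`.
#' @return named numeric vector: `acc_target`, `acc_target_norm`,
#'   `acc_last15`, `acc_last8`, `acc_max8`.
#' @export
accessibilityScores <- function(profile, targetOffset, targetLength,
                                endConvention = c("target", "oligo")) {
  endConvention <- match.arg(endConvention)
  stopifnot(is(profile, "AccessibilityProfile"))
  targetOffset <- as.integer(targetOffset)
  targetLength <- as.integer(targetLength)
  if (targetLength < 15L)
    stop("accessibility scores are defined for targets of >= 15 bases",
         call. = FALSE)
  if (targetOffset < 0L ||
      targetOffset + targetLength > length(profile@probs))
    stop("target does not lie within the profiled region", call. = FALSE)
  pt <- profile@probs[(targetOffset + 1L):(targetOffset + targetLength)]
  if (endConvention == "oligo") pt <- rev(pt)
  win8 <- vapply(seq_len(targetLength - 7L),
                 function(i) sum(pt[i:(i + 7L)]), 0)
  c(acc_target = sum(pt),
    acc_target_norm = sum(pt) / targetLength,
    acc_last15 = sum(tail(pt, 15L)),
    acc_last8 = sum(tail(pt, 8L)),
    acc_max8 = max(win8))
}

#' Write an accessibility profile as two-column delimited text
#'
#' @param profile an [AccessibilityProfile-class].
#' @param path output path (tab-separated `position<TAB>probability`,
#'   positions 0-based).
#' @return `path`, invisibly.
#' @export
writeAccessibilityProfile <- function(profile, path) {
  df <- data.frame(position = seq_along(profile@probs) - 1L,
                   probability = sprintf("%.17g", profile@probs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
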