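# Binding-energy descriptors: duplex nearest-neighbor energies and
# backend-based binding energies of the oligo to flanked target regions.

.pkgCache <- new.env(parent = emptyenv())

#' Bundled RNA stacking parameter table
#'
#' 6x6 matrix of stacking free energies (kcal/mol, 37 C, Turner 2004 set)
#' indexed by pair type (CG, GC, GU, UG, AU, UA); entry `[p1, p2]` is the
#' stack between adjacent pairs `(i, j)` and `(i+1, j-1)` with
#' `p1 = type(seq[i], seq[j])` and `p2 = type(seq[j-1], seq[i+1])`.
#'
#' @param path optional alternative parameter file (same layout).
#' @return named 6x6 numeric matrix.
#' @export
stackTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkgCache$stack)) return(.pkgCache$stack)
    path <- .extdata("stack_rna_turner2004.tsv")
    cacheIt <- TRUE
  } else cacheIt <- FALSE
  tab <- read.delim(path, comment.char = "#", row.names = 1L,
                    check.names = FALSE)
  m <- as.matrix(tab)
  types <- c("CG", "GC", "GU", "UG", "AU", "UA")
  if (!identical(rownames(m), types) || !identical(colnames(m), types))
    stop("stack table must be a 6x6 matrix over pair types ",
         paste(types, collapse = ", "), call. = FALSE)
  if (cacheIt) .pkgCache$stack <- m
  m
}

.duplexMisc <- function() {
  if (is.null(.pkgCache$misc)) {
    tab <- read.delim(.extdata("duplex_misc_turner2004.tsv"),
                      comment.char = "#")
    .pkgCache$misc <- stats::setNames(tab$value, tab$key)
  }
  .pkgCache$misc
}

.pairTypeStr <- function(a, b) {
  key <- paste0(a, b)
  idx <- match(key, c("CG", "GC", "GU", "UG", "AU", "UA"))
  if (is.na(idx)) 0L else idx
}

#' Free energy of a fully complementary oligo:target duplex
#'
#' Nearest-neighbor sum over the fully paired duplex: duplex initiation +
#' stacking terms + terminal AU/GU penalties, from the bundled Turner-style
#' table. The oligo must be the exact reverse complement of the target
#' (Watson-Crick; G.U acceptable only with `allowWobble = TRUE`). This is the
#' `dg_target` descriptor. With `backend = ViennaRNABackend(dangles = 0)` the
#' same fully paired structure is instead evaluated by `RNAeval` as a
#' cross-check route.
#'
#' @param oligo antisense sequence 5'->3' ([Oligo-class] or string; T read as
#'   U).
#' @param target target (sense) sequence 5'->3'.
#' @param allowWobble accept G.U pairs in the complementarity check.
#' @param backend `NULL` for the internal summation, or a
#'   [ViennaRNABackend-class] for the external evaluation route.
#' @return an [EnergyResult-class].
#' @examples
#' dG(duplexEnergy("CCCCCCCCCC", "GGGGGGGGGG"))
#' @export
duplexEnergy <- function(oligo, target, allowWobble = FALSE, backend = NULL) {
  o <- .toRNA(rnaSequence(oligo))
  t <- .toRNA(target)
  if (nchar(o) != nchar(t))
    stop("oligo and target lengths differ (", nchar(o), " vs ", nchar(t), ")",
         call. = FALSE)
  L <- nchar(o)
  if (L < 2L) stop("duplex must be at least 2 bp", call. = FALSE)
  ob <- strsplit(o, "")[[1]]
  tb <- strsplit(t, "")[[1]]
  # antiparallel: oligo base k pairs target base L + 1 - k
  okType <- c(TRUE, TRUE, allowWobble, allowWobble, TRUE, TRUE) # CG GC GU UG AU UA
  types <- vapply(seq_len(L), function(k)
    .pairTypeStr(ob[k], tb[L + 1L - k]), 0L)
  valid <- types > 0L
  valid[valid] <- okType[types[valid]]
  if (!all(valid))
    stop("oligo is not complementary to target at position(s) ",
         paste(which(!valid), collapse = ", "), call. = FALSE)
  if (!is.null(backend)) {
    if (!is(backend, "ViennaRNABackend"))
      stop("cross-check evaluation requires a ViennaRNABackend", call. = FALSE)
    db <- paste0(strrep("(", L), "&", strrep(")", L))
    out <- system2("RNAeval", c("-d0"), stdout = TRUE,
                   input = paste0(o, "&", t, "\n", db))
    dg <- .parseViennaEnergy(out[length(out)])
    return(new("EnergyResult", dg = dg, method = "RNAeval-d0",
               components = list()))
  }
  st <- stackTable()
  misc <- .duplexMisc()
  stacks <- vapply(seq_len(L - 1L), function(k) {
    p1 <- types[k]
    p2 <- .pairTypeStr(tb[L - k], ob[k + 1L])
    st[p1, p2]
  }, 0)
  termAU <- sum(types[c(1L, L)] >= 3L) * misc[["terminal_au"]]
  dg <- misc[["duplex_init"]] + sum(stacks) + termAU
  new("EnergyResult", dg = dg, method = "nn-duplex-turner2004",
      components = list(init = misc[["duplex_init"]], stacks = sum(stacks),
                        terminal_au = termAU))
}

## ---- backend methods -------------------------------------------------------

#' @rdname foldEnergy
setMethod("foldEnergy", "SimpleNNBackend", function(backend, seq) {
  codes <- .encodeRNA(seq)
  c_nn_mfe(codes, 0L, backend@minLoop, stackTable(), backend@maxSpan)
})

#' @rdname cofoldEnergy
setMethod("cofoldEnergy", "SimpleNNBackend", function(backend, seqA, seqB) {
  a <- .encodeRNA(seqA, "strand A")
  b <- .encodeRNA(seqB, "strand B")
  c_nn_mfe(c(a, b), length(a), backend@minLoop, stackTable(),
           backend@maxSpan)
})

.parseViennaEnergy <- function(line) {
  m <- regmatches(line, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", line))
  if (!length(m))
    stop("could not parse ViennaRNA output line: ", line, call. = FALSE)
  as.numeric(gsub("[()\\s]", "", m))
}

.vienna <- function(tool, args, input) {
  out <- tryCatch(system2(tool, args, stdout = TRUE, stderr = FALSE,
                          input = input),
                  error = function(e)
                    stop(tool, " failed: ", conditionMessage(e),
                         call. = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(tool, " exited with status ", status, call. = FALSE)
  out
}

#' @rdname foldEnergy
setMethod("foldEnergy", "ViennaRNABackend", function(backend, seq) {
  out <- .vienna("RNAfold", c("--noPS", paste0("-d", backend@dangles)),
                 .toRNA(seq))
  .parseViennaEnergy(out[length(out)])
})

#' @rdname cofoldEnergy
setMethod("cofoldEnergy", "ViennaRNABackend", function(backend, seqA, seqB) {
  out <- .vienna("RNAcofold", c("--noPS", paste0("-d", backend@dangles)),
                 paste0(.toRNA(seqA), "&", .toRNA(seqB)))
  .parseViennaEnergy(out[length(out)])
})

## ---- binding energy --------------------------------------------------------

#' Binding energy of an oligo to a flanked target region
#'
#' The standard cofold binding free energy:
#' `dG = dG(complex) - dG(region monomer) - dG(oligo monomer)`.
#' Depending on `region@flankMode` this is the `dG50`, `dG100`, `dG200` or
#' `dG_et+10` descriptor. With `targetOnlyReference = TRUE` only the region's
#' fold energy is subtracted (a calibration switch; the symmetric definition
#' is the default).
#'
#' @param oligo [Oligo-class] or antisense string 5'->3'.
#' @param region a [FlankedRegion-class] whose target slice the oligo
#'   complements.
#' @param backend a [ThermoBackend-class].
#' @param targetOnlyReference subtract only the region monomer term.
#' @return an [EnergyResult-class] with a `components` breakdown.
#' @export
bindingEnergy <- function(oligo, region, backend = SimpleNNBackend(),
                          targetOnlyReference = FALSE) {
  stopifnot(is(region, "FlankedRegion"))
  oseq <- if (is(oligo, "Oligo")) oligo@sequence else oligo
  tgt <- regionTarget(region)
  if (grepl("N", region@sequence, fixed = TRUE))
    stop("region contains N bases; thermodynamic parameters undefined",
         call. = FALSE)
  if (!identical(.toRNA(oseq), .toRNA(.revcompDNA(tgt))))
    stop("oligo does not complement the region's target slice", call. = FALSE)
  complex <- cofoldEnergy(backend, oseq, region@sequence)
  monoRegion <- foldEnergy(backend, region@sequence)
  monoOligo <- if (targetOnlyReference) 0 else foldEnergy(backend, oseq)
  method <- if (is(backend, "SimpleNNBackend")) backend@paramId
            else backend@paramId
  new("EnergyResult", dg = complex - monoRegion - monoOligo,
      method = paste0("cofold-binding/", method),
      components = list(complex = complex, monomer_region = monoRegion,
                        monomer_oligo = monoOligo))
}

#' All binding-energy descriptors for one target site
#'
#' Convenience wrapper producing the bare-duplex energy plus the four
#' flanked-region binding energies.
#'
#' @param ctx an [ExonContext-class].
#' @param site a [TargetSite-class] on that exon.
#' @param backend a [ThermoBackend-class].
#' @param targetOnlyReference see [bindingEnergy()].
#' @return named list of [EnergyResult-class]: `dg_target`, `dg50`, `dg100`,
#'   `dg200`, `dg_et10`.
#' @export
dgSuite <- function(ctx, site, backend = SimpleNNBackend(),
                    targetOnlyReference = FALSE) {
  oligo <- antisenseOligo(site, lengthBounds = NULL)
  modes <- c(dg50 = "f50", dg100 = "f100", dg200 = "f200",
             dg_et10 = "exon_start_plus10")
  out <- lapply(modes, function(mode)
    bindingEnergy(oligo, flankedRegion(ctx, site, mode), backend,
                  targetOnlyReference))
  c(list(dg_target = duplexEnergy(oligo, site@targetSeq)), out)
}
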