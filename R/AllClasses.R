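# S4 classes for the exon-skipping screening toolkit.

#' ExonContext: an exon with its intronic flanks
#'
#' Holds one exon sequence together with its upstream (acceptor-side) and
#' downstream (donor-side) intronic flanks and the exon's Malueka splice
#' category (a machine-learning classification of DMD exons by splice-related
#' characteristics; categories A and C carry offsets in the PMO efficacy
#' formula).
#'
#' @slot exonId character label.
#' @slot exonSeq exon sequence (uppercase DNA).
#' @slot flank5 upstream intronic flank (may be empty).
#' @slot flank3 downstream intronic flank (may be empty).
#' @slot maluekaCategory one of `"A"`, `"B"`, `"C"`, `"unknown"`.
#' @export
setClass("ExonContext",
  representation(exonId = "character", exonSeq = "character",
                 flank5 = "character", flank3 = "character",
                 maluekaCategory = "character"),
  prototype(flank5 = "", flank3 = "", maluekaCategory = "unknown"))

setValidity("ExonContext", function(object) {
  msg <- character()
  if (length(object@exonId) != 1L || !nzchar(object@exonId))
    msg <- c(msg, "exonId must be a non-empty string")
  if (nchar(object@exonSeq) < 1L)
    msg <- c(msg, "exonSeq must have length >= 1")
  for (s in c(exonSeq = object@exonSeq, flank5 = object@flank5,
              flank3 = object@flank3))
    if (!grepl("^[ACGTN]*$", s))
      msg <- c(msg, "sequences must contain only A/C/G/T/N")
  if (!object@maluekaCategory %in% c("A", "B", "C", "unknown"))
    msg <- c(msg, "maluekaCategory must be A, B, C or unknown")
  if (length(msg)) msg else TRUE
})

#' Construct an ExonContext
#'
#' @param exonId exon label.
#' @param exonSeq exon sequence (DNA, uppercased).
#' @param flank5,flank3 upstream/downstream intronic flanks.
#' @param maluekaCategory exon splice category (`"A"`, `"B"`, `"C"`,
#'   `"unknown"`).
#' @return An [ExonContext-class] object.
#' @examples
#' ExonContext("ex1", "ACGTACGTACGT", flank5 = "TTTT", flank3 = "AAAA")
#' @export
ExonContext <- function(exonId, exonSeq, flank5 = "", flank3 = "",
                        maluekaCategory = "unknown") {
  new("ExonContext", exonId = as.character(exonId),
      exonSeq = toupper(exonSeq), flank5 = toupper(flank5),
      flank3 = toupper(flank3), maluekaCategory = maluekaCategory)
}

#' TargetSite: a candidate oligo target interval on an exon
#'
#' Coordinates are 0-based: `dfa` (distance from acceptor) is the offset of the
#' target's 5'-most base from the first exon base, so `dfa = 0` is the
#' acceptor-adjacent placement. `dfd` is the distance of the target's 3'-most
#' base from the donor site and `acp` the distance from the acceptor to the
#' target midpoint.
#'
#' @slot exonId character.
#' @slot dfa integer >= 0.
#' @slot length integer oligo/target length.
#' @slot targetSeq target (sense) sequence.
#' @slot dfd integer, `exon_length - dfa - length`.
#' @slot acp numeric, `dfa + (length - 1)/2`.
#' @export
setClass("TargetSite",
  representation(exonId = "character", dfa = "integer", length = "integer",
                 targetSeq = "character", dfd = "integer", acp = "numeric"))

setValidity("TargetSite", function(object) {
  msg <- character()
  if (object@dfa < 0L) msg <- c(msg, "dfa must be >= 0")
  if (nchar(object@targetSeq) != object@length)
    msg <- c(msg, "targetSeq length must equal `length`")
  if (abs(object@acp - object@dfa - (object@length - 1) / 2) > 1e-9)
    msg <- c(msg, "acp must equal dfa + (length - 1)/2")
  if (length(msg)) msg else TRUE
})

#' Oligo: an antisense oligonucleotide
#'
#' @slot sequence antisense sequence written 5' to 3' (DNA alphabet).
#' @slot chemistry `"PMO"` or `"2OMe"`.
#' @slot length integer.
#' @export
setClass("Oligo",
  representation(sequence = "character", chemistry = "character",
                 length = "integer"))

setValidity("Oligo", function(object) {
  msg <- character()
  if (!object@chemistry %in% c("PMO", "2OMe"))
    msg <- c(msg, "chemistry must be PMO or 2OMe")
  if (nchar(object@sequence) != object@length)
    msg <- c(msg, "sequence length must equal `length`")
  if (length(msg)) msg else TRUE
})

#' FlankedRegion: a target with surrounding genomic context
#'
#' @slot sequence region sequence (contiguous in genomic coordinates).
#' @slot targetOffset 0-based index of the target start within `sequence`.
#' @slot targetLength integer.
#' @slot flankMode one of `"f50"`, `"f100"`, `"f200"`, `"exon_start_plus10"`,
#'   `"none"`.
#' @slot clipped TRUE when the requested extent ran past available sequence.
#' @export
setClass("FlankedRegion",
  representation(sequence = "character", targetOffset = "integer",
                 targetLength = "integer", flankMode = "character",
                 clipped = "logical"))

setValidity("FlankedRegion", function(object) {
  if (object@targetOffset + object@targetLength > nchar(object@sequence))
    "target must lie within the region sequence" else TRUE
})

#' EnergyResult: a free-energy value with provenance
#'
#' @slot dg free energy in kcal/mol (more negative = stronger binding).
#' @slot method backend/parameter-set identifier.
#' @slot components optional breakdown (complex and monomer energies).
#' @export
setClass("EnergyResult",
  representation(dg = "numeric", method = "character", components = "list"),
  prototype(components = list()))

setValidity("EnergyResult", function(object) {
  if (!is.finite(object@dg)) "dg must be finite" else TRUE
})

#' Thermodynamic backends
#'
#' `ThermoBackend` is the virtual interface: a backend provides
#' [foldEnergy()] (single-strand minimum free energy) and [cofoldEnergy()]
#' (bimolecular complex minimum free energy), plus windowed per-base unpaired
#' probabilities through [unpairedProbabilities()].
#'
#' `SimpleNNBackend` is the built-in simplified engine: stacking-only
#' nearest-neighbor energies (Turner 2004 stack table), minimum hairpin loop
#' of 3, wobble pairs allowed, exact dynamic programming. It is deterministic,
#' fully reproducible, and shares its energy model with the exhaustive
#' enumeration oracle used in the test-suite.
#'
#' `ViennaRNABackend` shells out to the ViennaRNA command-line programs
#' (`RNAfold`, `RNAcofold`, `RNAplfold`) with full Turner parameters; use it
#' for production screening. Absolute energies differ between backends, so a
#' model fitted on one backend's scale should be applied to energies from the
#' same backend.
#'
#' @slot minLoop minimum hairpin loop size (bases).
#' @slot maxSpan maximum pairing span; 0 = unrestricted.
#' @slot paramId parameter-set identifier recorded in results.
#' @aliases SimpleNNBackend-class ViennaRNABackend-class
#' @export
setClass("ThermoBackend", representation("VIRTUAL"))

#' @rdname ThermoBackend-class
#' @export
setClass("SimpleNNBackend", contains = "ThermoBackend",
  representation(minLoop = "integer", maxSpan = "integer",
                 paramId = "character"),
  prototype(minLoop = 3L, maxSpan = 0L, paramId = "turner2004-stack-subset"))

#' @rdname ThermoBackend-class
#' @export
setClass("ViennaRNABackend", contains = "ThermoBackend",
  representation(dangles = "integer", paramId = "character"),
  prototype(dangles = 2L, paramId = "viennarna-default"))

#' @param minLoop minimum hairpin loop size.
#' @param maxSpan maximum pairing span (0 = unrestricted).
#' @rdname ThermoBackend-class
#' @export
SimpleNNBackend <- function(minLoop = 3L, maxSpan = 0L) {
  new("SimpleNNBackend", minLoop = as.integer(minLoop),
      maxSpan = as.integer(maxSpan))
}

#' @param dangles ViennaRNA dangling-end model (0 or 2).
#' @rdname ThermoBackend-class
#' @export
ViennaRNABackend <- function(dangles = 2L) {
  for (tool in c("RNAfold", "RNAcofold", "RNAplfold"))
    if (!nzchar(Sys.which(tool)))
      stop("ViennaRNA tool not found on PATH: ", tool, call. = FALSE)
  new("ViennaRNABackend", dangles = as.integer(dangles),
      paramId = paste0("viennarna-d", dangles))
}

#' AccessibilityProfile: per-base unpaired probabilities
#'
#' @slot exonId label of the profiled region.
#' @slot probs numeric vector in \[0, 1\], one per base.
#' @slot window folding window length (bases).
#' @export
setClass("AccessibilityProfile",
  representation(exonId = "character", probs = "numeric", window = "integer"))

setValidity("AccessibilityProfile", function(object) {
  if (any(object@probs < -1e-9 | object@probs > 1 + 1e-9))
    "probabilities must lie in [0, 1]" else TRUE
})

#' SkipModelCoefficients: a parameterized efficacy model
#'
#' A coefficient bag for either the least-squares PMO formula
#' (`link = "identity"`) or the logistic 2'-O-methyl classifier
#' (`link = "logit"`). Interactions are centered: the cross term is
#' `coef_cross * (DfA - center_dfa) * (dG50 - center_dg50)`.
#'
#' @slot chemistry `"PMO"` or `"2OMe"`.
#' @slot link `"identity"` (predicted skip \%) or `"logit"` (good
#'   probability).
#' @slot coefficients named numeric vector.
#' @slot centers named numeric vector of interaction centering constants.
#' @slot distanceTerm `"dfa"` or `"acp"` (which distance feeds the model).
#' @slot id provenance identifier echoed into output headers.
#' @export
setClass("SkipModelCoefficients",
  representation(chemistry = "character", link = "character",
                 coefficients = "numeric", centers = "numeric",
                 distanceTerm = "character", id = "character"),
  prototype(distanceTerm = "dfa", id = "unversioned"))

#' FittedSkipModel: a least-squares efficacy fit
#'
#' @slot fit the underlying `lm` object.
#' @slot terms character vector of main-effect terms.
#' @slot interactions list of character pairs (centered interactions).
#' @slot centers named numeric, centering constants actually used.
#' @slot r2,rmse,n,p fit statistics (`rmse` uses denominator n - p, p =
#'   number of estimated coefficients including the intercept).
#' @export
setClass("FittedSkipModel",
  representation(fit = "ANY", terms = "character", interactions = "list",
                 centers = "numeric", r2 = "numeric", rmse = "numeric",
                 n = "integer", p = "integer"))

#' ConfusionMatrix: binary classification counts
#'
#' Rows are observed, columns predicted; `tn`/`fp` are observed-bad rows,
#' `fn`/`tp` observed-good.
#'
#' @slot tn,fp,fn,tp non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(tn = "integer", fp = "integer", fn = "integer",
                 tp = "integer"))

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tn, object@fp, object@fn, object@tp) < 0L))
    "counts must be non-negative" else TRUE
})

#' SkipClassifier: a good/bad efficacy classifier
#'
#' @slot coefficients named numeric (linear predictor on descriptor columns).
#' @slot terms model terms.
#' @slot interactions list of centered interactions.
#' @slot centers centering constants.
#' @slot confusion in-sample [ConfusionMatrix-class] at probability 0.5.
#' @slot separable TRUE when complete separation was detected (a ridge
#'   penalized fit is then used).
#' @slot method `"glm"` or `"ridge-irls"`.
#' @export
setClass("SkipClassifier",
  representation(coefficients = "numeric", terms = "character",
                 interactions = "list", centers = "numeric",
                 confusion = "ConfusionMatrix", separable = "logical",
                 method = "character"))

#' StepwisePath: forward-selection trace with K-fold validation
#'
#' @slot steps data.frame with one row per accepted term: `term`, `bic`,
#'   `r2`, `kfold_r2`.
#' @slot K number of folds.
#' @slot seed fold-assignment seed.
#' @export
setClass("StepwisePath",
  representation(steps = "data.frame", K = "integer", seed = "integer"))

setValidity("StepwisePath", function(object) {
  r2 <- object@steps$r2
  if (length(r2) > 1 && any(diff(r2) < -1e-9))
    "in-sample r2 must be non-decreasing along the path" else TRUE
})

#' ScreenProfile: per-position predictions across an exon
#'
#' @slot exonId exon label.
#' @slot oligoLength oligo length screened.
#' @slot chemistry `"PMO"` or `"2OMe"`.
#' @slot rows data.frame, one row per acceptor distance (`dfa`): target and
#'   oligo sequences, `dg50`, `prediction`, `clipped`.
#' @slot movingAvg centered moving average of the prediction series (NA where
#'   the full window does not fit).
#' @slot window moving-average window (bases).
#' @slot modelId provenance identifier of the coefficient set.
#' @slot backendId thermodynamic backend identifier.
#' @export
setClass("ScreenProfile",
  representation(exonId = "character", oligoLength = "integer",
                 chemistry = "character", rows = "data.frame",
                 movingAvg = "numeric", window = "integer",
                 modelId = "character", backendId = "character"))

setValidity("ScreenProfile", function(object) {
  if (nrow(object@rows) != length(object@movingAvg))
    "movingAvg must align with rows" else TRUE
})
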