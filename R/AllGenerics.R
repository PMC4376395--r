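# Generics and accessors.

#' @describeIn ExonContext-class exon label accessor.
#' @param object an object.
#' @export
setGeneric("exonId", function(object) standardGeneric("exonId"))

#' @describeIn ExonContext-class exon sequence accessor.
#' @export
setGeneric("exonSeq", function(object) standardGeneric("exonSeq"))

#' @describeIn ExonContext-class upstream intronic flank accessor.
#' @export
setGeneric("flank5", function(object) standardGeneric("flank5"))

#' @describeIn ExonContext-class downstream intronic flank accessor.
#' @export
setGeneric("flank3", function(object) standardGeneric("flank3"))

#' @describeIn ExonContext-class Malueka splice category accessor.
#' @export
setGeneric("maluekaCategory",
           function(object) standardGeneric("maluekaCategory"))

#' Single-strand minimum free energy under a backend's model
#'
#' @param backend a [ThermoBackend-class].
#' @param seq nucleotide string (DNA or RNA alphabet; T is read as U).
#' @return free energy in kcal/mol; sequences that cannot pair return 0.
#' @export
setGeneric("foldEnergy", function(backend, seq) standardGeneric("foldEnergy"))

#' Bimolecular complex minimum free energy under a backend's model
#'
#' Symmetric in its two strands.
#'
#' @param backend a [ThermoBackend-class].
#' @param seqA,seqB the two strands (DNA or RNA alphabet).
#' @return complex minimum free energy in kcal/mol.
#' @export
setGeneric("cofoldEnergy",
           function(backend, seqA, seqB) standardGeneric("cofoldEnergy"))

#' @describeIn EnergyResult-class free-energy accessor (kcal/mol).
#' @param object an object.
#' @export
setGeneric("dG", function(object) standardGeneric("dG"))

#' Percentage of classifications that are correct
#'
#' @param object a [ConfusionMatrix-class] (or anything coercible).
#' @return `100 * (tn + tp) / (tn + fp + fn + tp)`.
#' @export
setGeneric("proportionCorrect",
           function(object) standardGeneric("proportionCorrect"))

setMethod("exonId", "ExonContext", function(object) object@exonId)
setMethod("exonSeq", "ExonContext", function(object) object@exonSeq)
setMethod("flank5", "ExonContext", function(object) object@flank5)
setMethod("flank3", "ExonContext", function(object) object@flank3)
setMethod("maluekaCategory", "ExonContext",
          function(object) object@maluekaCategory)
setMethod("exonId", "TargetSite", function(object) object@exonId)
setMethod("dG", "EnergyResult", function(object) object@dg)

setMethod("show", "ExonContext", function(object) {
  cat(sprintf(
    "ExonContext '%s': exon %d nt (GC %.1f%%), flanks %d/%d nt, Malueka %s\n",
    object@exonId, nchar(object@exonSeq), gcPercent(object@exonSeq),
    nchar(object@flank5), nchar(object@flank3), object@maluekaCategory))
})

setMethod("show", "TargetSite", function(object) {
  cat(sprintf("TargetSite %s dfa=%d len=%d dfd=%d acp=%.1f %s\n",
              object@exonId, object@dfa, object@length, object@dfd,
              object@acp, object@targetSeq))
})

setMethod("show", "EnergyResult", function(object) {
  cat(sprintf("EnergyResult: dG = %.3f kcal/mol [%s]\n",
              object@dg, object@method))
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tn, object@fp, object@fn, object@tp), 2, 2,
              byrow = TRUE,
              dimnames = list(observed = c("bad", "good"),
                              predicted = c("bad", "good")))
  print(m)
  cat(sprintf("proportion correct: %.1f%%\n", proportionCorrect(object)))
})

setMethod("show", "ScreenProfile", function(object) {
  cat(sprintf("ScreenProfile '%s': %d positions, %d-mer %s, window %d [%s]\n",
              object@exonId, nrow(object@rows), object@oligoLength,
              object@chemistry, object@window, object@backendId))
})

setMethod("show", "FittedSkipModel", function(object) {
  cat(sprintf("FittedSkipModel: n=%d p=%d R2=%.3f RMSE=%.2f\n",
              object@n, object@p, object@r2, object@rmse))
  print(round(coef(object@fit), 4))
})

setMethod("show", "SkipModelCoefficients", function(object) {
  cat(sprintf("SkipModelCoefficients [%s, %s link, distance=%s, id=%s]\n",
              object@chemistry, object@link, object@distanceTerm, object@id))
  print(object@coefficients)
  if (length(object@centers)) {
    cat("centers:\n"); print(object@centers)
  }
})
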