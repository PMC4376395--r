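# Predictive scoring: the published PMO least-squares formula, the
# config-driven 2'-O-methyl logistic model, and good/bad classification.

#' The published PMO efficacy formula coefficients
#'
#' Defaults are the printed least-squares model:
#' `predicted skip = -44.177 - 0.253*DfA - 2.435*dG50 + (A: -11.4 | C: +11.4)
#' + 0.02*(DfA - 80.197)*(dG50 + 37.467)`.
#' The cross term is the centered interaction: 80.197 and -37.467 are the
#' dataset means of DfA and dG50 at which the interaction vanishes. Categories
#' other than A and C contribute no offset.
#'
#' @param intercept,coef_dfa,coef_dg50,malueka_offset_A,malueka_offset_C,coef_cross
#'   model coefficients.
#' @param center_dfa,center_dg50 interaction centering constants.
#' @param id provenance identifier.
#' @return a [SkipModelCoefficients-class] with `link = "identity"`.
#' @examples
#' pmoPredictedSkip(0, -50, "A")  # 86.275
#' @export
pmoCoefficients <- function(intercept = -44.177, coef_dfa = -0.253,
                            coef_dg50 = -2.435, malueka_offset_A = -11.4,
                            malueka_offset_C = 11.4, coef_cross = 0.02,
                            center_dfa = 80.197, center_dg50 = -37.467,
                            id = "pmo-published") {
  new("SkipModelCoefficients", chemistry = "PMO", link = "identity",
      coefficients = c(intercept = intercept, coef_dfa = coef_dfa,
                       coef_dg50 = coef_dg50,
                       malueka_offset_A = malueka_offset_A,
                       malueka_offset_C = malueka_offset_C,
                       coef_cross = coef_cross),
      centers = c(center_dfa = center_dfa, center_dg50 = center_dg50),
      distanceTerm = "dfa", id = id)
}

#' Predicted exon-skipping percentage for a PMO oligo
#'
#' Evaluates the PMO least-squares formula. The raw value is returned
#' unclamped (the linear model is unbounded); use [clampSkip()] for display.
#' `strictLiteral = TRUE` evaluates the cross term as the literal product
#' `DfA * (-center_dfa) * (dG50 - center_dg50) * coef_cross` instead of the
#' centered interaction — an audit mode only; the literal reading dwarfs every
#' other term and is not a sensible model.
#'
#' @param dfa distance of the target's 5' end from the splice acceptor
#'   (bases, 0-based). Vectorized.
#' @param dg50 binding energy of the oligo to the target with 50-base flanks
#'   (kcal/mol). Vectorized.
#' @param malueka exon category (`"A"`, `"B"`, `"C"`, `"unknown"`).
#' @param coeffs a [SkipModelCoefficients-class] with `link = "identity"`.
#' @param strictLiteral audit mode (see above).
#' @return predicted skipping percentage(s).
#' @export
pmoPredictedSkip <- function(dfa, dg50, malueka = "unknown",
                             coeffs = pmoCoefficients(),
                             strictLiteral = FALSE) {
  stopifnot(is(coeffs, "SkipModelCoefficients"),
            coeffs@link == "identity")
  k <- coeffs@coefficients
  cn <- coeffs@centers
  n <- max(length(dfa), length(dg50), length(malueka))
  dfa <- rep_len(dfa, n); dg50 <- rep_len(dg50, n)
  malueka <- rep_len(malueka, n)
  offset <- ifelse(malueka == "A", k[["malueka_offset_A"]],
                   ifelse(malueka == "C", k[["malueka_offset_C"]], 0))
  cross <- if (strictLiteral)
    dfa * (-cn[["center_dfa"]]) * (dg50 - cn[["center_dg50"]]) *
      k[["coef_cross"]]
  else
    k[["coef_cross"]] * (dfa - cn[["center_dfa"]]) *
      (dg50 - cn[["center_dg50"]])
  k[["intercept"]] + k[["coef_dfa"]] * dfa + k[["coef_dg50"]] * dg50 +
    offset + cross
}

#' @describeIn pmoPredictedSkip clip predictions to the displayable 0-100
#'   range.
#' @param x predicted value(s).
#' @export
clampSkip <- function(x) pmin(pmax(x, 0), 100)

#' 2'-O-methyl model coefficients
#'
#' The 2'-O-methyl classifier is a logistic model on `dG50`, distance from the
#' acceptor (DfA by default; ACP selectable), their centered cross-term and
#' the oligo-length category (> 22 nt). Its published coefficients are not
#' transcribed in the main text, so they must be supplied: either from a
#' config file written by [writeModelConfig()] (e.g. a refit exported with
#' [exportCoefficients()]) or passed explicitly. There are no silent defaults.
#'
#' @param coefficients named numeric: `intercept`, `coef_dg50`, `coef_dist`,
#'   `coef_cross`, `coef_length_gt22`.
#' @param centers named numeric: `center_dist`, `center_dg50`.
#' @param distanceTerm `"dfa"` or `"acp"`.
#' @param id provenance identifier.
#' @return a [SkipModelCoefficients-class] with `link = "logit"`.
#' @export
omeCoefficients <- function(coefficients, centers = c(center_dist = 0,
                                                      center_dg50 = 0),
                            distanceTerm = c("dfa", "acp"),
                            id = "ome-config") {
  distanceTerm <- match.arg(distanceTerm)
  need <- c("intercept", "coef_dg50", "coef_dist", "coef_cross",
            "coef_length_gt22")
  if (!all(need %in% names(coefficients)))
    stop("2'OMe model is unfitted: missing coefficient(s) ",
         paste(setdiff(need, names(coefficients)), collapse = ", "),
         "; supply a config or refit with fitBinaryLogistic()",
         call. = FALSE)
  new("SkipModelCoefficients", chemistry = "2OMe", link = "logit",
      coefficients = coefficients[need], centers = centers,
      distanceTerm = distanceTerm, id = id)
}

#' Probability that a 2'-O-methyl oligo achieves 'good' skipping
#'
#' Logistic inverse link applied to the model's linear predictor.
#'
#' @param descriptors a one-row data.frame (or named list) with `dg50`,
#'   `dfa`/`acp` and `length_gt22` fields (as from [assembleDescriptors()]).
#'   Multi-row data.frames are handled row-wise.
#' @param coeffs a [SkipModelCoefficients-class] with `link = "logit"`
#'   (mandatory; see [omeCoefficients()]).
#' @return probability (or vector of probabilities) in \[0, 1\].
#' @export
omeGoodProbability <- function(descriptors, coeffs) {
  if (missing(coeffs) || is.null(coeffs))
    stop("2'OMe model is unfitted: coefficients must be supplied ",
         "(no silent defaults)", call. = FALSE)
  stopifnot(is(coeffs, "SkipModelCoefficients"), coeffs@link == "logit")
  k <- coeffs@coefficients
  cn <- coeffs@centers
  dist <- descriptors[[coeffs@distanceTerm]]
  if (is.null(dist) || is.null(descriptors[["dg50"]]) ||
      is.null(descriptors[["length_gt22"]]))
    stop("descriptors must provide dg50, ", coeffs@distanceTerm,
         " and length_gt22", call. = FALSE)
  dg50 <- descriptors[["dg50"]]
  lp <- k[["intercept"]] + k[["coef_dg50"]] * dg50 +
    k[["coef_dist"]] * dist +
    k[["coef_cross"]] * (dist - cn[["center_dist"]]) *
      (dg50 - cn[["center_dg50"]]) +
    k[["coef_length_gt22"]] * as.numeric(descriptors[["length_gt22"]])
  plogis(lp)
}

#' Per-study 'good' skipping thresholds
#'
#' The efficacy level above which each study's authors considered an oligo
#' effective.
#'
#' @return named numeric vector of percentages.
#' @export
studyThresholds <- function() {
  c(AartsmaRus = 25, DwiPramono = 27.5, Harding = 30, Popplewell = 30,
    Wilton = 30)
}

#' Classify an efficacy value as good or bad
#'
#' Strictly greater than the threshold is 'good'; a value exactly at the
#' threshold is 'bad' (the boundary convention follows the studies' "> x%"
#' stratifications).
#'
#' @param value skipping percentage(s) or probability(ies).
#' @param threshold cutoff on the same scale (a percentage from
#'   [studyThresholds()], or e.g. 0.5 for probabilities).
#' @return character vector of `"good"`/`"bad"`.
#' @examples
#' classifyGood(c(30, 30.01), 30)
#' @export
classifyGood <- function(value, threshold = 30) {
  ifelse(value > threshold, "good", "bad")
}

#' Read and write model-coefficient configs
#'
#' Flat `key = value` text files carrying a [SkipModelCoefficients-class];
#' coefficient keys are prefixed `coef.`, centers `center.`. The `id` is
#' echoed into all screen output headers for provenance.
#'
#' @param path config file path.
#' @return [SkipModelCoefficients-class] for `readModelConfig`; `path`
#'   invisibly for `writeModelConfig`.
#' @export
readModelConfig <- function(path) {
  kv <- .readKeyValue(path)
  getnum <- function(prefix) {
    sel <- startsWith(names(kv), prefix)
    stats::setNames(vapply(kv[sel], as.numeric, 0),
                    substring(names(kv)[sel], nchar(prefix) + 1L))
  }
  coefs <- getnum("coef.")
  centers <- getnum("center.")
  # center keys are stored with their full names (center_dfa etc.)
  names(centers) <- paste0("center_", names(centers))
  link <- kv[["link"]] %||% "identity"
  if (link == "identity") {
    pmoCoefficients(
      intercept = coefs[["intercept"]], coef_dfa = coefs[["dfa"]],
      coef_dg50 = coefs[["dg50"]],
      malueka_offset_A = coefs[["malueka_offset_A"]],
      malueka_offset_C = coefs[["malueka_offset_C"]],
      coef_cross = coefs[["cross"]],
      center_dfa = centers[["center_dfa"]],
      center_dg50 = centers[["center_dg50"]],
      id = kv[["id"]] %||% "config")
  } else {
    omeCoefficients(
      coefficients = c(intercept = coefs[["intercept"]],
                       coef_dg50 = coefs[["dg50"]],
                       coef_dist = coefs[["dist"]],
                       coef_cross = coefs[["cross"]],
                       coef_length_gt22 = coefs[["length_gt22"]]),
      centers = c(center_dist = centers[["center_dist"]],
                  center_dg50 = centers[["center_dg50"]]),
      distanceTerm = kv[["distance_term"]] %||% "dfa",
      id = kv[["id"]] %||% "config")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param coeffs a [SkipModelCoefficients-class].
#' @rdname readModelConfig
#' @export
writeModelConfig <- function(coeffs, path) {
  stopifnot(is(coeffs, "SkipModelCoefficients"))
  k <- coeffs@coefficients
  if (coeffs@link == "identity") {
    kv <- list(link = "identity", chemistry = coeffs@chemistry,
               id = coeffs@id,
               "coef.intercept" = k[["intercept"]],
               "coef.dfa" = k[["coef_dfa"]],
               "coef.dg50" = k[["coef_dg50"]],
               "coef.malueka_offset_A" = k[["malueka_offset_A"]],
               "coef.malueka_offset_C" = k[["malueka_offset_C"]],
               "coef.cross" = k[["coef_cross"]],
               "center.dfa" = coeffs@centers[["center_dfa"]],
               "center.dg50" = coeffs@centers[["center_dg50"]])
  } else {
    kv <- list(link = "logit", chemistry = coeffs@chemistry,
               id = coeffs@id, distance_term = coeffs@distanceTerm,
               "coef.intercept" = k[["intercept"]],
               "coef.dg50" = k[["coef_dg50"]],
               "coef.dist" = k[["coef_dist"]],
               "coef.cross" = k[["coef_cross"]],
               "coef.length_gt22" = k[["coef_length_gt22"]],
               "center.dist" = coeffs@centers[["center_dist"]],
               "center.dg50" = coeffs@centers[["center_dg50"]])
  }
  .writeKeyValue(kv, path, header = "skipAO model coefficients")
}
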