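# End-to-end per-position exon screening: descriptor computation at every
# target position, formula application, moving averages, ranking, and the
# two-file reference output.

#' Screen every target position of an exon
#'
#' For each of the `exon_length - oligo_length + 1` exonic placements:
#' extracts the 50-base-flanked region, computes the dG50 binding energy, and
#' applies the efficacy model — the PMO least-squares formula (prediction =
#' predicted skip %) or the 2'-O-methyl logistic model (prediction = good
#' probability). The per-row dG50 values are cached per (sequence window,
#' backend, parameter set), so re-screens are incremental.
#'
#' @param ctx an [ExonContext-class].
#' @param oligoLength oligo length (default 30).
#' @param chemistry `"PMO"` or `"2OMe"`.
#' @param coeffs a [SkipModelCoefficients-class] matching the chemistry.
#' @param backend a [ThermoBackend-class].
#' @param window moving-average window; defaults to `ceiling(oligoLength/2)`
#'   (15 for 30-mers, 13 for 25-mers, 10 for 20-mers), placing the smoothed
#'   value at the midpoint of each target site.
#' @return a [ScreenProfile-class].
#' @export
screenExon <- function(ctx, oligoLength = 30L, chemistry = c("PMO", "2OMe"),
                       coeffs = pmoCoefficients(),
                       backend = SimpleNNBackend(), window = NULL) {
  chemistry <- match.arg(chemistry)
  stopifnot(is(ctx, "ExonContext"), is(coeffs, "SkipModelCoefficients"))
  if (chemistry == "PMO" && coeffs@link != "identity")
    stop("PMO screening needs identity-link (least squares) coefficients",
         call. = FALSE)
  if (chemistry == "2OMe" && coeffs@link != "logit")
    stop("2'OMe screening needs logit-link coefficients; see ",
         "omeCoefficients()", call. = FALSE)
  oligoLength <- as.integer(oligoLength)
  sites <- enumerateTargetSites(ctx, oligoLength)
  rows <- do.call(rbind, lapply(sites, function(site) {
    region <- flankedRegion(ctx, site, "f50")
    oligo <- antisenseOligo(site, lengthBounds = NULL)
    dg50 <- tryCatch(
      .cachedBindingEnergy(oligo, region, backend),
      error = function(e)
        stop("screen failed at dfa=", site@dfa, ": ", conditionMessage(e),
             call. = FALSE))
    pred <- if (chemistry == "PMO")
      pmoPredictedSkip(site@dfa, dg50, maluekaCategory(ctx), coeffs)
    else
      omeGoodProbability(
        list(dg50 = dg50, dfa = site@dfa, acp = site@acp,
             length_gt22 = oligoLength >= 23L), coeffs)
    data.frame(dfa = site@dfa, target_seq = site@targetSeq,
               oligo_seq = oligo@sequence, dg50 = dg50, prediction = pred,
               clipped = region@clipped, stringsAsFactors = FALSE)
  }))
  if (is.null(window)) window <- ceiling(oligoLength / 2)
  ma <- if (window <= nrow(rows)) movingAverage(rows$prediction, window)
        else rep(NA_real_, nrow(rows))  # window never fits a short profile
  new("ScreenProfile", exonId = exonId(ctx), oligoLength = oligoLength,
      chemistry = chemistry, rows = rows,
      movingAvg = ma,
      window = as.integer(window),
      modelId = coeffs@id,
      backendId = if (is(backend, "SimpleNNBackend")) backend@paramId
                  else backend@paramId)
}

.cachedBindingEnergy <- function(oligo, region, backend) {
  key <- paste(region@sequence, region@targetOffset, region@targetLength,
               class(backend), backend@paramId, sep = "|")
  if (is.null(.pkgCache$dg)) .pkgCache$dg <- new.env(parent = emptyenv())
  hit <- .pkgCache$dg[[key]]
  if (!is.null(hit)) return(hit)
  val <- dG(bindingEnergy(oligo, region, backend))
  .pkgCache$dg[[key]] <- val
  val
}

#' Centered moving average
#'
#' Arithmetic mean over a centered window; positions where the full window
#' does not fit are `NA`. For even windows the extra base falls on the
#' acceptor (left) side.
#'
#' @param series numeric vector.
#' @param window window size (>= 1, <= length of series).
#' @return numeric vector of the same length.
#' @examples
#' movingAverage(c(0, 10, 20), 3)
#' @export
movingAverage <- function(series, window) {
  window <- as.integer(window)
  if (window < 1L || window > length(series))
    stop("window must be between 1 and the series length", call. = FALSE)
  as.numeric(zoo::rollmean(zoo::zoo(series), window, fill = NA,
                           align = "center"))
}

#' Rank screened candidates by predicted efficacy
#'
#' Rows sorted by prediction descending; ties broken by smaller `dfa`, then
#' lexicographically by oligo sequence (stable).
#'
#' @param profile a [ScreenProfile-class].
#' @param topN number of rows to return (the full profile if larger).
#' @return data.frame of ranked rows with a `rank` column.
#' @export
rankCandidates <- function(profile, topN = Inf) {
  stopifnot(is(profile, "ScreenProfile"))
  rows <- profile@rows
  if (!nrow(rows)) stop("empty profile", call. = FALSE)
  ord <- order(-rows$prediction, rows$dfa, rows$oligo_seq)
  out <- rows[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  head(out, n = min(topN, nrow(out)))
}

#' Write the screen output files
#'
#' Emits the reference two-file output plus a consolidated report:
#' `<prefix>_sequences.tsv` (per-position oligo and flanked target sequences,
#' numbered by distance from the acceptor starting at 0),
#' `<prefix>_energies.tsv` (per-position dG values) and
#' `<prefix>_report.tsv` (predictions, moving average, rank). Headers carry
#' the package version, model id and backend id. An optional `normalizeTo`
#' adds a display column with predictions rescaled to a given mean observed
#' skip (a plotting device for cross-study comparison; stored predictions are
#' never altered).
#'
#' @param profile a [ScreenProfile-class].
#' @param outPrefix output path prefix.
#' @param ctx optional [ExonContext-class] to include flanked target
#'   sequences in the sequences file.
#' @param normalizeTo optional mean observed skip for the display column.
#' @return character vector of the three file paths, invisibly.
#' @export
writeScreenOutputs <- function(profile, outPrefix, ctx = NULL,
                               normalizeTo = NULL) {
  stopifnot(is(profile, "ScreenProfile"))
  rows <- profile@rows
  hdr <- sprintf(
    "# skipAO %s | exon=%s | length=%d | chemistry=%s | model=%s | backend=%s | ma_window=%d",
    as.character(utils::packageVersion("skipAO")), profile@exonId,
    profile@oligoLength, profile@chemistry, profile@modelId,
    profile@backendId, profile@window)
  paths <- paste0(outPrefix, c("_sequences.tsv", "_energies.tsv",
                               "_report.tsv"))
  writeTsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fmt <- function(x) sprintf("%.17g", x)
  flanked <- if (!is.null(ctx)) {
    vapply(rows$dfa, function(d) {
      site <- new("TargetSite", exonId = profile@exonId, dfa = as.integer(d),
                  length = profile@oligoLength,
                  targetSeq = .slice0(exonSeq(ctx), d,
                                      d + profile@oligoLength),
                  dfd = as.integer(nchar(exonSeq(ctx)) - d -
                                     profile@oligoLength),
                  acp = d + (profile@oligoLength - 1) / 2)
      flankedRegion(ctx, site, "f50")@sequence
    }, "")
  } else rows$target_seq
  writeTsv(data.frame(dfa = rows$dfa, oligo_seq = rows$oligo_seq,
                      target_flanked = flanked), paths[1])
  writeTsv(data.frame(dfa = rows$dfa, dg50 = fmt(rows$dg50)), paths[2])
  report <- data.frame(dfa = rows$dfa, target_seq = rows$target_seq,
                       oligo_seq = rows$oligo_seq, dg50 = fmt(rows$dg50),
                       prediction = fmt(rows$prediction),
                       moving_avg = ifelse(is.na(profile@movingAvg), "NA",
                                           fmt(profile@movingAvg)),
                       clipped = rows$clipped)
  if (!is.null(normalizeTo))
    report$prediction_normalized <-
      fmt(rows$prediction * normalizeTo / mean(rows$prediction))
  rk <- rankCandidates(profile)
  report$rank <- rk$rank[match(rows$dfa, rk$dfa)]
  writeTsv(report, paths[3])
  invisible(paths)
}

#' Reload a screen report into a ScreenProfile
#'
#' Inverse of the report file written by [writeScreenOutputs()]; the
#' round trip is lossless (numerics are serialized at full precision).
#'
#' @param path path of a `<prefix>_report.tsv` file.
#' @return a [ScreenProfile-class].
#' @export
readScreenReport <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^|]+", hdr))[[1]]
  kv <- strsplit(trimws(meta), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) trimws(x[2]), ""),
                          vapply(kv, `[`, "", 1))
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  new("ScreenProfile", exonId = vals[["exon"]],
      oligoLength = as.integer(vals[["length"]]),
      chemistry = vals[["chemistry"]],
      rows = data.frame(dfa = df$dfa, target_seq = df$target_seq,
                        oligo_seq = df$oligo_seq,
                        dg50 = as.numeric(df$dg50),
                        prediction = as.numeric(df$prediction),
                        clipped = df$clipped, stringsAsFactors = FALSE),
      movingAvg = suppressWarnings(as.numeric(df$moving_avg)),
      window = as.integer(vals[["ma_window"]]),
      modelId = vals[["model"]], backendId = vals[["backend"]])
}
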