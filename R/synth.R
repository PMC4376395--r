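# Synthetic fixtures: DMD-like exon contexts, efficacy datasets drawn from
# the efficacy formula, and hexamer tables. Every generator is a pure
# function of its seed and spec, so all modules are testable without
# downloads.

#' Specification for the synthetic fixture generators
#'
#' Defaults emulate the DMD exon architecture: GC-rich exons (44%) in GC-poor
#' introns (32%) with long flanks, mid-length internal exons, and efficacy
#' values drawn from the published PMO formula plus Gaussian noise with the
#' published residual scale (RMSE 21.1).
#'
#' @param seed RNG seed (every generator is deterministic given it).
#' @param nExons number of exons.
#' @param exonLenRange exon length range (bases).
#' @param exonGC,intronGC target GC percentages.
#' @param flankLen intronic flank length (bases).
#' @param datasetN efficacy-dataset size.
#' @param noiseSD residual standard deviation of simulated skip values.
#' @param maluekaMix category sampling weights.
#' @param oligoLenRange oligo length range for sampled sites.
#' @return a `synthSpec` list.
#' @export
synthSpec <- function(seed = 1L, nExons = 4L, exonLenRange = c(120L, 200L),
                      exonGC = 44, intronGC = 32, flankLen = 200L,
                      datasetN = 66L, noiseSD = 21.1,
                      maluekaMix = c(A = 0.4, B = 0.2, C = 0.4),
                      oligoLenRange = c(25L, 30L)) {
  stopifnot(exonGC > 0, exonGC <= 100, intronGC > 0, intronGC <= 100,
            noiseSD >= 0, all(maluekaMix >= 0))
  structure(list(seed = as.integer(seed), nExons = as.integer(nExons),
                 exonLenRange = as.integer(exonLenRange), exonGC = exonGC,
                 intronGC = intronGC, flankLen = as.integer(flankLen),
                 datasetN = as.integer(datasetN), noiseSD = noiseSD,
                 maluekaMix = maluekaMix / sum(maluekaMix),
                 oligoLenRange = as.integer(oligoLenRange)),
            class = "synthSpec")
}

# allocate categories by largest-remainder quota so that the realized mix
# matches the weights as closely as n allows (guarantees A and C are both
# represented for n >= 3 under the default mix, keeping refits full rank),
# then shuffle
.quotaCategories <- function(mix, n) {
  quota <- mix * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(names(mix), times = counts))
}

# sample one element of a vector (immune to sample()'s scalar expansion)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.randSeq <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc / 100) / 2, C = gc / 200, G = gc / 200,
         T = (1 - gc / 100) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate synthetic DMD-like exon contexts
#'
#' Bases are sampled independently with per-region G/C frequencies set so the
#' expected GC content matches the spec's targets (type-2 exon/intron
#' architecture: GC-rich exon in GC-poor introns).
#'
#' @param spec a [synthSpec()].
#' @return named list of [ExonContext-class] objects (ids `synthExon1`, ...).
#' @examples
#' ctxs <- synthExonSet(synthSpec(seed = 7, nExons = 2))
#' vapply(ctxs, function(c) gcPercent(exonSeq(c)), 0)
#' @export
synthExonSet <- function(spec = synthSpec()) {
  .withSeed(spec$seed, {
    cats <- .quotaCategories(spec$maluekaMix, spec$nExons)
    out <- lapply(seq_len(spec$nExons), function(i) {
      len <- .sample1(spec$exonLenRange[1]:spec$exonLenRange[2])
      ExonContext(
        exonId = paste0("synthExon", i),
        exonSeq = .randSeq(len, spec$exonGC),
        flank5 = .randSeq(spec$flankLen, spec$intronGC),
        flank3 = .randSeq(spec$flankLen, spec$intronGC),
        maluekaCategory = cats[i])
    })
    names(out) <- vapply(out, exonId, "")
    out
  })
}

#' @describeIn synthExonSet a single synthetic exon context.
#' @export
synthExonContext <- function(spec = synthSpec()) synthExonSet(spec)[[1L]]

#' Generate a synthetic hexamer score table
#'
#' All 4096 hexamers with standard-normal scores (or a constant).
#'
#' @param seed RNG seed.
#' @param constant if non-`NULL`, every hexamer gets this score instead.
#' @return named numeric vector of length 4096.
#' @export
synthHexamerTable <- function(seed = 1L, constant = NULL) {
  bases <- c("A", "C", "G", "T")
  hexes <- do.call(paste0, expand.grid(rep(list(bases), 6L),
                                       stringsAsFactors = FALSE))
  if (!is.null(constant))
    return(stats::setNames(rep(as.numeric(constant), 4096L), hexes))
  .withSeed(seed, stats::setNames(rnorm(4096L), hexes))
}

#' @describeIn synthHexamerTable write a hexamer table as two-column text.
#' @param table named numeric hexamer table.
#' @param path output path.
#' @export
writeHexamerTable <- function(table, path) {
  write.table(data.frame(hexamer = names(table),
                         score = sprintf("%.17g", table)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Generate a synthetic oligo-efficacy dataset from the efficacy formula
#'
#' Samples target sites across the supplied exon contexts, computes their true
#' descriptors (DfA, dG50 via the backend, Malueka category, length), and sets
#' `observed_skip_pct = formula(descriptors) + Normal(0, noiseSD)`. The output
#' conforms to the compiled-dataset schema consumed by
#' [loadCompiledDataset()]. Simulated values are left unbounded by default
#' (the linear model is unbounded; truncation to \[0, 100\] would bias
#' parameter-recovery tests); set `truncate = TRUE` for realism demos.
#'
#' Loader-branch switches: `nGradeOnly` appends records reported only as the
#' unstratified `">5%"` grade and `nWilton` appends Wilton-study rows, so the
#' loader's exclusion flags can be exercised.
#'
#' @param spec a [synthSpec()].
#' @param contexts exon contexts (defaults to `synthExonSet(spec)`).
#' @param coeffs generating [SkipModelCoefficients-class]
#'   (default [pmoCoefficients()]).
#' @param backend a [ThermoBackend-class] for dG50.
#' @param truncate clip simulated skip values to \[0, 100\].
#' @param nGradeOnly,nWilton extra loader-branch rows.
#' @param study study label for the main rows.
#' @return data.frame of records (compiled schema plus `good` and flags via
#'   [loadCompiledDataset()] semantics).
#' @export
synthEfficacyDataset <- function(spec = synthSpec(), contexts = NULL,
                                 coeffs = pmoCoefficients(),
                                 backend = SimpleNNBackend(),
                                 truncate = FALSE, nGradeOnly = 0L,
                                 nWilton = 0L, study = "Popplewell") {
  if (is.null(contexts)) contexts <- synthExonSet(spec)
  n <- spec$datasetN
  nSitesAvail <- sum(vapply(contexts, function(ctx)
    nchar(exonSeq(ctx)) - spec$oligoLenRange[1] + 1L, 0L))
  if (n > nSitesAvail)
    warning("requested ", n, " records from ~", nSitesAvail,
            " distinct sites; sampling with replacement", call. = FALSE)
  .withSeed(spec$seed + 1L, {
    rows <- lapply(seq_len(n), function(i) {
      ctx <- contexts[[.sample1(seq_along(contexts))]]
      L <- .sample1(spec$oligoLenRange[1]:spec$oligoLenRange[2])
      exLen <- nchar(exonSeq(ctx))
      dfa <- .sample1(0:(exLen - L))
      site <- enumerateTargetSites(ctx, L)[[dfa + 1L]]
      region <- flankedRegion(ctx, site, "f50")
      oligo <- antisenseOligo(site, lengthBounds = NULL)
      dg50 <- dG(bindingEnergy(oligo, region, backend))
      truth <- pmoPredictedSkip(site@dfa, dg50, maluekaCategory(ctx), coeffs)
      data.frame(study = study, exon = exonId(ctx),
                 oligo_name = sprintf("syn%03d", i), chemistry = "PMO",
                 sequence = oligo@sequence, observed_skip_pct = truth,
                 observed_grade = NA_character_, dfa = site@dfa,
                 acp = site@acp, length = L, length_gt22 = L >= 23L,
                 dg50 = dg50, malueka = maluekaCategory(ctx),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$observed_skip_pct <- df$observed_skip_pct +
      rnorm(n, 0, spec$noiseSD)
    if (truncate)
      df$observed_skip_pct <- pmin(pmax(df$observed_skip_pct, 0), 100)
    if (nGradeOnly > 0L) {
      extra <- df[sample(n, nGradeOnly, replace = TRUE), , drop = FALSE]
      extra$study <- "AartsmaRus"
      extra$observed_skip_pct <- NA_real_
      extra$observed_grade <- ">5%"
      extra$oligo_name <- sprintf("synG%03d", seq_len(nGradeOnly))
      df <- rbind(df, extra)
    }
    if (nWilton > 0L) {
      extra <- df[sample(n, nWilton, replace = TRUE), , drop = FALSE]
      extra$study <- "Wilton"
      extra$observed_grade <- ">30%"
      extra$observed_skip_pct <- NA_real_
      extra$oligo_name <- sprintf("synW%03d", seq_len(nWilton))
      df <- rbind(df, extra)
    }
    thr <- studyThresholds()[df$study]
    thr[is.na(thr)] <- 30
    df$wilton_omitted <- df$study == "Wilton"
    df$grade_only_gt5 <- is.na(df$observed_skip_pct) &
      df$observed_grade == ">5%" & !is.na(df$observed_grade)
    df$good <- ifelse(!is.na(df$observed_skip_pct),
                      df$observed_skip_pct > thr,
                      .gradeToGood(df$observed_grade, thr))
    rownames(df) <- NULL
    df
  })
}
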