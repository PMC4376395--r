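# Model derivation: compiled-dataset loading, least squares with centered
# interactions, logistic good/bad classification, stepwise selection with
# K-fold cross-validation, confusion matrices, leave-one-exon-out refits.

#' Load a compiled oligo-efficacy dataset
#'
#' Reads a delimited text table (tab- or comma-separated by extension)
#' mirroring the compiled-study schema. Mandatory columns: `study`, `exon`,
#' `oligo_name`, `chemistry`, `sequence`, plus at least one of
#' `observed_skip_pct` (exact percentage) / `observed_grade` (a stratified
#' level such as `">30%"`, `"10-30%"`, `"<5%"`). Any further columns
#' (descriptors such as `dfa`, `dg50`, `length`, `malueka`, imported scores)
#' are carried through.
#'
#' Exclusion flags are populated: `wilton_omitted` marks Wilton-study rows
#' (omitted from cross-chemistry analyses because of that dataset's reporting
#' peculiarities) and `grade_only_gt5` marks rows whose only efficacy
#' information is the unstratified `">5%"` grade, unusable for good/bad
#' classification. A logical `good` column is derived from the per-study
#' threshold where the percentage or grade determines it, else `NA`.
#'
#' @param path file path.
#' @param thresholds named per-study 'good' cutoffs ([studyThresholds()]).
#' @param quiet suppress the per-study count message.
#' @return data.frame of typed records with flag columns.
#' @export
loadCompiledDataset <- function(path, thresholds = studyThresholds(),
                                quiet = FALSE) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#")
  mandatory <- c("study", "exon", "oligo_name", "chemistry", "sequence")
  missingCols <- setdiff(mandatory, names(df))
  if (length(missingCols))
    stop("missing mandatory column(s): ", paste(missingCols, collapse = ", "),
         call. = FALSE)
  if (!"observed_skip_pct" %in% names(df)) df$observed_skip_pct <- NA_real_
  if (!"observed_grade" %in% names(df)) df$observed_grade <- NA_character_
  df$observed_skip_pct <- .parseEfficacy(df$observed_skip_pct, path)
  # descriptor columns are doubles even when their values happen to be whole
  numericCols <- c("acp", "dg_target", "dg50", "dg100", "dg200", "dg_et10",
                   "gc_oligo", "acc_target", "acc_target_norm", "acc_last15",
                   "acc_last8", "acc_max8", "ni_cumulative", "ni_per_base",
                   "exon_gc", "intron_gc", "delta_gc",
                   "delta_gc_ignoring_target", "delta_gc_change")
  for (nm in intersect(numericCols, names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  df$observed_grade <- as.character(df$observed_grade)
  df$observed_grade[df$observed_grade %in% c("", "NA")] <- NA_character_
  noInfo <- is.na(df$observed_skip_pct) & is.na(df$observed_grade)
  if (any(noInfo))
    stop("row(s) ", paste(which(noInfo), collapse = ", "),
         " carry neither an exact percentage nor a grade", call. = FALSE)
  thr <- thresholds[df$study]
  thr[is.na(thr)] <- 30
  df$wilton_omitted <- df$study == "Wilton"
  df$grade_only_gt5 <- is.na(df$observed_skip_pct) &
    !is.na(df$observed_grade) & df$observed_grade == ">5%"
  df$good <- ifelse(!is.na(df$observed_skip_pct),
                    df$observed_skip_pct > thr,
                    .gradeToGood(df$observed_grade, thr))
  if (!quiet) {
    counts <- table(df$study)
    message("loaded ", nrow(df), " oligo records (",
            paste(names(counts), counts, sep = ": ", collapse = "; "), ")")
  }
  df
}

.parseEfficacy <- function(x, path) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA
  out <- suppressWarnings(as.numeric(sub("%$", "", x)))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("unparseable efficacy value(s) in ", path, " at row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

# map a stratified grade ("<5%", ">30%", "10-30%") to good/bad at `thr`;
# NA when the grade interval straddles the threshold
.gradeToGood <- function(grade, thr) {
  lo <- rep(NA_real_, length(grade))
  hi <- rep(NA_real_, length(grade))
  gt <- grepl("^>\\s*[0-9.]+%?$", grade)
  lt <- grepl("^<\\s*[0-9.]+%?$", grade)
  rng <- grepl("^[0-9.]+\\s*-\\s*[0-9.]+%?$", grade)
  num <- function(g) as.numeric(gsub("[^0-9.]", "", g))
  lo[gt] <- vapply(grade[gt], num, 0); hi[gt] <- 100
  hi[lt] <- vapply(grade[lt], num, 0); lo[lt] <- 0
  if (any(rng, na.rm = TRUE)) {
    parts <- strsplit(gsub("%", "", grade[which(rng)]), "-")
    lo[which(rng)] <- as.numeric(vapply(parts, `[`, "", 1))
    hi[which(rng)] <- as.numeric(vapply(parts, `[`, "", 2))
  }
  ifelse(is.na(lo) | is.na(hi), NA,
         ifelse(lo >= thr, TRUE, ifelse(hi <= thr, FALSE, NA)))
}

#' Write a compiled dataset back to delimited text
#'
#' Inverse of [loadCompiledDataset()]; numeric columns are written at full
#' precision so that a round trip reproduces identical values.
#'
#' @param records data.frame of records.
#' @param path output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
writeCompiledDataset <- function(records, path) {
  records <- records[setdiff(names(records),
                             c("wilton_omitted", "grade_only_gt5", "good"))]
  out <- records
  for (nm in names(out))
    if (is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

## ---- design matrices -------------------------------------------------------

# Build the numeric design data.frame for `terms` + centered `interactions`.
# `malueka` expands to indicator offsets for categories A and C (B/unknown
# are the reference, matching the published formula's structure).
.buildDesign <- function(data, terms, interactions, centers = NULL) {
  X <- data.frame(row.names = seq_len(nrow(data)))
  for (tm in terms) {
    if (tm == "malueka") {
      X$malueka_offset_A <- as.numeric(data$malueka == "A")
      X$malueka_offset_C <- as.numeric(data$malueka == "C")
    } else if (tm == "length_gt22") {
      X$length_gt22 <- as.numeric(data$length_gt22)
    } else {
      if (is.null(data[[tm]]))
        stop("term '", tm, "' not found in the data", call. = FALSE)
      X[[tm]] <- as.numeric(data[[tm]])
    }
  }
  usedCenters <- numeric()
  for (ia in interactions) {
    a <- ia[1]; b <- ia[2]
    ca <- centers[[paste0("center_", a)]] %||% mean(as.numeric(data[[a]]))
    cb <- centers[[paste0("center_", b)]] %||% mean(as.numeric(data[[b]]))
    X[[paste0("cross_", a, "_", b)]] <-
      (as.numeric(data[[a]]) - ca) * (as.numeric(data[[b]]) - cb)
    usedCenters[paste0("center_", a)] <- ca
    usedCenters[paste0("center_", b)] <- cb
  }
  attr(X, "centers") <- usedCenters
  X
}

#' Standard least squares with centered interactions
#'
#' Ordinary least squares of `response` on main-effect `terms` plus centered
#' pairwise `interactions` (each interaction is the product of its two factors
#' after subtracting their sample means, or supplied `centers`). The special
#' term `"malueka"` expands to offset indicators for categories A and C.
#'
#' @param data data.frame of records (as from [loadCompiledDataset()] or
#'   [synthEfficacyDataset()]); rows with missing response are dropped.
#' @param response response column (default `observed_skip_pct`).
#' @param terms main-effect terms.
#' @param interactions list of 2-vectors of numeric term names.
#' @param centers optional named centering constants
#'   (`center_<term> = value`); defaults to sample means.
#' @return a [FittedSkipModel-class]. `r2 = 1 - SSE/SST`;
#'   `rmse = sqrt(SSE/(n - p))` with `p` the number of coefficients including
#'   the intercept.
#' @export
fitLeastSquares <- function(data, response = "observed_skip_pct",
                            terms = c("dfa", "dg50", "malueka"),
                            interactions = list(c("dfa", "dg50")),
                            centers = NULL) {
  y <- as.numeric(data[[response]])
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  X <- .buildDesign(data, terms, interactions, centers)
  p <- ncol(X) + 1L
  if (length(y) < p + 2L)
    stop("need at least p + 2 = ", p + 2L, " records with a response",
         call. = FALSE)
  df <- cbind(.response = y, X)
  fit <- lm(.response ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    collinear <- names(coef(fit))[is.na(coef(fit))]
    stop("design is rank deficient; collinear term(s): ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  new("FittedSkipModel", fit = fit, terms = terms,
      interactions = interactions, centers = attr(X, "centers"),
      r2 = if (sst > 0) 1 - sse / sst else 0,
      rmse = sqrt(sse / (length(y) - p)),
      n = length(y), p = as.integer(p))
}

#' @describeIn fitLeastSquares predictions from a fitted model on new records.
#' @param model a [FittedSkipModel-class].
#' @param newdata data.frame of records.
#' @export
predictSkip <- function(model, newdata) {
  X <- .buildDesign(newdata, model@terms, model@interactions,
                    as.list(model@centers))
  as.numeric(predict(model@fit, newdata = X))
}

#' Export a fitted PMO model as formula coefficients
#'
#' Maps a [FittedSkipModel-class] fitted on
#' `terms = c("dfa", "dg50", "malueka")` with the `dfa x dg50` interaction to
#' a [SkipModelCoefficients-class] consumable by [pmoPredictedSkip()].
#'
#' @param model a [FittedSkipModel-class].
#' @param id provenance identifier.
#' @return a [SkipModelCoefficients-class].
#' @export
exportCoefficients <- function(model, id = "pmo-refit") {
  b <- coef(model@fit)
  pick <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  pmoCoefficients(
    intercept = b[["(Intercept)"]], coef_dfa = pick("dfa"),
    coef_dg50 = pick("dg50"),
    malueka_offset_A = pick("malueka_offset_A"),
    malueka_offset_C = pick("malueka_offset_C"),
    coef_cross = pick("cross_dfa_dg50"),
    center_dfa = model@centers[["center_dfa"]],
    center_dg50 = model@centers[["center_dg50"]], id = id)
}

#' Re-express centered-interaction coefficients at different centers
#'
#' The model `b0 + b1 x + b2 y + g (x - a)(y - c)` is invariant under a change
#' of centering constants once the intercept and main effects absorb the
#' shift; this maps a coefficient set to new centers so that fits with
#' different centerings can be compared coefficient-by-coefficient.
#'
#' @param coeffs a PMO-style [SkipModelCoefficients-class].
#' @param center_dfa,center_dg50 the new centers.
#' @return a [SkipModelCoefficients-class] at the new centers.
#' @export
recenterCoefficients <- function(coeffs, center_dfa, center_dg50) {
  k <- coeffs@coefficients
  a <- coeffs@centers[["center_dfa"]]
  c0 <- coeffs@centers[["center_dg50"]]
  g <- k[["coef_cross"]]
  pmoCoefficients(
    intercept = k[["intercept"]] + g * a * c0 - g * center_dfa * center_dg50,
    coef_dfa = k[["coef_dfa"]] + g * (center_dg50 - c0),
    coef_dg50 = k[["coef_dg50"]] + g * (center_dfa - a),
    malueka_offset_A = k[["malueka_offset_A"]],
    malueka_offset_C = k[["malueka_offset_C"]],
    coef_cross = g, center_dfa = center_dfa, center_dg50 = center_dg50,
    id = paste0(coeffs@id, "-recentered"))
}

## ---- classification --------------------------------------------------------

#' Construct a confusion matrix
#'
#' @param observed,predicted logical (or `"good"`/`"bad"`) vectors, or pass
#'   counts directly via `tn`/`fp`/`fn`/`tp`.
#' @param tn,fp,fn,tp counts (used when `observed` is missing).
#' @return a [ConfusionMatrix-class].
#' @examples
#' proportionCorrect(confusionMatrix(tn = 9, fp = 1, fn = 3, tp = 10))
#' @export
confusionMatrix <- function(observed, predicted, tn = 0L, fp = 0L, fn = 0L,
                            tp = 0L) {
  if (!missing(observed)) {
    toLogical <- function(x) if (is.character(x)) x == "good" else as.logical(x)
    o <- toLogical(observed); p <- toLogical(predicted)
    keep <- !is.na(o) & !is.na(p)
    o <- o[keep]; p <- p[keep]
    tn <- sum(!o & !p); fp <- sum(!o & p)
    fn <- sum(o & !p); tp <- sum(o & p)
  }
  new("ConfusionMatrix", tn = as.integer(tn), fp = as.integer(fp),
      fn = as.integer(fn), tp = as.integer(tp))
}

#' @rdname proportionCorrect
setMethod("proportionCorrect", "ConfusionMatrix", function(object) {
  total <- object@tn + object@fp + object@fn + object@tp
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  100 * (object@tn + object@tp) / total
})

#' Logistic good/bad classifier
#'
#' Maximum-likelihood logistic regression of the `good` label on the model
#' terms (binary case of the ordinal model, one cutpoint). Complete separation
#' is reported as a warning and the fit falls back to a lightly
#' ridge-penalized IRLS. The in-sample confusion matrix is taken at
#' probability 0.5. Rows with `NA` labels (e.g. `grade_only_gt5` records) are
#' dropped.
#'
#' @param data data.frame of records with a logical `good` column (see
#'   [loadCompiledDataset()]).
#' @param terms,interactions,centers as in [fitLeastSquares()].
#' @param response label column (default `"good"`).
#' @return a [SkipClassifier-class].
#' @export
fitBinaryLogistic <- function(data, terms = c("dfa", "dg50", "malueka"),
                              interactions = list(c("dfa", "dg50")),
                              centers = NULL, response = "good") {
  y <- data[[response]]
  if (is.character(y)) y <- y == "good"
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit a classifier", call. = FALSE)
  X <- .buildDesign(data, terms, interactions, centers)
  df <- cbind(.good = y, X)
  separable <- FALSE
  fit <- withCallingHandlers(
    glm(.good ~ ., family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separable) {
    warning("complete separation detected; using ridge-penalized logistic ",
            "fit", call. = FALSE)
    beta <- .ridgeLogistic(cbind(1, as.matrix(X)), y, lambda = 1e-2)
    names(beta) <- c("(Intercept)", colnames(X))
  } else {
    beta <- coef(fit)
  }
  lp <- as.numeric(cbind(1, as.matrix(X)) %*% beta)
  pred <- plogis(lp) > 0.5
  new("SkipClassifier", coefficients = beta, terms = terms,
      interactions = interactions, centers = attr(X, "centers"),
      confusion = confusionMatrix(y > 0.5, pred), separable = separable,
      method = if (separable) "ridge-irls" else "glm")
}

# minimal ridge-penalized logistic IRLS (intercept unpenalized)
.ridgeLogistic <- function(X, y, lambda = 1e-2, iter = 100L) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(iter)) {
    mu <- plogis(as.numeric(X %*% beta))
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' @describeIn fitBinaryLogistic predicted good probabilities on new records.
#' @param classifier a [SkipClassifier-class].
#' @param newdata data.frame of records.
#' @export
predictGoodProbability <- function(classifier, newdata) {
  X <- .buildDesign(newdata, classifier@terms, classifier@interactions,
                    as.list(classifier@centers))
  plogis(as.numeric(cbind(1, as.matrix(X)) %*% classifier@coefficients))
}

#' Ordinal logistic fit on graded efficacy levels
#'
#' Proportional-odds model ([MASS::polr]) for studies that report efficacy as
#' ordered grades rather than exact percentages.
#'
#' @param data data.frame of records.
#' @param terms,interactions,centers as in [fitLeastSquares()].
#' @param gradeColumn ordered-factor (or character) grade column.
#' @return the fitted `polr` object with the design attached.
#' @export
fitOrdinalLogistic <- function(data, terms = c("dfa", "dg50"),
                               interactions = list(), centers = NULL,
                               gradeColumn = "observed_grade") {
  g <- data[[gradeColumn]]
  keep <- !is.na(g)
  data <- data[keep, , drop = FALSE]
  g <- g[keep]
  if (!is.ordered(g)) g <- factor(g, levels = unique(g), ordered = TRUE)
  X <- .buildDesign(data, terms, interactions, centers)
  df <- cbind(.grade = g, X)
  MASS::polr(.grade ~ ., data = df, Hess = TRUE)
}

## ---- stepwise selection with K-fold validation -----------------------------

# fold assignment by seeded shuffle; sizes differ by at most 1
.makeFolds <- function(n, K, seed) {
  .withSeed(seed, sample(rep(seq_len(K), length.out = n)))
}

.kfoldR2 <- function(data, response, terms, interactions, folds) {
  y <- as.numeric(data[[response]])
  K <- max(folds)
  r2s <- vapply(seq_len(K), function(k) {
    train <- data[folds != k, , drop = FALSE]
    test <- data[folds == k, , drop = FALSE]
    m <- tryCatch(fitLeastSquares(train, response, terms, interactions),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    pred <- predictSkip(m, test)
    yt <- as.numeric(test[[response]])
    sst <- sum((yt - mean(yt))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((yt - pred)^2) / sst
  }, 0)
  mean(r2s, na.rm = TRUE)
}

#' Forward stepwise selection with K-fold cross-validation
#'
#' Starting from the intercept-only model, repeatedly adds the candidate term
#' minimizing the BIC of the enlarged least-squares fit, stopping when no
#' candidate improves BIC (`criterion = "bic"`, default) or when the average
#' held-out K-fold R-squared stops improving (`criterion = "kfold"`). For each
#' accepted step the in-sample R-squared and the K-fold R-squared (average
#' over folds of `1 - SSE/SST` on the held-out fold) are recorded. Candidate
#' names of the form `"a:b"` denote centered interactions.
#'
#' @param data data.frame of records (rows with missing response dropped).
#' @param response response column.
#' @param candidates character vector of candidate terms.
#' @param K number of folds (>= 2; n >= 2K required).
#' @param seed fold-assignment seed.
#' @param criterion `"bic"` or `"kfold"`.
#' @return a [StepwisePath-class].
#' @export
stepwiseKfold <- function(data, response = "observed_skip_pct", candidates,
                          K = 5L, seed = 20150327L,
                          criterion = c("bic", "kfold")) {
  criterion <- match.arg(criterion)
  K <- as.integer(K)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  n <- nrow(data)
  if (K < 2L || n < 2L * K)
    stop("need K >= 2 and n >= 2K (n = ", n, ", K = ", K, ")", call. = FALSE)
  folds <- .makeFolds(n, K, seed)
  splitTerm <- function(tm) {
    if (grepl(":", tm, fixed = TRUE)) strsplit(tm, ":", fixed = TRUE)[[1]]
    else NULL
  }
  chosen <- character()
  steps <- data.frame(term = character(), bic = numeric(), r2 = numeric(),
                      kfold_r2 = numeric(), stringsAsFactors = FALSE)
  currentBIC <- BIC(lm(data[[response]] ~ 1))
  currentKfold <- -Inf
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    scores <- vapply(remaining, function(cand) {
      trial <- c(chosen, cand)
      terms <- trial[!grepl(":", trial)]
      ints <- lapply(trial[grepl(":", trial)], splitTerm)
      m <- tryCatch(fitLeastSquares(data, response, terms, ints),
                    error = function(e) NULL)
      if (is.null(m)) NA_real_ else BIC(m@fit)
    }, 0)
    if (all(is.na(scores))) break
    best <- names(which.min(scores))
    trial <- c(chosen, best)
    terms <- trial[!grepl(":", trial)]
    ints <- lapply(trial[grepl(":", trial)], splitTerm)
    kf <- .kfoldR2(data, response, terms, ints, folds)
    if (criterion == "bic" && min(scores, na.rm = TRUE) >= currentBIC) break
    if (criterion == "kfold" && kf <= currentKfold) break
    m <- fitLeastSquares(data, response, terms, ints)
    chosen <- trial
    remaining <- setdiff(remaining, best)
    currentBIC <- min(scores, na.rm = TRUE)
    currentKfold <- kf
    steps <- rbind(steps, data.frame(term = best, bic = currentBIC,
                                     r2 = m@r2, kfold_r2 = kf,
                                     stringsAsFactors = FALSE))
  }
  new("StepwisePath", steps = steps, K = K, seed = as.integer(seed))
}

#' Refit the models with one exon held out
#'
#' Guards against single-exon bias: removes all records of `excludedExon`,
#' refits the least-squares model and the good/bad classifier on the same
#' terms, and reports their statistics.
#'
#' @param data data.frame of records with an `exon` column.
#' @param excludedExon exon to remove.
#' @param terms,interactions as in [fitLeastSquares()].
#' @return list with elements `linear` ([FittedSkipModel-class]),
#'   `classifier` ([SkipClassifier-class]), `r2`, `proportion_correct`, `n`.
#' @export
leaveExonOutRefit <- function(data, excludedExon,
                              terms = c("dfa", "dg50", "malueka"),
                              interactions = list(c("dfa", "dg50"))) {
  if (!excludedExon %in% data$exon)
    stop("exon ", excludedExon, " not present in the data", call. = FALSE)
  sub <- data[data$exon != excludedExon, , drop = FALSE]
  linear <- fitLeastSquares(sub, terms = terms, interactions = interactions)
  classifier <- fitBinaryLogistic(sub, terms = terms,
                                  interactions = interactions)
  list(linear = linear, classifier = classifier, r2 = linear@r2,
       proportion_correct = proportionCorrect(classifier@confusion),
       n = nrow(sub))
}
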