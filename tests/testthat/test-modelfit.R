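makeDataset <- function(seed = 3, n = 60, noise = 0, nExons = 4) {
  synthEfficacyDataset(synthSpec(seed = seed, nExons = nExons,
                                 exonLenRange = c(100L, 140L),
                                 flankLen = 120L, datasetN = n,
                                 noiseSD = noise))
}

test_that("the loader types records and populates exclusion flags", {
  df <- data.frame(
    study = c("Popplewell", "Popplewell", "AartsmaRus", "AartsmaRus",
              "Wilton"),
    exon = c(44, 44, 51, 51, 53), oligo_name = paste0("o", 1:5),
    chemistry = c("PMO", "PMO", "2OMe", "2OMe", "2OMe"),
    sequence = replicate(5, randomDNA(20)),
    observed_skip_pct = c(55.5, 12, NA, NA, NA),
    observed_grade = c(NA, NA, ">5%", ">25%", "10-30%"),
    dfa = c(0, 10, 5, 8, 2), dg50 = c(-40, -20, -30, -35, -25),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rec <- loadCompiledDataset(f, quiet = TRUE)
  expect_identical(nrow(rec), 5L)
  expect_identical(rec$wilton_omitted, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(rec$grade_only_gt5, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # good: 55.5 > 30 TRUE; 12 FALSE; ">5%" undecidable at 25; ">25%" TRUE;
  # "10-30%" at threshold 30 -> FALSE
  expect_identical(rec$good, c(TRUE, FALSE, NA, TRUE, FALSE))

  df$observed_skip_pct <- as.character(df$observed_skip_pct)
  df$observed_skip_pct[1] <- "n.d."
  write.csv(df, f, row.names = FALSE)
  expect_error(loadCompiledDataset(f, quiet = TRUE), "unparseable")
  df2 <- df[, setdiff(names(df), "sequence")]
  write.csv(df2, f, row.names = FALSE)
  expect_error(loadCompiledDataset(f, quiet = TRUE), "mandatory")
})

test_that("compiled datasets round-trip through write + load", {
  ds <- makeDataset(seed = 8, n = 20, noise = 10)
  f <- tempfile(fileext = ".tsv")
  writeCompiledDataset(ds, f)
  back <- loadCompiledDataset(f, quiet = TRUE)
  expect_identical(back$observed_skip_pct, ds$observed_skip_pct)
  expect_identical(back$dg50, ds$dg50)
  expect_identical(back$good, ds$good)
})

test_that("noise-free synthetic data refits to the generating coefficients", {
  ds <- makeDataset(seed = 3, n = 60, noise = 0)
  m <- fitLeastSquares(ds)
  expect_equal(m@r2, 1, tolerance = 1e-12)
  truth <- pmoCoefficients()
  refit <- recenterCoefficients(exportCoefficients(m),
                                truth@centers[["center_dfa"]],
                                truth@centers[["center_dg50"]])
  expect_equal(refit@coefficients, truth@coefficients, tolerance = 1e-6)
})

test_that("degenerate and deficient designs are handled explicitly", {
  ds <- makeDataset(seed = 9, n = 30, noise = 0)
  ds$observed_skip_pct <- 42
  m <- fitLeastSquares(ds, terms = c("dfa", "dg50"), interactions = list())
  expect_equal(unname(coef(m@fit)[-1]), c(0, 0), tolerance = 1e-12)
  expect_equal(m@r2, 0)
  ds$dup <- ds$dfa
  expect_error(fitLeastSquares(ds, terms = c("dfa", "dup", "dg50"),
                               interactions = list()),
               "rank deficient")
  expect_error(fitLeastSquares(ds[1:5, ]), "at least")
})

test_that("OLS residuals are orthogonal to the design columns", {
  ds <- makeDataset(seed = 10, n = 50, noise = 21.1)
  m <- fitLeastSquares(ds)
  X <- stats::model.matrix(m@fit)
  expect_lt(max(abs(crossprod(X, residuals(m@fit)))), 1e-7)
  # rmse convention: sqrt(SSE / (n - p))
  expect_equal(m@rmse, sqrt(sum(residuals(m@fit)^2) / (m@n - m@p)))
})

test_that("predictSkip reproduces the fit's own predictions", {
  ds <- makeDataset(seed = 11, n = 40, noise = 5)
  m <- fitLeastSquares(ds)
  expect_equal(predictSkip(m, ds), unname(fitted(m@fit)))
})

test_that("the classifier separates separable data and flags separation", {
  ds <- makeDataset(seed = 12, n = 40, noise = 0)
  # split between two distinct dg50 values so the classes are separable
  u <- sort(unique(ds$dg50))
  cut <- mean(u[c(length(u) %/% 2, length(u) %/% 2 + 1L)])
  ds$good <- ds$dg50 < cut
  expect_warning(
    cl <- fitBinaryLogistic(ds, terms = "dg50", interactions = list()),
    "separation")
  expect_true(cl@separable)
  expect_identical(cl@method, "ridge-irls")
  expect_equal(proportionCorrect(cl@confusion), 100)
})

test_that("swapping class labels negates the logistic linear predictor", {
  ds <- makeDataset(seed = 13, n = 60, noise = 21.1)
  cl1 <- suppressWarnings(fitBinaryLogistic(ds))
  ds2 <- ds; ds2$good <- !ds$good
  cl2 <- suppressWarnings(fitBinaryLogistic(ds2))
  expect_equal(cl1@coefficients, -cl2@coefficients, tolerance = 1e-6)
  expect_equal(predictGoodProbability(cl1, ds),
               1 - predictGoodProbability(cl2, ds), tolerance = 1e-6)
})

test_that("classifier confusion counts match a brute-force recount", {
  ds <- makeDataset(seed = 14, n = 60, noise = 21.1)
  cl <- suppressWarnings(fitBinaryLogistic(ds))
  p <- predictGoodProbability(cl, ds) > 0.5
  cm <- cl@confusion
  expect_identical(cm@tp, sum(ds$good & p))
  expect_identical(cm@tn, sum(!ds$good & !p))
  expect_equal(proportionCorrect(cm), 100 * mean(ds$good == p))
})

test_that("proportion correct follows its definition", {
  expect_equal(proportionCorrect(confusionMatrix(tn = 9, fp = 1, fn = 3,
                                                 tp = 10)),
               100 * 19 / 23)
  expect_equal(proportionCorrect(confusionMatrix(tn = 5, fp = 0, fn = 0,
                                                 tp = 7)), 100)
  expect_error(proportionCorrect(confusionMatrix(tn = 0, fp = 0, fn = 0,
                                                 tp = 0)), "empty")
  cm <- confusionMatrix(observed = c(TRUE, TRUE, FALSE, NA),
                        predicted = c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(c(cm@tn, cm@fp, cm@fn, cm@tp), c(1L, 0L, 1L, 1L))
})

test_that("ordinal fits run on graded responses", {
  ds <- makeDataset(seed = 15, n = 60, noise = 21.1)
  ds$observed_grade <- cut(ds$observed_skip_pct, c(-Inf, 10, 30, Inf),
                           labels = c("<10%", "10-30%", ">30%"),
                           ordered_result = TRUE)
  fit <- fitOrdinalLogistic(ds, terms = c("dfa", "dg50"))
  expect_s3_class(fit, "polr")
  expect_lt(coef(fit)[["dg50"]], 0)  # stronger binding -> higher grade
})

test_that("fold assignment partitions the data evenly and reproducibly", {
  folds <- skipAO:::.makeFolds(23, 5, seed = 99)
  expect_identical(length(folds), 23L)
  expect_identical(sort(unique(folds)), 1:5)
  expect_lte(diff(range(table(folds))), 1)
  expect_identical(folds, skipAO:::.makeFolds(23, 5, seed = 99))
})

test_that("stepwise selection finds planted effects and stops on noise", {
  set.seed(61)
  n <- 80
  ds <- data.frame(matrix(rnorm(n * 10), n, 10))
  names(ds) <- paste0("x", 1:10)
  ds$observed_skip_pct <- 8 * ds$x3 - 6 * ds$x7 + rnorm(n, 0, 1)
  path <- stepwiseKfold(ds, candidates = paste0("x", 1:10), K = 5, seed = 1)
  expect_identical(sort(path@steps$term[1:2]), c("x3", "x7"))
  expect_true(all(diff(path@steps$r2) >= -1e-9))
  expect_gt(path@steps$kfold_r2[2], 0.9)
  # pure noise: nothing beats the intercept's BIC (or at most one step)
  ds$observed_skip_pct <- rnorm(n)
  pathN <- stepwiseKfold(ds, candidates = paste0("x", 1:10), K = 5, seed = 1)
  expect_lte(nrow(pathN@steps), 1L)
  # interaction candidates are recognized
  ds$observed_skip_pct <- 5 * ds$x1 * ds$x2 + rnorm(n, 0, 0.5)
  pathI <- stepwiseKfold(ds, candidates = c("x1", "x2", "x1:x2"), K = 5,
                         seed = 1)
  expect_true("x1:x2" %in% pathI@steps$term)
  expect_error(stepwiseKfold(ds[1:8, ], candidates = "x1", K = 5, seed = 1),
               "n >= 2K")
})

test_that("stepwise selection is deterministic given the seed", {
  ds <- makeDataset(seed = 16, n = 60, noise = 21.1)
  ds$noise1 <- rnorm(60); ds$noise2 <- rnorm(60)
  cands <- c("dfa", "dg50", "noise1", "noise2", "dfa:dg50")
  p1 <- stepwiseKfold(ds, candidates = cands, K = 5, seed = 20150327)
  p2 <- stepwiseKfold(ds, candidates = cands, K = 5, seed = 20150327)
  expect_identical(p1@steps, p2@steps)
  expect_true(all(c("dg50") %in% p1@steps$term))
})

test_that("leave-one-exon-out refits drop the exon and keep both fits", {
  ds <- makeDataset(seed = 17, n = 70, noise = 21.1, nExons = 4)
  ex <- ds$exon[1]
  out <- leaveExonOutRefit(ds, ex)
  expect_identical(out$n, sum(ds$exon != ex))
  expect_s4_class(out$linear, "FittedSkipModel")
  expect_s4_class(out$classifier, "SkipClassifier")
  expect_true(out$r2 > 0 && out$r2 <= 1)
  expect_true(out$proportion_correct > 50)
  expect_error(leaveExonOutRefit(ds, "absent-exon"), "not present")
})
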