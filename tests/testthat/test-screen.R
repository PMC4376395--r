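test_that("screen rows equal independent per-position formula evaluation", {
  ctx <- toyContext(seed = 107, exonLen = 40, flankLen = 50, malueka = "C")
  prof <- screenExon(ctx, 30)
  expect_identical(nrow(prof@rows), 11L)
  expect_identical(prof@rows$dfa, 0:10)
  sites <- enumerateTargetSites(ctx, 30)
  for (i in c(1, 6, 11)) {
    direct <- dG(bindingEnergy(antisenseOligo(sites[[i]]),
                               flankedRegion(ctx, sites[[i]], "f50"),
                               simpleBackend))
    expect_equal(prof@rows$dg50[i], direct)
    expect_equal(prof@rows$prediction[i],
                 pmoPredictedSkip(sites[[i]]@dfa, direct, "C"))
    expect_identical(prof@rows$oligo_seq[i],
                     antisenseOligo(sites[[i]])@sequence)
  }
})

test_that("Malueka A and C contexts differ by the constant formula offset", {
  ctxC <- toyContext(seed = 108, exonLen = 40, flankLen = 50, malueka = "C")
  ctxA <- ExonContext(exonId(ctxC), exonSeq(ctxC), flank5(ctxC),
                      flank3(ctxC), maluekaCategory = "A")
  pC <- screenExon(ctxC, 30)@rows$prediction
  pA <- screenExon(ctxA, 30)@rows$prediction
  expect_equal(pC - pA, rep(22.8, length(pC)), tolerance = 1e-12)
})

test_that("uniform-dG50 screens are exactly affine in acceptor distance", {
  # poly-A exon and flanks: every f50 window is identical sequence, so dG50
  # is constant and the prediction series must be affine in dfa with slope
  # coef_dfa + coef_cross * (dG50 - center_dg50)
  ctx <- ExonContext("flat", strrep("A", 60), strrep("A", 50), strrep("A", 50),
                     maluekaCategory = "B")
  prof <- screenExon(ctx, 30)
  dg <- unique(prof@rows$dg50)
  expect_length(dg, 1L)
  slope <- -0.253 + 0.02 * (dg + 37.467)
  expect_equal(diff(prof@rows$prediction),
               rep(slope, nrow(prof@rows) - 1L), tolerance = 1e-9)
})

test_that("moving averages are centered means with documented defaults", {
  expect_equal(movingAverage(c(0, 10, 20), 3), c(NA, 10, NA))
  expect_equal(movingAverage(rep(7, 10), 5), c(NA, NA, rep(7, 6), NA, NA))
  expect_error(movingAverage(1:3, 4), "window")
  ctx <- toyContext(seed = 109, exonLen = 45, flankLen = 40)
  expect_identical(screenExon(ctx, 30)@window, 15L)
  expect_identical(screenExon(ctx, 25)@window, 13L)
  expect_identical(screenExon(ctx, 20)@window, 10L)
  prof <- screenExon(ctx, 30)
  expect_equal(prof@movingAvg[8], mean(prof@rows$prediction[1:15]))
  expect_true(all(is.na(prof@movingAvg[1:7])))
})

test_that("ranking is stable with documented tie-breaks", {
  rows <- data.frame(dfa = c(0L, 1L, 2L, 3L),
                     target_seq = c("AA", "CC", "GG", "TT"),
                     oligo_seq = c("TT", "GG", "CC", "AA"),
                     dg50 = c(-30, -20, -30, -10),
                     prediction = c(50, 80, 50, 20), clipped = FALSE,
                     stringsAsFactors = FALSE)
  prof <- new("ScreenProfile", exonId = "t", oligoLength = 2L,
              chemistry = "PMO", rows = rows,
              movingAvg = rep(NA_real_, 4), window = 1L,
              modelId = "m", backendId = "b")
  rk <- rankCandidates(prof)
  expect_identical(rk$dfa, c(1L, 0L, 2L, 3L))  # tie at 50 -> smaller dfa
  expect_identical(rk$rank, 1:4)
  expect_identical(nrow(rankCandidates(prof, topN = 2)), 2L)
  expect_identical(nrow(rankCandidates(prof, topN = 99)), 4L)
})

test_that("screen outputs round-trip losslessly and deterministically", {
  ctx <- toyContext(seed = 110, exonLen = 40, flankLen = 50, malueka = "A")
  prof <- screenExon(ctx, 30)
  pre1 <- tempfile(); pre2 <- tempfile()
  paths1 <- writeScreenOutputs(prof, pre1, ctx = ctx)
  paths2 <- writeScreenOutputs(screenExon(ctx, 30), pre2, ctx = ctx)
  expect_true(all(file.exists(paths1)))
  # re-running the screen writes byte-identical outputs
  for (k in 1:3)
    expect_identical(readLines(paths1[k]), readLines(paths2[k]))
  # sequences file numbers positions from 0 and carries the flanked target
  seqs <- read.delim(paths1[1], skip = 1)
  expect_identical(seqs$dfa[1], 0L)
  expect_identical(nrow(seqs), 11L)
  site1 <- enumerateTargetSites(ctx, 30)[[1]]
  expect_identical(seqs$target_flanked[1],
                   flankedRegion(ctx, site1, "f50")@sequence)
  energies <- read.delim(paths1[2], skip = 1)
  expect_equal(energies$dg50, prof@rows$dg50)
  # report reloads into an identical profile
  back <- readScreenReport(paths1[3])
  expect_identical(back@rows, prof@rows)
  expect_equal(back@movingAvg, prof@movingAvg)
  expect_identical(back@window, prof@window)
  expect_identical(back@modelId, prof@modelId)
  expect_identical(back@exonId, prof@exonId)
})

test_that("the 2'OMe screening path uses the logistic model", {
  ctx <- toyContext(seed = 111, exonLen = 40, flankLen = 50)
  ome <- omeCoefficients(c(intercept = -1, coef_dg50 = -0.1, coef_dist = -0.05,
                           coef_cross = 0, coef_length_gt22 = 0.5))
  prof <- screenExon(ctx, 25, chemistry = "2OMe", coeffs = ome)
  expect_true(all(prof@rows$prediction >= 0 & prof@rows$prediction <= 1))
  r <- prof@rows[4, ]
  expect_equal(r$prediction,
               omeGoodProbability(list(dg50 = r$dg50, dfa = r$dfa,
                                       length_gt22 = TRUE), ome))
  # chemistry/link mismatches are rejected
  expect_error(screenExon(ctx, 25, chemistry = "2OMe"), "logit")
  expect_error(screenExon(ctx, 25, coeffs = ome), "identity|least squares")
})

test_that("the command-line screen wrapper runs end to end", {
  fa <- tempfile(fileext = ".fa")
  ann <- tempfile()
  ctx <- toyContext(seed = 112, exonLen = 40, flankLen = 50)
  writeExonFasta(list(ctx), fa)
  writeLines("toy\tC", ann)
  script <- system.file("scripts", "screen_exons.R", package = "skipAO")
  out <- tempfile()
  status <- system2("Rscript",
                    c(script, "--fasta", fa, "--flank5", "50", "--flank3",
                      "50", "--exon", "toy", "--length", "30", "--backend",
                      "simple", "--annotations", ann, "--out", out),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  report <- paste0(out, "_toy_report.tsv")
  expect_true(file.exists(report))
  prof <- readScreenReport(report)
  expect_identical(nrow(prof@rows), 11L)
  # prediction agrees with an in-process screen under the C annotation
  ctxC <- ExonContext("toy", exonSeq(ctx), flank5(ctx), flank3(ctx), "C")
  expect_equal(prof@rows$prediction, screenExon(ctxC, 30)@rows$prediction)
  # a missing exon id fails with nonzero status
  bad <- system2("Rscript", c(script, "--fasta", fa, "--exon", "nope",
                              "--flank5", "50", "--flank3", "50"),
                 stdout = FALSE, stderr = FALSE)
  expect_gt(bad, 0L)
})
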