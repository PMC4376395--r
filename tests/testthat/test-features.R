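test_that("NI scores sum the overlapping hexamer windows", {
  const <- synthHexamerTable(constant = 1)
  ni <- niScores(randomDNA(20), const)
  expect_equal(ni[["ni_cumulative"]], 15)       # L - 5 windows
  expect_equal(ni[["ni_per_base"]], 0.75)
  tab <- synthHexamerTable(seed = 5)
  seq6 <- "ACGTAC"
  expect_equal(niScores(seq6, tab)[["ni_cumulative"]],
               unname(tab[seq6]))
  # brute-force recomputation by explicit substring extraction
  set.seed(41)
  for (i in 1:10) {
    s <- randomDNA(12)
    brute <- sum(vapply(1:7, function(j) tab[[substr(s, j, j + 5)]], 0))
    expect_equal(niScores(s, tab)[["ni_cumulative"]], brute)
    expect_equal(niScores(s, tab)[["ni_per_base"]], brute / 12)
  }
  expect_error(niScores("ACGTA", tab), "at least 6")
  expect_error(niScores("ACGTAC", tab[-1]), "4096")
})

test_that("NI cumulative scores decompose additively over a split", {
  tab <- synthHexamerTable(seed = 6)
  set.seed(42)
  for (i in 1:5) {
    s <- randomDNA(24)
    k <- sample(7:17, 1)
    whole <- niScores(s, tab)[["ni_cumulative"]]
    left <- niScores(substr(s, 1, k + 5), tab)[["ni_cumulative"]]
    right <- niScores(substr(s, k - 4, 24), tab)[["ni_cumulative"]]
    # windows starting in (k-4)..k are counted by both extended halves
    dup <- niScores(substr(s, k - 4, k + 5), tab)[["ni_cumulative"]]
    expect_equal(whole, left + right - dup)
  }
})

test_that("motif hexamer counting matches a brute-force recount", {
  expect_identical(countMotifHexamers(randomDNA(20), character()), 0L)
  expect_identical(countMotifHexamers(strrep("A", 8), "AAAAAA"), 3L)
  set.seed(43)
  motifs <- unique(vapply(1:10, function(i) randomDNA(6), ""))
  for (i in 1:5) {
    s <- randomDNA(30)
    brute <- sum(vapply(1:25, function(j) substr(s, j, j + 5) %in% motifs,
                        NA))
    expect_identical(countMotifHexamers(s, motifs), as.integer(brute))
  }
})

test_that("GC percentage is exact and reverse-complement invariant", {
  expect_equal(gcPercent("GGCC"), 100)
  expect_equal(gcPercent("AATT"), 0)
  expect_equal(gcPercent("ACGT"), 50)
  expect_error(gcPercent(""), "empty")
  set.seed(44)
  for (i in 1:10) {
    s <- randomDNA(17)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gcPercent(s), gcPercent(rc))
  }
})

test_that("GC architecture descriptors follow their definitions", {
  ctx <- ExonContext("e", strrep("G", 60), flank5 = strrep("A", 200))
  site <- enumerateTargetSites(ctx, 20)[[5]]
  arch <- gcArchitecture(ctx, site)
  expect_equal(arch[["exon_gc"]], 100)
  expect_equal(arch[["intron_gc"]], 0)
  expect_equal(arch[["delta_gc"]], 100)
  # target composition equals exon composition -> no change from blocking
  expect_equal(arch[["delta_gc_change"]], 0)
  expect_false(attr(arch, "partial_intron"))

  # random exon: explicit string-slicing recomputation
  set.seed(45)
  ctx2 <- ExonContext("e2", randomDNA(80), flank5 = randomDNA(160))
  site2 <- enumerateTargetSites(ctx2, 25)[[30]]
  arch2 <- gcArchitecture(ctx2, site2)
  intron150 <- substr(flank5(ctx2), 11, 160)
  rest <- paste0(substr(exonSeq(ctx2), 1, 29), substr(exonSeq(ctx2), 55, 80))
  expect_equal(arch2[["intron_gc"]], gcPercent(intron150))
  expect_equal(arch2[["delta_gc_ignoring_target"]],
               gcPercent(rest) - gcPercent(intron150))
  expect_equal(arch2[["delta_gc_change"]],
               arch2[["delta_gc_ignoring_target"]] - arch2[["delta_gc"]])

  # degenerate cases
  whole <- enumerateTargetSites(ctx, 60)[[1]]
  expect_error(gcArchitecture(ctx, whole), "whole exon")
  short <- ExonContext("e3", strrep("ACGT", 10), flank5 = strrep("T", 40))
  expect_true(attr(gcArchitecture(short, enumerateTargetSites(short, 15)[[1]]),
                   "partial_intron"))
})

test_that("assembled descriptor vectors are consistent with direct calls", {
  ctx <- toyContext(seed = 105, exonLen = 50, flankLen = 60, malueka = "A")
  tab <- synthHexamerTable(seed = 9)
  motifs <- c("AAAAAA", "GGGGGG")
  site <- enumerateTargetSites(ctx, 30)[[1]]
  d <- assembleDescriptors(ctx, site, simpleBackend, hexamerTable = tab,
                           motifSet = motifs,
                           imported = list(L1 = 0.42, L3 = 7))
  expect_identical(d$dfa, 0L)
  expect_identical(d$dfd, nchar(exonSeq(ctx)) - 30L)
  expect_true(d$length_gt22)
  expect_identical(d$malueka, "A")
  # dg50 equals a direct binding-energy call on the same f50 region
  direct <- bindingEnergy(antisenseOligo(site), flankedRegion(ctx, site, "f50"),
                          simpleBackend)
  expect_equal(d$dg50, dG(direct))
  expect_equal(d$ni_per_base, niScores(site@targetSeq, tab)[["ni_per_base"]])
  expect_equal(d$L1, 0.42)
  prov <- attr(d, "provenance")
  expect_identical(unname(prov["L1"]), "imported")
  expect_identical(unname(prov["dg50"]), "computed")

  site20 <- enumerateTargetSites(ctx, 20)[[3]]
  d20 <- assembleDescriptors(ctx, site20, simpleBackend,
                             computeAccessibility = FALSE)
  expect_false(d20$length_gt22)
  expect_true(is.na(d20$acc_target))
  expect_identical(unname(attr(d20, "provenance")["acc_target"]), "missing")
})

test_that("descriptor rows survive a write/load round trip exactly", {
  ctx <- toyContext(seed = 106, exonLen = 45, flankLen = 50)
  site <- enumerateTargetSites(ctx, 25)[[7]]
  d <- assembleDescriptors(ctx, site, simpleBackend,
                           computeAccessibility = FALSE)
  d$study <- "Synthetic"; d$exon <- exonId(ctx); d$oligo_name <- "o1"
  d$chemistry <- "PMO"; d$sequence <- antisenseOligo(site)@sequence
  d$observed_skip_pct <- 12.345678901234567
  f <- tempfile(fileext = ".tsv")
  writeCompiledDataset(d, f)
  back <- loadCompiledDataset(f, quiet = TRUE)
  for (nm in c("dfa", "dfd", "acp", "dg50", "dg200", "gc_oligo",
               "observed_skip_pct"))
    expect_identical(back[[nm]], d[[nm]], label = nm)
})

test_that("hexamer tables read back from disk", {
  tab <- synthHexamerTable(seed = 10)
  f <- tempfile(fileext = ".tsv")
  writeHexamerTable(tab, f)
  back <- readHexamerTable(f)
  expect_identical(length(back), 4096L)
  expect_equal(back[names(tab)], tab, tolerance = 1e-15)
})
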