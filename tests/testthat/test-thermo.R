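test_that("duplex energy equals the hand-summed nearest-neighbor value", {
  # frozen references computed by evaluating the fully paired duplex with
  # RNAeval -d0 (full Turner set, no dangles): init 4.10 + stacks + term AU
  expect_equal(dG(duplexEnergy("CCCCCCCCCC", "GGGGGGGGGG")), -25.6)
  expect_equal(dG(duplexEnergy("AAAAAAAAAA", "TTTTTTTTTT")), -3.0)
  # independent per-position summation on random duplexes
  set.seed(11)
  for (i in 1:20) {
    target <- randomDNA(sample(8:20, 1))
    oligo <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(target)))
    expect_equal(dG(duplexEnergy(oligo, target)),
                 handDuplexEnergy(rnaSequence(oligo), rnaSequence(target)))
  }
})

test_that("duplex energy agrees with external RNAeval on the same structure", {
  set.seed(12)
  vb <- ViennaRNABackend(dangles = 0L)
  for (i in 1:5) {
    target <- randomDNA(12)
    oligo <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(target)))
    expect_equal(dG(duplexEnergy(oligo, target)),
                 dG(duplexEnergy(oligo, target, backend = vb)),
                 tolerance = 1e-6)
  }
})

test_that("non-complementary duplexes are rejected with offending positions", {
  expect_error(duplexEnergy("GGGGGGGGGG", "GGGGGGGGGG"),
               "not complementary.*position")
  expect_error(duplexEnergy("CCCCC", "GGGG"), "lengths differ")
  # wobble only when enabled: G opposite U
  expect_error(duplexEnergy("GCCCC", "GGGGU"), "not complementary")
  expect_silent(duplexEnergy("GCCCC", "GGGGU", allowWobble = TRUE))
})

test_that("GC duplexes bind more strongly than AU duplexes", {
  gc <- dG(duplexEnergy(strrep("C", 12), strrep("G", 12)))
  au <- dG(duplexEnergy(strrep("U", 12), strrep("A", 12)))
  expect_lt(gc, au)
})

test_that("binding energy is complex minus both monomers", {
  # all-A region cannot self-pair and all-U oligo cannot either, so the
  # binding dG is exactly the complex energy
  region <- new("FlankedRegion", sequence = strrep("A", 20),
                targetOffset = 0L, targetLength = 20L, flankMode = "none",
                clipped = FALSE)
  res <- bindingEnergy(strrep("T", 20), region, simpleBackend)
  expect_equal(res@components$monomer_region, 0)
  expect_equal(res@components$monomer_oligo, 0)
  expect_equal(dG(res), res@components$complex)
  expect_lt(dG(res), 0)
  # targetOnlyReference drops the oligo monomer term
  res2 <- bindingEnergy(strrep("T", 20), region, simpleBackend,
                        targetOnlyReference = TRUE)
  expect_equal(dG(res2), res@components$complex - res@components$monomer_region)
})

test_that("binding energy matches exhaustive enumeration on a structured region", {
  # hairpin-forming 20-nt region, complementary 8-mer oligo at its 3' end
  region_seq <- "GGGGAAAACCCCAUGCAUGC"
  oligo <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", substr(region_seq, 13, 20)))))
  region <- new("FlankedRegion", sequence = chartr("U", "T", region_seq),
                targetOffset = 12L, targetLength = 8L, flankMode = "none",
                clipped = FALSE)
  got <- dG(bindingEnergy(oligo, region, simpleBackend))
  want <- oracleMinEnergy(oligo, region_seq) -
    oracleMinEnergy(region_seq) - oracleMinEnergy(oligo)
  expect_equal(got, want)
})

test_that("cofold energy is symmetric in its strands", {
  set.seed(13)
  for (i in 1:10) {
    a <- randomRNA(sample(8:16, 1))
    b <- randomRNA(sample(8:16, 1))
    expect_equal(cofoldEnergy(simpleBackend, a, b),
                 cofoldEnergy(simpleBackend, b, a))
  }
})

test_that("dG suite covers all flank modes and collapses under clipping", {
  ctx <- toyContext(exonLen = 40, flankLen = 30)
  site <- enumerateTargetSites(ctx, 20)[[10]]
  suite <- dgSuite(ctx, site, simpleBackend)
  expect_named(suite, c("dg_target", "dg50", "dg100", "dg200", "dg_et10"))
  # flanks of 30 clip f50/f100/f200 to the same window -> identical energies
  expect_equal(dG(suite$dg50), dG(suite$dg100))
  expect_equal(dG(suite$dg100), dG(suite$dg200))
  # determinism: same inputs give bit-identical results
  expect_identical(dG(suite$dg50), dG(dgSuite(ctx, site, simpleBackend)$dg50))
})

test_that("duplex energy of enumerated sites >= 15 nt is negative", {
  ctx <- toyContext(seed = 104, exonLen = 60, flankLen = 0)
  for (site in enumerateTargetSites(ctx, 15)[seq(1, 46, by = 9)]) {
    oligo <- antisenseOligo(site)
    expect_lte(dG(duplexEnergy(oligo, site@targetSeq)), 0)
  }
})

test_that("lengthening an oligo never weakens the bare duplex energy", {
  set.seed(14)
  target <- randomDNA(30)
  dgs <- vapply(15:30, function(L) {
    sub <- substr(target, 1, L)
    oligo <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sub)))
    dG(duplexEnergy(oligo, sub))
  }, 0)
  expect_true(all(diff(dgs) <= 1e-12))
})

test_that("ViennaRNA backend parses fold and cofold energies", {
  vb <- ViennaRNABackend()
  e <- foldEnergy(vb, "GGGGAAAACCCCAAAGGGAAACCC")
  expect_true(is.finite(e) && e < 0)
  expect_equal(cofoldEnergy(vb, "GGGGG", "CCCCC"),
               cofoldEnergy(vb, "CCCCC", "GGGGG"))
  # N bases are rejected before reaching any backend
  region <- new("FlankedRegion", sequence = "ANAAAAAAAA", targetOffset = 0L,
                targetLength = 10L, flankMode = "none", clipped = FALSE)
  expect_error(bindingEnergy(strrep("T", 10), region, simpleBackend), "N")
})
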