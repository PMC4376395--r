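# Shared fixture helpers: everything is generated in code, no stored data.

randomRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                               collapse = "")
randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# a small deterministic exon context with real sequence variety
toyContext <- function(seed = 101, exonLen = 40, flankLen = 60,
                       malueka = "C") {
  set.seed(seed)
  ExonContext("toy", randomDNA(exonLen), randomDNA(flankLen),
              randomDNA(flankLen), maluekaCategory = malueka)
}

simpleBackend <- SimpleNNBackend()

# hand re-implementation of the nearest-neighbor duplex sum, reading the
# stack table through explicit per-position lookups (test-side oracle)
handDuplexEnergy <- function(oligoRNA, targetRNA) {
  st <- stackTable()
  types <- c("CG", "GC", "GU", "UG", "AU", "UA")
  pt <- function(a, b) match(paste0(a, b), types)
  o <- strsplit(oligoRNA, "")[[1]]
  t <- strsplit(targetRNA, "")[[1]]
  L <- length(o)
  s <- 0
  for (k in seq_len(L - 1)) {
    s <- s + st[pt(o[k], t[L + 1 - k]), pt(t[L - k], o[k + 1])]
  }
  termAU <- sum(c(pt(o[1], t[L]), pt(o[L], t[1])) >= 3) * 0.50
  4.10 + s + termAU
}
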