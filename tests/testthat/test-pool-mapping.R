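# a hand-built pool pair around the fixture model's plus-strand gene: the
# causative record sits at a known missense position inside its CDS
fxPoolPair <- function(extraTsp = NULL, wtPoolRec = NULL) {
  m <- fxModel()
  cds <- cdsSequence(getGene(m, "plusGene"), m)
  hit <- NULL
  for (cdsPos in 4:297) {
    refNt <- substr(cds, cdsPos, cdsPos)
    codon <- ceiling(cdsPos / 3)
    refCodon <- substr(cds, (codon - 1) * 3 + 1, codon * 3)
    for (alt in setdiff(c("A", "C", "G", "T"), refNt)) {
      altCodon <- refCodon
      off <- cdsPos - (codon - 1) * 3
      substr(altCodon, off, off) <- alt
      if (Biostrings::GENETIC_CODE[[altCodon]] !=
            Biostrings::GENETIC_CODE[[refCodon]] &&
          Biostrings::GENETIC_CODE[[altCodon]] != "*") {
        hit <- vrec("chr01", 1000L + cdsPos, refNt, alt, 100, "tsp_pool")
        break
      }
    }
    if (!is.null(hit)) break
  }
  tsp <- rbind(hit, extraTsp)
  list(model = m, causative = hit,
       pp = PoolPair(VariantTable(tsp),
                     if (is.null(wtPoolRec)) VariantTable()
                     else VariantTable(wtPoolRec),
                     wtRefs = list()))
}

test_that("the pool causal filter keeps a planted 100% causative variant", {
  fx <- fxPoolPair()
  out <- poolCausalFilter(fx$pp, fx$model)
  expect_identical(matchKey(out), matchKey(fx$causative))
})

test_that("presence in the phenotype-negative pool disqualifies at any frequency", {
  base <- fxPoolPair()
  wtRec <- base$causative          # same key, low frequency, other pool
  wtRec$frequency <- 40; wtRec$source <- "wt_pool"
  fx <- fxPoolPair(wtPoolRec = wtRec)
  out <- poolCausalFilter(fx$pp, fx$model)
  expect_identical(nrow(variantRecords(out)), 0L)
})

test_that("sub-cutoff phenotype-positive records are removed", {
  m <- fxModel()
  low <- vrec("chr01", 1100, "N", "N", 75, "tsp_pool")
  # use a real genome base so the record is well-formed
  refNt <- as.character(Biostrings::extractAt(
    genomeSequences(m)[["chr01"]], IRanges::IRanges(1100, 1100)))
  low$ref <- refNt; low$alt <- setdiff(c("A", "C", "G", "T"), refNt)[1]
  pp <- PoolPair(VariantTable(low), VariantTable(), wtRefs = list())
  expect_identical(nrow(variantRecords(poolCausalFilter(pp, m))), 0L)
})

test_that("causative recall under read-level noise stays near one", {
  m <- fxBreedingModel()
  mut <- fxMutant(m)
  set.seed(71)
  sp <- spawnStrains(m, nOutcrossSnps = 500)
  oc <- sp$outcross
  pools <- runOutcrossPools(mut, oc, 25, m)
  sites <- segregatingSites(c(pools$tspPool, pools$wtPool))
  cfg <- SimConfig(meanCoverage = 30, baseErrorRate = 0.01)
  key <- causativeSite(mut)
  nRep <- 500
  recalled <- logical(nRep)
  for (i in seq_len(nRep)) {
    tspT <- simulatePoolSequencing(pools$tspPool, m, cfg, sites = sites,
                                   source = "tsp_pool")
    wtT <- simulatePoolSequencing(pools$wtPool, m, cfg, sites = sites,
                                  source = "wt_pool")
    bgT <- simulatePoolSequencing(list(sp$background), m, cfg,
                                  source = "background_wt")
    ocT <- simulatePoolSequencing(list(oc), m, cfg, source = "outcross_wt")
    out <- poolCausalFilter(PoolPair(tspT, wtT, list(bgT, ocT)), m)
    recalled[i] <- key %in% matchKey(out)
  }
  expect_gte(mean(recalled), 0.99)
})

test_that("frequency histogram fractions are coherent", {
  all100 <- VariantTable(vrec("chr01", 1:5, "A", "G", rep(100, 5)))
  h <- frequencyHistogram(all100)
  expect_identical(h$fractionAt100, 1)
  expect_identical(frequencyHistogram(all100, band = c(0, 100))$fractionInBand,
                   1)
  set.seed(72)
  vt <- VariantTable(randomVariantDf(200))
  h2 <- frequencyHistogram(vt)
  expect_true(all(diff(h2$cumulative$fraction) >= 0))
  expect_equal(h2$cumulative$fraction[nrow(h2$cumulative)], 1)
  for (x in c(10, 50, 90)) {
    below <- mean(variantRecords(vt)$frequency <= x)
    above <- mean(variantRecords(vt)$frequency > x)
    expect_equal(below + above, 1)
  }
  expect_error(frequencyHistogram(VariantTable()), "empty")
})
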