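mkTagged <- function(model, poolDf, bgDf = NULL, ocDf = NULL) {
  tagOrigin(VariantTable(poolDf),
            if (is.null(bgDf)) VariantTable() else VariantTable(bgDf, ""),
            if (is.null(ocDf)) VariantTable() else VariantTable(ocDf, ""))
}

test_that("origin tagging is a partition decided by panel membership", {
  m <- fxModel()
  pool <- rbind(vrec("chr01", 100, "A", "G", 95, "pool"),
                vrec("chr01", 200, "C", "T", 50, "pool"),
                vrec("chr01", 300, "G", "A", 99, "pool"))
  bg <- vrec("chr01", 100, "A", "G", 100, "bg")
  oc <- vrec("chr01", 200, "C", "T", 100, "oc")
  tagged <- mkTagged(m, pool, bg, oc)
  expect_identical(tagged$origin, c("background_wt", "outcross_wt", "novel"))
  expect_true(all(table(tagged$key) == 1))
  # contamination: one key in both panels
  expect_error(mkTagged(m, pool, bg, rbind(oc, transform(bg, source = "oc"))),
               "contamination")
})

test_that("clean flanks measure the outcross-SNP-free region", {
  m <- fxBreedingModel()  # chromosomes of 5 Mbp
  pool <- rbind(vrec("chr01", 3000000, "A", "G", 100, "pool"),   # candidate
                vrec("chr01", 2000000, "C", "T", 50, "pool"),    # oc left
                vrec("chr01", 4999000, "G", "A", 50, "pool"),    # oc right
                vrec("chr02", 1000000, "T", "C", 100, "pool"))   # no oc SNPs
  oc <- rbind(vrec("chr01", 2000000, "C", "T", 100, "oc"),
              vrec("chr01", 4999000, "G", "A", 100, "oc"))
  tagged <- cleanFlanks(mkTagged(m, pool, NULL, oc), m)
  cand <- tagged[tagged$key == "chr01:3000000:A:G", ]
  expect_equal(cand$leftFlank, 1e6)
  expect_equal(cand$rightFlank, 1999000)
  expect_equal(cand$regionSize, 2999000)
  lone <- tagged[tagged$chrom == "chr02", ]
  expect_equal(lone$regionSize, 5e6)          # whole chromosome is clean
  expect_equal(lone$leftFlank, 1e6)           # through position 1
  expect_equal(lone$rightFlank, 4e6)          # to the chromosome end
  # flanks never exceed chromosome bounds
  expect_true(all(tagged$leftFlank <= tagged$pos))
  expect_true(all(tagged$rightFlank <=
                    chromLengths(m)[tagged$chrom] - tagged$pos))
  one <- cleanFlank("chr01:3000000:A:G", mkTagged(m, pool, NULL, oc), m)
  expect_equal(one$regionSize, 2999000)
})

test_that("candidates rank by clean region then frequency, deterministically", {
  m <- fxBreedingModel()
  pool <- rbind(vrec("chr01", 1000000, "A", "G", 100, "pool"),
                vrec("chr01", 1200000, "C", "T", 88, "pool"))
  tagged <- cleanFlanks(mkTagged(m, pool), m)
  # both clean regions span the whole chromosome: frequency decides
  rep <- rankCandidates(tagged)
  expect_identical(candidates(rep)$frequency, c(100, 88))
  expect_identical(candidates(rep)$rank, 1:2)
  # a larger clean region beats a higher frequency; the outcross SNPs are
  # part of the pool's call list (as inherited S1D2 markers would be) and
  # of the outcross panel
  oc <- rbind(vrec("chr01", 990000, "G", "C", 100, "oc"),
              vrec("chr01", 1010000, "T", "A", 100, "oc"))
  ocInPool <- transform(oc, frequency = 50, source = "pool")
  tagged2 <- cleanFlanks(mkTagged(m, rbind(pool, ocInPool), NULL, oc), m)
  rep2 <- rankCandidates(tagged2)
  expect_identical(candidates(rep2)$pos[1], 1200000L)
  # single candidate ranks first; zero novel candidates is an error
  single <- cleanFlanks(mkTagged(m, pool[1, ]), m)
  expect_identical(candidates(rankCandidates(single))$rank, 1L)
  onlyOc <- mkTagged(m, pool[1, ], NULL,
                     transform(pool[1, ], source = "oc"))
  expect_error(rankCandidates(onlyOc), "no novel")
})

test_that("the causative variant's clean region dominates unlinked novel variants", {
  m <- fxBreedingModel()
  mut <- fxMutant(m)
  key <- causativeSite(mut)
  set.seed(81)
  wins <- replicate(200, {
    sp <- spawnStrains(m, nOutcrossSnps = 1000)
    pools <- runOutcrossPools(mut, sp$outcross, 25, m)
    tsp <- alleleFrequencyTable(pools$tspPool, source = "tsp_pool")
    tagged <- cleanFlanks(tagOrigin(tsp, strainPanelTable(sp$background),
                                    strainPanelTable(sp$outcross)), m)
    causRegion <- tagged$regionSize[tagged$key == key]
    ocRegions <- tagged$regionSize[tagged$origin == "outcross_wt"]
    causRegion > stats::median(ocRegions)
  })
  expect_gte(mean(wins), 0.95)
})
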