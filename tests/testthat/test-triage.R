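test_that("the frequency cutoff keeps strictly-over-cutoff records", {
  vt <- VariantTable(vrec("chr01", c(1, 2, 3, 4), "A", "G",
                          c(100, 88, 79, 50)))
  kept <- variantRecords(frequencyFilter(vt, TriageConfig(80)))
  expect_equal(sort(kept$frequency, decreasing = TRUE), c(100, 88))
  at80 <- VariantTable(vrec("chr01", 1, "A", "G", 80))
  expect_identical(nrow(variantRecords(frequencyFilter(at80))), 0L)
  expect_identical(nrow(variantRecords(
    frequencyFilter(at80, TriageConfig(80, keepAtCutoff = TRUE)))), 1L)
  expect_equal(variantRecords(frequencyFilter(vt, TriageConfig(0))),
               variantRecords(vt))
})

test_that("filters agree with brute-force oracles on random tables", {
  set.seed(55)
  for (i in 1:1000) {
    df <- randomVariantDf(sample(0:40, 1))
    refDf <- randomVariantDf(sample(0:40, 1), source = "r")
    cutoff <- runif(1, 0, 100)
    vt <- VariantTable(df); ref <- VariantTable(refDf)

    got <- variantRecords(frequencyFilter(vt, TriageConfig(cutoff)))
    oracle <- variantRecords(vt)[variantRecords(vt)$frequency > cutoff, ,
                                 drop = FALSE]
    rownames(oracle) <- NULL
    expect_equal(got, oracle)

    got2 <- variantRecords(subtractVariants(vt, ref))
    dfS <- variantRecords(vt)
    inRef <- vapply(seq_len(nrow(dfS)), function(j) {
      any(variantRecords(ref)$chrom == dfS$chrom[j] &
          variantRecords(ref)$pos == dfS$pos[j] &
          variantRecords(ref)$ref == dfS$ref[j] &
          variantRecords(ref)$alt == dfS$alt[j])
    }, logical(1))
    oracle2 <- dfS[!inRef, , drop = FALSE]
    rownames(oracle2) <- NULL
    expect_equal(got2, oracle2)
  }
})

test_that("subtraction removes on presence at any reference frequency", {
  mutantRec <- VariantTable(vrec("chr01", 10, "C", "T", 100, "mut"))
  lowFreqRef <- VariantTable(vrec("chr01", 10, "C", "T", 40, "wt_pool"))
  expect_identical(nrow(variantRecords(
    subtractVariants(mutantRec, lowFreqRef))), 0L)
  expect_identical(nrow(variantRecords(
    subtractVariants(mutantRec, mutantRec))), 0L)
  expect_equal(variantRecords(subtractVariants(mutantRec, list())),
               variantRecords(mutantRec))
})

test_that("non-synonymous selection classifies coding consequences", {
  m <- fxModel()
  g <- getGene(m, "plusGene")  # CDS chr01:1001-1300, plus strand
  cds <- cdsSequence(g, m)
  # search the real CDS for one missense and one synonymous substitution
  findSub <- function(wantSame) {
    for (cdsPos in 4:297) {
      refNt <- substr(cds, cdsPos, cdsPos)
      codon <- ceiling(cdsPos / 3)
      refCodon <- substr(cds, (codon - 1) * 3 + 1, codon * 3)
      for (alt in setdiff(c("A", "C", "G", "T"), refNt)) {
        altCodon <- refCodon
        substr(altCodon, cdsPos - (codon - 1) * 3, cdsPos - (codon - 1) * 3) <- alt
        refAa <- Biostrings::GENETIC_CODE[[refCodon]]
        altAa <- Biostrings::GENETIC_CODE[[altCodon]]
        if (wantSame && altAa == refAa)
          return(list(gpos = 1000L + cdsPos, ref = refNt, alt = alt))
        if (!wantSame && altAa != refAa && altAa != "*")
          return(list(gpos = 1000L + cdsPos, ref = refNt, alt = alt))
      }
    }
    stop("no such substitution in fixture CDS")
  }
  mis <- findSub(FALSE); syn <- findSub(TRUE)
  refAt <- function(pos) as.character(Biostrings::extractAt(
    genomeSequences(m)[["chr01"]], IRanges::IRanges(pos, pos)))
  intergenicRef <- refAt(400000)
  tbl <- VariantTable(rbind(
    vrec("chr01", mis$gpos, mis$ref, mis$alt, 100),
    vrec("chr01", syn$gpos, syn$ref, syn$alt, 100),
    vrec("chr01", 400000, intergenicRef,
         setdiff(c("A", "C", "G", "T"), intergenicRef)[1], 100)))
  kept <- variantRecords(selectNonsynonymous(tbl, m))
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$pos, mis$gpos)
})

test_that("frameshift indels inside a CDS are kept", {
  m <- fxModel()
  refAt <- function(pos) as.character(Biostrings::extractAt(
    genomeSequences(m)[["chr01"]], IRanges::IRanges(pos, pos)))
  ins <- VariantTable(vrec("chr01", 1100, refAt(1100),
                           paste0(refAt(1100), "TT"), 100))
  expect_identical(nrow(variantRecords(selectNonsynonymous(ins, m))), 1L)
})

test_that("experiment intersection keeps commonly reported variants", {
  tA <- VariantTable(vrec("chr01", c(1, 2, 3), "A", "G", c(100, 90, 85), "A"))
  tB <- VariantTable(vrec("chr01", c(2, 4), "A", "G", c(50, 99), "B"))
  got <- variantRecords(intersectExperiments(list(tA, tB)))
  expect_identical(got$pos, 2L)
  expect_identical(got$frequency, 90)  # reported from the first table
  expect_identical(got$source, "A")
  tC <- VariantTable(vrec("chr02", 9, "C", "T", 70, "C"))
  expect_identical(nrow(variantRecords(
    intersectExperiments(list(tA, tC)))), 0L)
  # order-insensitive at key level
  ab <- matchKey(intersectExperiments(list(tA, tB)))
  ba <- matchKey(intersectExperiments(list(tB, tA)))
  expect_setequal(ab, ba)
  expect_error(intersectExperiments(list(tA)), "at least 2")
})

test_that("the cascade recovers the planted causative variant across replicates", {
  m <- fxBreedingModel()
  set.seed(66)
  cfg <- SimConfig(meanCoverage = 20, nMutations = 60)
  bg <- spawnStrains(m, 0)$background
  hits <- 0L
  nRep <- 60
  for (i in seq_len(nRep)) {
    mut <- mutagenize(bg, m, cfg@nMutations, "causal")
    bc <- runBackcrossScheme(mut, bg, 5, m)
    run <- function(strain, src) {
      tb <- simulatePoolSequencing(list(strain), m, cfg, source = src)
      wt <- simulatePoolSequencing(list(bg), m, cfg, source = "bg")
      selectNonsynonymous(subtractVariants(frequencyFilter(tb), wt), m)
    }
    surv <- intersectExperiments(list(run(mut, "mut"), run(bc, "bc5")))
    if (causativeSite(mut) %in% matchKey(surv)) hits <- hits + 1L
  }
  expect_identical(hits, as.integer(nRep))
})
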