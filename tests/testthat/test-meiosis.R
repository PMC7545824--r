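test_that("every inter-parental heterozygous site segregates exactly 2:2", {
  set.seed(41)
  for (rate in c(0, 3, 12)) {
    m <- buildGenomeModel(nChromosomes = 2, chromLength = 1e6,
                          nGenes = 2, geneLength = 300, mapRate = rate)
    sp <- spawnStrains(m, nOutcrossSnps = 40)
    for (rep in 1:5) {
      tet <- meiosisTetrad(sp$background, sp$outcross, m)
      prods <- tetradProducts(tet)
      for (key in alleles(sp$outcross)) {
        carried <- sum(vapply(prods, function(p) key %in% alleles(p),
                              logical(1)))
        expect_identical(carried, 2L)
      }
      # mating type is a Mendelian locus: 2:2 as well
      expect_identical(sum(vapply(prods, matingType,
                                  character(1)) == "+"), 2L)
    }
  }
})

test_that("sites carried by both parents are carried by all four products", {
  m <- fxBreedingModel()
  shared <- "chr01:4000000:A:G"
  p1 <- StrainGenome("p1", "+", alleles = shared)
  p2 <- StrainGenome("p2", "-", alleles = shared)
  tet <- meiosisTetrad(p1, p2, m, seed = 5)
  expect_true(all(vapply(tetradProducts(tet),
                         function(p) shared %in% alleles(p), logical(1))))
})

test_that("same mating types cannot cross", {
  m <- fxBreedingModel()
  a <- StrainGenome("a", "+")
  b <- StrainGenome("b", "+")
  expect_error(meiosisTetrad(a, b, m), "opposite mating types")
})

test_that("recombinant gamete frequency follows the Haldane map", {
  m <- fxBreedingModel()  # 6 cM/Mbp
  keyA <- "chr01:100000:A:G"
  for (dist in c(1e6, 3e6)) {
    keyB <- sprintf("chr01:%d:C:T", 100000 + as.integer(dist))
    p1 <- StrainGenome("p1", "+", alleles = c(keyA, keyB))
    p2 <- StrainGenome("p2", "-")
    set.seed(40 + dist / 1e6)
    nTet <- 2000
    recomb <- 0L
    for (i in seq_len(nTet)) {
      for (p in tetradProducts(meiosisTetrad(p1, p2, m))) {
        hasA <- keyA %in% alleles(p); hasB <- keyB %in% alleles(p)
        if (xor(hasA, hasB)) recomb <- recomb + 1L
      }
    }
    cHat <- recomb / (4 * nTet)
    cTrue <- recombinationFraction(m, dist)
    se <- sqrt(cTrue * (1 - cTrue) / (4 * nTet))
    expect_lt(abs(cHat - cTrue), 3 * se)
  }
})

test_that("chromosomes assort independently across the tetrad", {
  m <- fxBreedingModel()
  keyA <- "chr01:100000:A:G"
  keyB <- "chr02:100000:C:T"
  p1 <- StrainGenome("p1", "+", alleles = c(keyA, keyB))
  p2 <- StrainGenome("p2", "-")
  set.seed(43)
  together <- replicate(800, {
    p <- tetradProducts(meiosisTetrad(p1, p2, m))[[1L]]
    (keyA %in% alleles(p)) == (keyB %in% alleles(p))
  })
  expect_lt(abs(mean(together) - 0.5), 3 * sqrt(0.25 / 800))
})

test_that("backcross scheme keeps the causative site and purges unlinked ones", {
  m <- fxBreedingModel()
  mut <- fxMutant(m)
  bg <- spawnStrains(m, 0)$background
  expect_error(runBackcrossScheme(mut, bg, -1, m), ">= 0")
  expect_identical(runBackcrossScheme(mut, bg, 0, m, seed = 1), mut)
  unlinked <- "chr02:1000000:A:C"
  mut2 <- carryAllele(mut, unlinked)
  set.seed(44)
  nRep <- 1000; g <- 3
  kept <- logical(nRep)
  for (i in seq_len(nRep)) {
    fin <- runBackcrossScheme(mut2, bg, g, m)
    expect_identical(causativeSite(fin), causativeSite(mut2))
    kept[i] <- unlinked %in% alleles(fin)
  }
  p0 <- 2^-g
  expect_lt(abs(mean(kept) - p0), 3 * sqrt(p0 * (1 - p0) / nRep))
})

test_that("outcross pooling keeps complete tetrads and splits by phenotype", {
  m <- fxBreedingModel()
  mut <- fxMutant(m)
  oc <- StrainGenome("oc", "-", alleles = "chr01:3000000:G:A")
  for (nTet in c(15, 25)) {
    pools <- runOutcrossPools(mut, oc, nTet, m, seed = nTet)
    expect_length(pools$tspPool, 2 * nTet)
    expect_length(pools$wtPool, 2 * nTet)
    expect_length(pools$tetrads, nTet)
    expect_true(all(vapply(pools$tspPool, function(p)
      !is.na(causativeSite(p)), logical(1))))
    expect_true(all(vapply(pools$wtPool, function(p)
      is.na(causativeSite(p)), logical(1))))
  }
  expect_error(runOutcrossPools(mut, oc, 0, m), ">= 1")
})

test_that("a fixed seed fixes every product of a meiosis", {
  m <- fxBreedingModel()
  mut <- fxMutant(m)
  oc <- StrainGenome("oc", "-", alleles = "chr02:2000000:G:A")
  t1 <- meiosisTetrad(mut, oc, m, seed = 77)
  t2 <- meiosisTetrad(mut, oc, m, seed = 77)
  for (k in 1:4) {
    expect_identical(alleles(tetradProducts(t1)[[k]]),
                     alleles(tetradProducts(t2)[[k]]))
    expect_identical(matingType(tetradProducts(t1)[[k]]),
                     matingType(tetradProducts(t2)[[k]]))
  }
})
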