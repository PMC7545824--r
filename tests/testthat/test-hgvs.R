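test_that("coding-change descriptors parse and round-trip", {
  cc <- parseHgvsC("c.479C>T")
  expect_identical(c(cc@cdsStart, cc@cdsEnd), c(479L, 479L))
  expect_identical(c(cc@refNt, cc@altNt), c("C", "T"))
  mnp <- parseHgvsC("c.2044_2045delCCinsTT")
  expect_identical(c(mnp@cdsStart, mnp@cdsEnd), c(2044L, 2045L))
  expect_identical(c(mnp@refNt, mnp@altNt), c("CC", "TT"))
  for (txt in c("c.479C>T", "c.302C>A", "c.2044_2045delCCinsTT",
                "c.10_12delACGinsTTT"))
    expect_identical(formatHgvsC(parseHgvsC(txt)), txt)
  expect_error(parseHgvsC("c.479+2T>A"), "unsupported")
  expect_error(parseHgvsC("p.Pro160Leu"), "not a coding-sequence")
  expect_error(parseHgvsC("c.10_12delACinsTT"), "span")
  expect_error(parseHgvsC("c.10dupA"), "token")
})

# a CDS carrying proline (CCT) at chosen codons and alanine elsewhere
prolineCds <- function(nCodons, prolineAt) {
  codons <- rep("GCA", nCodons)
  codons[prolineAt] <- "CCT"
  paste(codons, collapse = "")
}

test_that("published coding changes give the published residue changes", {
  # MNP in codon 682: CCT -> TTT, Pro -> Phe
  pc1 <- applyCodingChange(prolineCds(700, 682),
                           parseHgvsC("c.2044_2045delCCinsTT"))
  expect_identical(c(pc1@refAa, pc1@position, pc1@altAa),
                   c("P", 682L, "F"))
  expect_identical(pc1@consequence, "missense")
  # SNP in codon 160: CCT -> CTT, Pro -> Leu
  pc2 <- applyCodingChange(prolineCds(200, 160), parseHgvsC("c.479C>T"))
  expect_identical(c(pc2@refAa, pc2@position, pc2@altAa),
                   c("P", 160L, "L"))
  # SNP in codon 101: CCT -> CAT, Pro -> His
  pc3 <- applyCodingChange(prolineCds(150, 101), parseHgvsC("c.302C>A"))
  expect_identical(c(pc3@refAa, pc3@position, pc3@altAa),
                   c("P", 101L, "H"))
})

test_that("reference mismatches and bad CDS lengths are errors", {
  expect_error(applyCodingChange(prolineCds(200, 160),
                                 parseHgvsC("c.479G>T")),
               "mismatch")
  expect_error(applyCodingChange("ATGCC", parseHgvsC("c.2C>T")),
               "multiple of 3")
  expect_error(applyCodingChange("ATGTAA", parseHgvsC("c.100A>T")),
               "beyond")
})

test_that("consequence classes cover synonymous, nonsense and frameshift", {
  syn <- applyCodingChange("ATGCCTTAA",
                           CodingChange(6L, 6L, "T", "A"))  # CCT -> CCA
  expect_identical(syn@consequence, "synonymous")
  non <- applyCodingChange("ATGTGGTAA",
                           CodingChange(5L, 5L, "G", "A"))  # TGG -> TAG
  expect_identical(non@consequence, "nonsense")
  fs <- applyCodingChange("ATGCCTTAA", CodingChange(4L, 4L, "C", "CT"))
  expect_identical(fs@consequence, "frameshift")
  expect_identical(fs@altAa, "fs")
})

test_that("mature-protein numbering subtracts the transit peptide", {
  pc <- applyCodingChange(prolineCds(200, 160), parseHgvsC("c.479C>T"))
  mat <- toMature(pc, 31)
  expect_identical(mat@maturePosition, 129L)   # Pro129Leu in the mature protein
  expect_identical(toMature(pc, 0)@maturePosition, pc@position)
  small <- applyCodingChange(prolineCds(200, 20), parseHgvsC("c.59C>T"))
  expect_error(toMature(small, 31), "transit peptide")
})

test_that("genomic variants project onto the coding strand correctly", {
  m <- fxModel()
  minus <- getGene(m, "minusGene")   # chr02:2001-2300, minus strand
  plus <- getGene(m, "plusGene")
  seqs <- genomeSequences(m)
  # minus strand: genomic base at CDS position 10 is the complement
  gpos <- 2300 - 10 + 1
  gRef <- as.character(Biostrings::extractAt(seqs[["chr02"]],
                                             IRanges::IRanges(gpos, gpos)))
  gAlt <- setdiff(c("A", "C", "G", "T"), gRef)[1]
  cc <- genomicToCoding(list(chrom = "chr02", pos = gpos, ref = gRef,
                             alt = gAlt), minus, m)
  expect_identical(cc@cdsStart, 10L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(cc@refNt, unname(comp[gRef]))
  expect_identical(cc@altNt, unname(comp[gAlt]))
  # plus strand: alleles pass through unchanged
  gRefP <- as.character(Biostrings::extractAt(seqs[["chr01"]],
                                              IRanges::IRanges(1010, 1010)))
  gAltP <- setdiff(c("A", "C", "G", "T"), gRefP)[1]
  ccP <- genomicToCoding(list(chrom = "chr01", pos = 1010, ref = gRefP,
                              alt = gAltP), plus, m)
  expect_identical(ccP@cdsStart, 10L)
  expect_identical(ccP@refNt, gRefP)
  # outside the CDS: explicit no-coding-effect result
  gRefI <- as.character(Biostrings::extractAt(seqs[["chr01"]],
                                              IRanges::IRanges(50, 50)))
  expect_null(genomicToCoding(list(chrom = "chr01", pos = 50, ref = gRefI,
                                   alt = setdiff(c("A","C","G","T"), gRefI)[1]),
                              plus, m))
})

test_that("projection plus application equals the mutate-and-translate oracle", {
  m <- fxModel()
  seqs <- genomeSequences(m)
  genes <- list(getGene(m, "plusGene"), getGene(m, "minusGene"))
  set.seed(91)
  for (i in 1:1000) {
    g <- genes[[sample.int(2, 1)]]
    cdsLen <- sum(IRanges::width(g@cds))
    cdsPos <- sample.int(cdsLen, 1)
    # mutate one CDS base at the genomic level
    lo <- min(IRanges::start(g@cds)); hi <- max(IRanges::end(g@cds))
    gposAll <- lo:hi
    cdsMap <- TetradMap:::.genomicToCdsPos(g, gposAll)
    gpos <- gposAll[match(cdsPos, cdsMap)]
    gRef <- as.character(Biostrings::extractAt(seqs[[g@chrom]],
                                               IRanges::IRanges(gpos, gpos)))
    gAlt <- sample(setdiff(c("A", "C", "G", "T"), gRef), 1)
    v <- list(chrom = g@chrom, pos = gpos, ref = gRef, alt = gAlt)

    cc <- genomicToCoding(v, g, m)
    pc <- applyCodingChange(cdsSequence(g, m), cc)

    # oracle: rebuild the mutated chromosome, translate the whole protein
    mutSeqs <- as.character(seqs)
    substr(mutSeqs[[g@chrom]], gpos, gpos) <- gAlt
    mutModel <- Biostrings::DNAStringSet(mutSeqs)
    protBefore <- strsplit(TetradMap:::.translateNt(cdsSequence(g, seqs)),
                           "")[[1]]
    protAfter <- strsplit(TetradMap:::.translateNt(cdsSequence(g, mutModel)),
                          "")[[1]]
    changed <- which(protBefore != protAfter)
    if (pc@consequence == "synonymous") {
      expect_length(changed, 0)
    } else {
      expect_identical(changed, pc@position)
      expect_identical(protBefore[changed], pc@refAa)
      expect_identical(protAfter[changed], pc@altAa)
    }
    expect_identical(pc@position, as.integer(ceiling(cc@cdsStart / 3)))
  }
})
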