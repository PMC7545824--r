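#' Spawn the background and outcross wild-type strains
#'
#' Creates an isogenic pair (default) or a divergent pair of wild types.
#' The outcross strain carries exactly `nOutcrossSnps` private SNP alleles
#' placed uniformly along the genome — the dense private-SNP panel of an
#' S1D2-like divergent strain used as linkage markers.  Optionally the
#' background strain carries its own private panel relative to the
#' reference assembly (`nBackgroundSnps`; default 0, in which case the
#' background genotype equals the reference).  The two panels are disjoint.
#' The background strain is mating type `"+"`, the outcross strain `"-"`.
#'
#' @param model a [GenomeModel-class].
#' @param nOutcrossSnps number of private outcross-strain SNPs.
#' @param nBackgroundSnps number of private background-strain SNPs.
#' @param seed optional integer seed.
#' @param backgroundId,outcrossId strain labels.
#' @return list with elements `background` and `outcross`
#'   ([StrainGenome-class]).
#' @examples
#' m <- buildGenomeModel(nChromosomes = 1, chromLength = 1e5, nGenes = 2,
#'                       seed = 1)
#' sp <- spawnStrains(m, nOutcrossSnps = 20, seed = 2)
#' length(alleles(sp$outcross))
#' @export
spawnStrains <- function(model, nOutcrossSnps, nBackgroundSnps = 0L,
                         seed = NULL, backgroundId = "bg_wt",
                         outcrossId = "outcross_wt") {
  .seedIfGiven(seed)
  nOutcrossSnps <- as.integer(nOutcrossSnps)
  nBackgroundSnps <- as.integer(nBackgroundSnps)
  if (nOutcrossSnps < 0L || nBackgroundSnps < 0L)
    stop("SNP counts must be >= 0")
  lens <- chromLengths(model)
  total <- sum(as.numeric(lens))
  nTot <- nOutcrossSnps + nBackgroundSnps
  if (nTot > total)
    stop("requested more SNPs than the genome has positions")
  keys <- character(0)
  if (nTot > 0L) {
    off <- sample(total, nTot, replace = FALSE)
    cp <- .linearToChromPos(off, lens)
    ref <- .refBases(model, cp$chrom, cp$pos)
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    keys <- siteKey(cp$chrom, cp$pos, ref, alt)
  }
  ocKeys <- if (nOutcrossSnps) keys[seq_len(nOutcrossSnps)] else character(0)
  bgKeys <- if (nBackgroundSnps) keys[nOutcrossSnps + seq_len(nBackgroundSnps)]
            else character(0)
  list(background = StrainGenome(backgroundId, "+", alleles = bgKeys),
       outcross = StrainGenome(outcrossId, "-", alleles = ocKeys))
}

#' UV-style mutagenesis of a strain
#'
#' Adds `nMutations` point mutations to a strain: exactly one is a
#' non-synonymous (missense) change inside `causativeGene` and is recorded
#' as the strain's causative site; the remaining mutations are placed
#' uniformly along the genome.  With full penetrance, carrying the
#' causative site is the temperature-sensitive phenotype.
#'
#' @param strain the [StrainGenome-class] to mutagenize.
#' @param model a [GenomeModel-class].
#' @param nMutations total new mutations (>= 1; the causative one counts).
#' @param causativeGene id of the gene to receive the causative change.
#' @param seed optional integer seed.
#' @param mutantId label for the returned strain.
#' @return a mutagenized [StrainGenome-class] carrying `causativeSite`.
#' @export
mutagenize <- function(strain, model, nMutations, causativeGene,
                       seed = NULL,
                       mutantId = paste0(strainId(strain), "_mut")) {
  .seedIfGiven(seed)
  nMutations <- as.integer(nMutations)
  if (nMutations < 1L)
    stop("'nMutations' must be >= 1 (the causative change itself)")
  gene <- getGene(model, causativeGene)
  causKey <- .placeCausativeMissense(gene, model)

  keys <- causKey
  lens <- chromLengths(model)
  total <- sum(as.numeric(lens))
  usedPos <- c(strain@alleles, keys)
  usedPos <- paste(parseSiteKeys(usedPos)$chrom, parseSiteKeys(usedPos)$pos)
  nSilent <- nMutations - 1L
  while (nSilent > 0L) {
    off <- sample(total, nSilent, replace = FALSE)
    cp <- .linearToChromPos(off, lens)
    posId <- paste(cp$chrom, cp$pos)
    fresh <- !posId %in% usedPos & !duplicated(posId)
    cp <- cp[fresh, , drop = FALSE]
    if (nrow(cp)) {
      ref <- .refBases(model, cp$chrom, cp$pos)
      alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                    character(1), USE.NAMES = FALSE)
      keys <- c(keys, siteKey(cp$chrom, cp$pos, ref, alt))
      usedPos <- c(usedPos, paste(cp$chrom, cp$pos))
      nSilent <- nSilent - nrow(cp)
    }
  }
  StrainGenome(mutantId, matingType = strain@matingType,
               alleles = c(strain@alleles, keys), causativeSite = causKey)
}

# choose a random internal CDS position of `gene` where a single-base
# substitution yields a missense change, and return its genomic site key
.placeCausativeMissense <- function(gene, model) {
  cds <- cdsSequence(gene, model)
  nCodon <- nchar(cds) %/% 3L
  if (nCodon < 3L)
    stop("causative gene has no internal codon for a non-synonymous change")
  for (try in 1:500) {
    codon <- sample(2:(nCodon - 1L), 1L)
    within <- sample.int(3L, 1L)
    cdsPos <- (codon - 1L) * 3L + within
    refNt <- substr(cds, cdsPos, cdsPos)
    refCodon <- substr(cds, (codon - 1L) * 3L + 1L, codon * 3L)
    refAa <- Biostrings::GENETIC_CODE[[refCodon]]
    for (altNt in sample(setdiff(.BASES, refNt))) {
      altCodon <- refCodon
      substr(altCodon, within, within) <- altNt
      altAa <- Biostrings::GENETIC_CODE[[altCodon]]
      if (altAa != refAa && altAa != "*" && refAa != "*") {
        g <- .cdsPosToGenomic(gene, cdsPos)
        gRef <- if (gene@strand == "-") .revcomp(refNt) else refNt
        gAlt <- if (gene@strand == "-") .revcomp(altNt) else altNt
        return(siteKey(gene@chrom, g, gRef, gAlt))
      }
    }
  }
  stop(sprintf("no possible non-synonymous change found in gene '%s'",
               gene@id))
}

#' Add a carried allele to a strain
#'
#' Utility for planting marker variants at controlled positions (e.g. a
#' non-causative variant at a chosen map distance from the causative site).
#'
#' @param strain a [StrainGenome-class].
#' @param key site key `"chrom:pos:ref:alt"`.
#' @return the strain carrying the extra allele.
#' @export
carryAllele <- function(strain, key) {
  if (key %in% strain@alleles) return(strain)
  StrainGenome(strain@strainId, strain@matingType,
               alleles = c(strain@alleles, key),
               causativeSite = strain@causativeSite)
}

#' Allele panel of a strain as a VariantTable
#'
#' The strain's carried alleles as variant records at frequency 100%
#' (haploid, noise-free) — the allele-level SNP panel used for origin
#' tagging.
#'
#' @param strain a [StrainGenome-class].
#' @param source source label (default the strain id).
#' @return a [VariantTable-class].
#' @export
strainPanelTable <- function(strain, source = strainId(strain)) {
  ps <- parseSiteKeys(strain@alleles)
  VariantTable(data.frame(chrom = ps$chrom, pos = ps$pos, ref = ps$ref,
                          alt = ps$alt, frequency = rep(100, nrow(ps)),
                          source = rep(source, nrow(ps)),
                          stringsAsFactors = FALSE),
               provenance = sprintf("allele panel of strain %s",
                                    strain@strainId))
}
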