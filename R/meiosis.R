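#' Map distance and recombination fraction
#'
#' Under the uniform genetic map (cM/Mbp) and the Haldane no-interference
#' crossover model, two loci separated by `bp` base pairs have map distance
#' \eqn{d = \mathrm{mapRate} \cdot bp / 10^8} Morgans and recombination
#' fraction \eqn{c = (1 - e^{-2d})/2}.
#'
#' @param model a [GenomeModel-class].
#' @param bp physical distance in bp.
#' @return recombination fraction in `[0, 0.5)`.
#' @examples
#' m <- buildGenomeModel(1, 6e6, nGenes = 1, mapRate = 6, seed = 1)
#' recombinationFraction(m, 2e6)
#' @export
recombinationFraction <- function(model, bp) {
  d <- model@mapRate * bp / 1e8
  0.5 * (1 - exp(-2 * d))
}

#' @rdname recombinationFraction
#' @param cFrac target recombination fraction in `[0, 0.5)`.
#' @return `bpForRecombinationFraction`: the physical distance in bp at
#'   which the map gives recombination fraction `cFrac`.
#' @export
bpForRecombinationFraction <- function(model, cFrac) {
  if (cFrac < 0 || cFrac >= 0.5)
    stop("recombination fraction must lie in [0, 0.5)")
  if (model@mapRate == 0) stop("map rate is 0; no distance maps to c > 0")
  d <- -log(1 - 2 * cFrac) / 2
  d * 1e8 / model@mapRate
}

# one chromosome's 4-chromatid bundle: Poisson(2d) crossovers, each between
# a random non-sister pair; returns per-chromatid breakpoints and origins
# (1 = plus parent, 2 = minus parent)
.bundleCrossovers <- function(chromLen, dMorgans) {
  nCo <- rpois(1L, 2 * dMorgans)
  breaks <- rep(list(numeric(0)), 4L)
  origs <- list(1L, 1L, 2L, 2L)
  cur <- c(1L, 1L, 2L, 2L)
  if (nCo > 0L) {
    pos <- sort(runif(nCo, min = 1, max = chromLen))
    i <- sample.int(2L, nCo, replace = TRUE)        # chromatid of plus parent
    j <- sample.int(2L, nCo, replace = TRUE) + 2L   # chromatid of minus parent
    for (m in seq_len(nCo)) {
      a <- i[m]; b <- j[m]
      breaks[[a]] <- c(breaks[[a]], pos[m])
      breaks[[b]] <- c(breaks[[b]], pos[m])
      tmp <- cur[a]; cur[a] <- cur[b]; cur[b] <- tmp
      origs[[a]] <- c(origs[[a]], cur[a])
      origs[[b]] <- c(origs[[b]], cur[b])
    }
  }
  list(breaks = breaks, origs = origs)
}

#' Simulate one meiosis as a complete tetrad
#'
#' Forms the diploid of the two parents and returns the four haploid
#' products.  Per chromosome, crossovers are placed as a Poisson process on
#' the four-chromatid bundle with rate `2 d` (so each chromatid experiences
#' `d` Morgans; Haldane model, no crossover or chromatid interference);
#' each crossover involves one randomly chosen chromatid of each parent.
#' Every site heterozygous between the parents therefore segregates exactly
#' 2:2, and mating type segregates 2:2 through the mating-type locus.
#'
#' @param parentPlus the mating-type `"+"` parent ([StrainGenome-class]).
#' @param parentMinus the mating-type `"-"` parent.
#' @param model a [GenomeModel-class].
#' @param seed optional integer seed.
#' @param idPrefix prefix for product strain ids.
#' @return a [Tetrad-class].
#' @examples
#' m <- buildGenomeModel(1, 1e6, nGenes = 2, seed = 1)
#' sp <- spawnStrains(m, nOutcrossSnps = 10, seed = 2)
#' tet <- meiosisTetrad(sp$background, sp$outcross, m, seed = 3)
#' tet
#' @export
meiosisTetrad <- function(parentPlus, parentMinus, model, seed = NULL,
                          idPrefix = NULL) {
  if (matingType(parentPlus) == matingType(parentMinus))
    stop("parents must be of opposite mating types")
  if (matingType(parentPlus) != "+") {  # allow either argument order
    tmp <- parentPlus; parentPlus <- parentMinus; parentMinus <- tmp
  }
  .seedIfGiven(seed)
  if (is.null(idPrefix))
    idPrefix <- paste0(parentPlus@strainId, "x", parentMinus@strainId)

  keys <- union(parentPlus@alleles, parentMinus@alleles)
  sites <- parseSiteKeys(keys)
  inPlus <- sites$key %in% parentPlus@alleles
  inMinus <- sites$key %in% parentMinus@alleles

  lens <- chromLengths(model)
  nSites <- nrow(sites)
  # origin of every site in every product (columns = meiotic products)
  origin <- matrix(1L, nrow = nSites, ncol = 4L)
  mtOrigin <- rep(1L, 4L)
  for (cn in names(lens)) {
    onChrom <- which(sites$chrom == cn)
    isMt <- identical(cn, model@mtLocus$chrom)
    if (!length(onChrom) && !isMt) next
    d <- model@mapRate * as.numeric(lens[[cn]]) / 1e8
    bun <- .bundleCrossovers(lens[[cn]], d)
    # chromosomes assort independently: meiosis I sends one centromere pair
    # (sister chromatids 1,2 or 3,4; centromeres at the left end are never
    # exchanged) to each pole at random, meiosis II splits the sisters
    perm <- if (runif(1L) < 0.5) c(sample(1:2), sample(3:4))
            else c(sample(3:4), sample(1:2))
    for (k in 1:4) {
      brk <- bun$breaks[[perm[k]]]; org <- bun$origs[[perm[k]]]
      if (length(onChrom)) {
        idx <- findInterval(sites$pos[onChrom], brk)
        origin[onChrom, k] <- org[idx + 1L]
      }
      if (isMt)
        mtOrigin[k] <- org[findInterval(model@mtLocus$pos, brk) + 1L]
    }
  }

  causKeys <- stats::na.omit(c(parentPlus@causativeSite,
                               parentMinus@causativeSite))
  products <- vector("list", 4L)
  for (k in 1:4) {
    carried <- sites$key[(origin[, k] == 1L & inPlus) |
                         (origin[, k] == 2L & inMinus)]
    cs <- causKeys[causKeys %in% carried]
    products[[k]] <- StrainGenome(
      sprintf("%s.%d", idPrefix, k),
      matingType = if (mtOrigin[k] == 1L) "+" else "-",
      alleles = carried,
      causativeSite = if (length(cs)) cs[1L] else NA_character_)
  }
  new("Tetrad", products = products)
}

#' Run an iterated selected backcross scheme
#'
#' Each generation crosses the current phenotype-positive carrier to the
#' (isogenic) wild-type partner, dissects one tetrad, and selects one
#' product that carries the causative site (two of four always do, by the
#' 2:2 law).  The wild-type partner is used in whichever mating type is
#' opposite to the selected carrier, as lab wild types are maintained in
#' both mating types.  Unlinked heterozygous mutations survive each
#' selected generation with probability 1/2, so after `g` generations an
#' unlinked non-causative mutation is retained with probability
#' \eqn{2^{-g}}; the causative site is retained always.
#'
#' @param mutant the causative-site-carrying [StrainGenome-class].
#' @param wt the wild-type [StrainGenome-class] to backcross against.
#' @param generations number of selected generations (>= 0; 0 returns the
#'   mutant unchanged).
#' @param model a [GenomeModel-class].
#' @param seed optional integer seed.
#' @return the selected final-generation [StrainGenome-class].
#' @export
runBackcrossScheme <- function(mutant, wt, generations, model, seed = NULL) {
  generations <- as.integer(generations)
  if (generations < 0L) stop("'generations' must be >= 0")
  if (is.na(causativeSite(mutant)))
    stop("the mutant must carry a causative site")
  .seedIfGiven(seed)
  if (generations == 0L) return(mutant)
  cur <- mutant
  for (g in seq_len(generations)) {
    partner <- StrainGenome(wt@strainId,
                            matingType = .otherMatingType(cur@matingType),
                            alleles = wt@alleles,
                            causativeSite = wt@causativeSite)
    tet <- meiosisTetrad(cur, partner, model,
                         idPrefix = sprintf("%s_bc%d", mutant@strainId, g))
    carriers <- Filter(function(p) !is.na(p@causativeSite), tet@products)
    cur <- carriers[[sample.int(length(carriers), 1L)]]
  }
  cur
}

#' Outcross a mutant and pool the progeny by phenotype
#'
#' Crosses the mutant to the divergent outcross wild type, dissects
#' `nTetrads` complete tetrads (progeny with incomplete tetrads are
#' discarded upstream, so only complete tetrads enter the pools), and
#' partitions all `4 * nTetrads` progeny by phenotype, i.e. by carriage of
#' the causative site.  By the 2:2 law each pool receives exactly
#' `2 * nTetrads` progeny.
#'
#' @param mutant the causative-site-carrying [StrainGenome-class].
#' @param outcrossWt the divergent wild-type [StrainGenome-class] (opposite
#'   mating type).
#' @param nTetrads number of complete tetrads to dissect (>= 1).
#' @param model a [GenomeModel-class].
#' @param seed optional integer seed.
#' @return list with `tspPool` and `wtPool` (lists of
#'   [StrainGenome-class]) and `tetrads` (the dissected [Tetrad-class]s).
#' @export
runOutcrossPools <- function(mutant, outcrossWt, nTetrads, model,
                             seed = NULL) {
  nTetrads <- as.integer(nTetrads)
  if (nTetrads < 1L) stop("'nTetrads' must be >= 1")
  if (is.na(causativeSite(mutant)))
    stop("the mutant must carry a causative site")
  .seedIfGiven(seed)
  tetrads <- vector("list", nTetrads)
  tsp <- list(); wtp <- list()
  for (t in seq_len(nTetrads)) {
    tet <- meiosisTetrad(mutant, outcrossWt, model,
                         idPrefix = sprintf("tet%03d", t))
    tetrads[[t]] <- tet
    for (p in tet@products) {
      if (!is.na(p@causativeSite)) tsp[[length(tsp) + 1L]] <- p
      else wtp[[length(wtp) + 1L]] <- p
    }
  }
  list(tspPool = tsp, wtPool = wtp, tetrads = tetrads)
}
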