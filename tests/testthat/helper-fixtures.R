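# Shared fixtures, built once per test run.  Kept deliberately small so the
# whole suite stays fast; statistical tests choose their own sizes.

# two chromosomes, one controlled gene per strand, plus an intergenic desert
fxModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- buildGenomeModel(
        nChromosomes = 2, chromLength = 5e5,
        genes = data.frame(
          id = c("plusGene", "minusGene"),
          chrom = c("chr01", "chr02"),
          start = c(1001L, 2001L),
          cdsLength = c(300L, 300L),
          strand = c("+", "-"),
          transitPeptideLen = c(0L, 31L)),
        mapRate = 6, seed = 101)
    }
    cache
  }
})

# mid-sized model for breeding-scheme statistics: 2 x 5 Mbp, causal gene
# near the start of chr01
fxBreedingModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- buildGenomeModel(
        nChromosomes = 2, chromLength = 5e6,
        genes = data.frame(id = "causal", chrom = "chr01", start = 101L,
                           cdsLength = 300L, strand = "+"),
        mapRate = 6, seed = 202)
    }
    cache
  }
})

fxMutant <- function(model = fxBreedingModel(), seed = 303) {
  bg <- spawnStrains(model, 0)$background
  mutagenize(bg, model, 1, "causal", seed = seed)
}

# quick variant record builder
vrec <- function(chrom, pos, ref, alt, frequency, source = "s") {
  if (!length(pos)) return(emptyVariantRecords()[, -6L])
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             frequency = frequency, source = source,
             stringsAsFactors = FALSE)
}

randomVariantDf <- function(n, source = "s") {
  if (n == 0L) return(vrec(character(0), integer(0), character(0),
                           character(0), numeric(0)))
  pos <- sample.int(1e5, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  vrec(sample(c("chr01", "chr02"), n, replace = TRUE), pos, ref, alt,
       round(runif(n, 0, 100), 2), source)
}
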