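#' @import methods
#' @importFrom stats rpois rbinom rbeta runif setNames
#' @importFrom utils read.delim
NULL

.MATING_TYPES <- c("+", "-")
.VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "frequency", "kind", "source")

#' Gene model with CDS intervals
#'
#' A protein-coding gene on one chromosome: its CDS intervals (1-based,
#' inclusive, genomic coordinates), coding strand, and the length of an
#' N-terminal transit peptide (0 for proteins without one).  Mature-protein
#' residue numbering subtracts the transit-peptide length, as is customary
#' for chloroplast-imported proteins.
#'
#' @slot id single gene identifier.
#' @slot chrom chromosome name.
#' @slot cds an [IRanges::IRanges] of CDS intervals, sorted, non-overlapping;
#'   total width must be a multiple of 3.
#' @slot strand `"+"` or `"-"`.
#' @slot transitPeptideLen transit-peptide length in residues (>= 0).
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    id = "character",
    chrom = "character",
    cds = "ANY",
    strand = "character",
    transitPeptideLen = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  if (!is(object@cds, "IRanges") || length(object@cds) < 1L)
    msg <- c(msg, "'cds' must be a non-empty IRanges")
  else {
    s <- IRanges::start(object@cds)
    e <- IRanges::end(object@cds)
    if (is.unsorted(s, strictly = TRUE))
      msg <- c(msg, "CDS intervals must be sorted by start")
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "CDS intervals must not overlap")
    if (sum(IRanges::width(object@cds)) %% 3L != 0L)
      msg <- c(msg, "total CDS length must be divisible by 3")
  }
  if (length(object@transitPeptideLen) != 1L || is.na(object@transitPeptideLen) ||
      object@transitPeptideLen < 0L)
    msg <- c(msg, "'transitPeptideLen' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param id gene identifier.
#' @param chrom chromosome name.
#' @param cds an [IRanges::IRanges] of CDS intervals (1-based inclusive) or a
#'   two-column matrix/data.frame of starts and ends.
#' @param strand `"+"` or `"-"`.
#' @param transitPeptideLen transit-peptide length in residues.
#' @return a [GeneModel-class] object.
#' @examples
#' GeneModel("g1", "chr01", IRanges::IRanges(101, 400), "+")
#' @export
GeneModel <- function(id, chrom, cds, strand = "+", transitPeptideLen = 0L) {
  if (!is(cds, "IRanges")) {
    cds <- as.matrix(cds)
    cds <- IRanges::IRanges(start = as.integer(cds[, 1L]),
                            end = as.integer(cds[, 2L]))
  }
  new("GeneModel", id = as.character(id), chrom = as.character(chrom),
      cds = cds, strand = strand,
      transitPeptideLen = as.integer(transitPeptideLen))
}

#' Reference genome model for simulation and annotation
#'
#' Holds the haploid reference: chromosome sequences, gene models, the
#' uniform genetic-map rate used by the meiosis simulator, and the position
#' of the mating-type locus (a single Mendelian locus, so mating type
#' segregates 2:2 through each tetrad).
#'
#' @slot sequences a named [Biostrings::DNAStringSet], one entry per
#'   chromosome.
#' @slot genes list of [GeneModel-class] objects.
#' @slot mapRate genetic-map rate in centimorgan per Mbp (uniform along the
#'   genome; crossovers are placed with no interference).
#' @slot mtLocus list with elements `chrom` and `pos`: the mating-type locus.
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(
    sequences = "ANY",
    genes = "list",
    mapRate = "numeric",
    mtLocus = "list"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character(0)
  if (!is(object@sequences, "DNAStringSet") || length(object@sequences) < 1L)
    msg <- c(msg, "'sequences' must be a non-empty DNAStringSet")
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "chromosomes must have unique names")
  len <- stats::setNames(Biostrings::width(object@sequences), nm)
  if (any(len <= 0L)) msg <- c(msg, "chromosome lengths must be > 0")
  if (length(object@mapRate) != 1L || is.na(object@mapRate) || object@mapRate < 0)
    msg <- c(msg, "'mapRate' must be a single value >= 0 (cM/Mbp)")
  for (g in object@genes) {
    if (!is(g, "GeneModel")) { msg <- c(msg, "'genes' must contain GeneModel objects"); break }
    if (!g@chrom %in% nm) {
      msg <- c(msg, sprintf("gene '%s' lies on unknown chromosome '%s'", g@id, g@chrom))
    } else if (min(IRanges::start(g@cds)) < 1L ||
               max(IRanges::end(g@cds)) > len[[g@chrom]]) {
      msg <- c(msg, sprintf("gene '%s' extends beyond chromosome '%s'", g@id, g@chrom))
    }
  }
  if (!all(c("chrom", "pos") %in% names(object@mtLocus)))
    msg <- c(msg, "'mtLocus' must have elements 'chrom' and 'pos'")
  else if (!object@mtLocus$chrom %in% nm)
    msg <- c(msg, "mating-type locus lies on an unknown chromosome")
  if (length(msg)) msg else TRUE
})

#' Haploid strain genotype
#'
#' A haploid strain is described by the set of alternate alleles it carries
#' at segregating sites, relative to the reference genome.  Each carried
#' allele is a site key `"chrom:pos:ref:alt"`; sites not listed carry the
#' reference allele.  The phenotype model is fully penetrant: a strain
#' expresses the temperature-sensitive phenotype exactly when
#' `causativeSite` is carried.
#'
#' @slot strainId strain label.
#' @slot matingType `"+"` or `"-"`.
#' @slot alleles character vector of carried site keys (unique).
#' @slot causativeSite site key of the causative mutation, or `NA` if the
#'   strain does not carry one.
#' @exportClass StrainGenome
setClass("StrainGenome",
  representation(
    strainId = "character",
    matingType = "character",
    alleles = "character",
    causativeSite = "character"
  ),
  prototype(causativeSite = NA_character_)
)

setValidity("StrainGenome", function(object) {
  msg <- character(0)
  if (length(object@strainId) != 1L) msg <- c(msg, "'strainId' must be a single string")
  if (length(object@matingType) != 1L || !object@matingType %in% .MATING_TYPES)
    msg <- c(msg, "'matingType' must be \"+\" or \"-\"")
  if (anyDuplicated(object@alleles))
    msg <- c(msg, "a haploid strain carries at most one allele per site")
  if (length(object@causativeSite) != 1L)
    msg <- c(msg, "'causativeSite' must be a single key or NA")
  else if (!is.na(object@causativeSite) &&
           !object@causativeSite %in% object@alleles)
    msg <- c(msg, "'causativeSite' must be among the carried alleles")
  if (length(msg)) msg else TRUE
})

#' Construct a StrainGenome
#'
#' @param strainId strain label.
#' @param matingType `"+"` or `"-"`.
#' @param alleles character vector of carried site keys
#'   (`"chrom:pos:ref:alt"`).
#' @param causativeSite site key of the causative mutation or `NA`.
#' @return a [StrainGenome-class].
#' @export
StrainGenome <- function(strainId, matingType = "+", alleles = character(0),
                         causativeSite = NA_character_) {
  new("StrainGenome", strainId = as.character(strainId),
      matingType = matingType, alleles = as.character(alleles),
      causativeSite = as.character(causativeSite))
}

#' The four products of one meiosis
#'
#' @slot products list of exactly four [StrainGenome-class] objects.  At
#'   every site heterozygous between the two parents, exactly two products
#'   carry each parental allele (the tetrad 2:2 law).
#' @exportClass Tetrad
setClass("Tetrad", representation(products = "list"))

setValidity("Tetrad", function(object) {
  if (length(object@products) != 4L)
    return("a tetrad holds exactly 4 meiotic products")
  if (!all(vapply(object@products, is, logical(1), "StrainGenome")))
    return("'products' must be StrainGenome objects")
  TRUE
})

#' Simulation configuration
#'
#' All knobs of the forward-genetics simulator.  Defaults reproduce the
#' study conditions: mean sequencing coverage 30 for pools (20 for single
#' strains, set per experiment design), about 60 induced mutations per
#' mutant, 5 selected backcross generations, and 25 dissected tetrads per
#' outcross pool.
#'
#' @slot seed integer seed, or `NA` to use the current RNG stream.
#' @slot meanCoverage mean read depth per site (Poisson).
#' @slot baseErrorRate per-read probability of a base-call error; an
#'   erroneous read reports one of the three other bases uniformly.
#' @slot artifactRate expected artifact variant calls per Mbp.
#' @slot artifactBeta shape `(a, b)` of the Beta distribution generating
#'   artifact frequency values (scaled to percent).
#' @slot nMutations mutations induced per mutagenized strain (including the
#'   one causative change).
#' @slot poolTetrads complete tetrads dissected per outcross experiment.
#' @slot backcrossGenerations selected backcross generations.
#' @slot minAltReads minimum variant-supporting reads for a variant to be
#'   reported (the caller's minimum-count rule).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "numeric",
    meanCoverage = "numeric",
    baseErrorRate = "numeric",
    artifactRate = "numeric",
    artifactBeta = "numeric",
    nMutations = "integer",
    poolTetrads = "integer",
    backcrossGenerations = "integer",
    minAltReads = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  num1 <- function(x) length(x) == 1L && !is.na(x)
  if (length(object@seed) != 1L) msg <- c(msg, "'seed' must be length 1 (or NA)")
  if (!num1(object@meanCoverage) || object@meanCoverage < 0)
    msg <- c(msg, "'meanCoverage' must be >= 0")
  if (!num1(object@baseErrorRate) || object@baseErrorRate < 0 ||
      object@baseErrorRate > 1)
    msg <- c(msg, "'baseErrorRate' must be in [0, 1]")
  if (!num1(object@artifactRate) || object@artifactRate < 0)
    msg <- c(msg, "'artifactRate' must be >= 0")
  if (length(object@artifactBeta) != 2L || any(object@artifactBeta <= 0))
    msg <- c(msg, "'artifactBeta' must be two positive shapes")
  if (!num1(object@nMutations) || object@nMutations < 0L)
    msg <- c(msg, "'nMutations' must be >= 0")
  if (!num1(object@poolTetrads) || object@poolTetrads < 1L)
    msg <- c(msg, "'poolTetrads' must be >= 1")
  if (!num1(object@backcrossGenerations) || object@backcrossGenerations < 0L)
    msg <- c(msg, "'backcrossGenerations' must be >= 0")
  if (!num1(object@minAltReads) || object@minAltReads < 0L)
    msg <- c(msg, "'minAltReads' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param seed integer seed, or `NA` to draw from the current RNG stream.
#' @param meanCoverage mean read depth (default 30, the pooled-sequencing
#'   coverage; single-strain designs use 20).
#' @param baseErrorRate per-read base-call error probability (default 0.005).
#' @param artifactRate artifact calls per Mbp (default 0.5).
#' @param artifactBeta Beta shapes for artifact frequencies (default
#'   `c(8, 8)`, concentrating mass in the 35--65\% band).
#' @param nMutations induced mutations per mutant (default 60).
#' @param poolTetrads dissected tetrads per outcross (default 25, i.e. 100
#'   progeny, 50 per phenotype pool).
#' @param backcrossGenerations selected backcross generations (default 5).
#' @param minAltReads caller minimum supporting reads (default 2).
#' @return a [SimConfig-class].
#' @examples
#' SimConfig(seed = 1)
#' @export
SimConfig <- function(seed = NA_integer_, meanCoverage = 30,
                      baseErrorRate = 0.005, artifactRate = 0.5,
                      artifactBeta = c(8, 8), nMutations = 60L,
                      poolTetrads = 25L, backcrossGenerations = 5L,
                      minAltReads = 2L) {
  new("SimConfig", seed = as.numeric(seed), meanCoverage = meanCoverage,
      baseErrorRate = baseErrorRate, artifactRate = artifactRate,
      artifactBeta = as.numeric(artifactBeta),
      nMutations = as.integer(nMutations),
      poolTetrads = as.integer(poolTetrads),
      backcrossGenerations = as.integer(backcrossGenerations),
      minAltReads = as.integer(minAltReads))
}

#' Triage configuration
#'
#' The frequency cutoff of the filtering cascade.  The published rule keeps
#' variants with a frequency value strictly over 80\% of mapped reads;
#' `keepAtCutoff = TRUE` relaxes the comparison to \eqn{\ge} for
#' sensitivity runs.
#'
#' @slot frequencyCutoff percent, in `[0, 100]`.
#' @slot keepAtCutoff keep records exactly at the cutoff?
#' @exportClass TriageConfig
setClass("TriageConfig",
  representation(frequencyCutoff = "numeric", keepAtCutoff = "logical")
)

setValidity("TriageConfig", function(object) {
  if (length(object@frequencyCutoff) != 1L || is.na(object@frequencyCutoff) ||
      object@frequencyCutoff < 0 || object@frequencyCutoff > 100)
    return("'frequencyCutoff' must be a single percent in [0, 100]")
  if (length(object@keepAtCutoff) != 1L || is.na(object@keepAtCutoff))
    return("'keepAtCutoff' must be TRUE or FALSE")
  TRUE
})

#' Construct a TriageConfig
#'
#' @param frequencyCutoff percent (default 80).
#' @param keepAtCutoff keep records exactly at the cutoff (default `FALSE`,
#'   i.e. strictly greater).
#' @return a [TriageConfig-class].
#' @export
TriageConfig <- function(frequencyCutoff = 80, keepAtCutoff = FALSE) {
  new("TriageConfig", frequencyCutoff = frequencyCutoff,
      keepAtCutoff = keepAtCutoff)
}

#' Table of called variants
#'
#' The pipeline's central record: one row per called variant with its
#' chromosome, 1-based position, reference and alternate alleles, frequency
#' value (percent of mapped reads supporting the variant), variant kind
#' (`SNP`, `MNP` or `indel`) and the sample or pool it was called in.
#' Rows are unique on (chrom, pos, ref, alt, source) and sorted by
#' chromosome and position.
#'
#' @slot records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `frequency`, `kind`, `source`.
#' @slot provenance free-text description of where the table came from.
#' @exportClass VariantTable
setClass("VariantTable",
  representation(records = "data.frame", provenance = "character")
)

.variantKindOf <- function(ref, alt) {
  if (!length(ref)) return(character(0))
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == na, ifelse(nr == 1L, "SNP", "MNP"), "indel")
}

setValidity("VariantTable", function(object) {
  df <- object@records
  msg <- character(0)
  if (!all(.VARIANT_COLS %in% names(df)))
    return(sprintf("records must have columns %s",
                   paste(.VARIANT_COLS, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$ref == df$alt)) msg <- c(msg, "ref and alt alleles must differ")
    if (any(is.na(df$frequency)) || any(df$frequency < 0) ||
        any(df$frequency > 100))
      msg <- c(msg, "frequency values must lie in [0, 100] percent")
    if (!all(df$kind == .variantKindOf(df$ref, df$alt)))
      msg <- c(msg, "'kind' inconsistent with ref/alt lengths")
    key <- paste(df$chrom, df$pos, df$ref, df$alt, df$source, sep = ":")
    if (anyDuplicated(key))
      msg <- c(msg, "records must be unique on (chrom, pos, ref, alt, source)")
    o <- order(df$chrom, df$pos)
    if (!identical(df$chrom, df$chrom[o]) || !identical(df$pos, df$pos[o]))
      msg <- c(msg, "records must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' An empty variant record data.frame
#'
#' @return zero-row data.frame with the [VariantTable-class] columns.
#' @export
emptyVariantRecords <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), frequency = numeric(0), kind = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Construct a VariantTable
#'
#' Normalizes the input (computes `kind`, sorts by chromosome/position,
#' coerces types) and enforces the class invariants.
#'
#' @param records data.frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `frequency`, `source` columns.
#' @param provenance free-text provenance.
#' @return a [VariantTable-class].
#' @examples
#' VariantTable(data.frame(chrom = "chr01", pos = 10L, ref = "C", alt = "T",
#'                         frequency = 100, source = "mutant"))
#' @export
VariantTable <- function(records = emptyVariantRecords(), provenance = "") {
  need <- setdiff(.VARIANT_COLS, "kind")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("variant records lack column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$frequency <- as.numeric(df$frequency)
  df$source <- as.character(df$source)
  df$kind <- .variantKindOf(df$ref, df$alt)
  df <- df[order(df$chrom, df$pos, df$ref, df$alt, df$source),
           .VARIANT_COLS, drop = FALSE]
  rownames(df) <- NULL
  new("VariantTable", records = df, provenance = as.character(provenance))
}

#' A phenotype-split pool pair with wild-type references
#'
#' The four tables of one outcross pooling experiment: the variant calls of
#' the phenotype-positive pool, of the phenotype-negative pool, and the two
#' wild-type reference strains (background and outcross).
#'
#' @slot tspTable [VariantTable-class] of the phenotype-positive pool.
#' @slot wtTable [VariantTable-class] of the phenotype-negative pool.
#' @slot wtRefs list of wild-type reference [VariantTable-class]s.
#' @exportClass PoolPair
setClass("PoolPair",
  representation(tspTable = "VariantTable", wtTable = "VariantTable",
                 wtRefs = "list")
)

setValidity("PoolPair", function(object) {
  if (!all(vapply(object@wtRefs, is, logical(1), "VariantTable")))
    return("'wtRefs' must be VariantTable objects")
  src <- c(unique(object@tspTable@records$source),
           unique(object@wtTable@records$source),
           unlist(lapply(object@wtRefs, function(x) unique(x@records$source))))
  src <- src[nzchar(src)]
  if (anyDuplicated(src))
    return("the pool and reference tables must come from distinct sources")
  TRUE
})

#' Construct a PoolPair
#'
#' @param tspTable phenotype-positive pool [VariantTable-class].
#' @param wtTable phenotype-negative pool [VariantTable-class].
#' @param wtRefs list of wild-type reference tables (background and
#'   outcross strains).
#' @return a [PoolPair-class].
#' @export
PoolPair <- function(tspTable, wtTable, wtRefs = list()) {
  new("PoolPair", tspTable = tspTable, wtTable = wtTable, wtRefs = wtRefs)
}

#' A coding-sequence change
#'
#' A substitution or equal-length delins on the coding strand, in 1-based
#' CDS coordinates (HGVS "c." numbering).
#'
#' @slot cdsStart first affected CDS nucleotide.
#' @slot cdsEnd last affected CDS nucleotide.
#' @slot refNt reference nucleotides on the coding strand.
#' @slot altNt alternate nucleotides on the coding strand.
#' @exportClass CodingChange
setClass("CodingChange",
  representation(cdsStart = "integer", cdsEnd = "integer",
                 refNt = "character", altNt = "character")
)

setValidity("CodingChange", function(object) {
  if (object@cdsEnd < object@cdsStart)
    return("'cdsEnd' must be >= 'cdsStart'")
  span <- object@cdsEnd - object@cdsStart + 1L
  if (nchar(object@refNt) == nchar(object@altNt) &&
      nchar(object@refNt) != span)
    return("allele length inconsistent with the CDS positions")
  TRUE
})

#' Construct a CodingChange
#'
#' @param cdsStart,cdsEnd 1-based CDS nucleotide positions.
#' @param refNt,altNt coding-strand alleles.
#' @return a [CodingChange-class].
#' @export
CodingChange <- function(cdsStart, cdsEnd, refNt, altNt) {
  new("CodingChange", cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd), refNt = toupper(refNt),
      altNt = toupper(altNt))
}

#' An annotated protein change
#'
#' @slot refAa reference residue(s), one-letter code.
#' @slot position 1-based residue index in the precursor protein
#'   (`ceiling(cdsStart / 3)`).
#' @slot altAa alternate residue(s), one-letter code (`"fs"` for
#'   frameshifts).
#' @slot maturePosition residue index in the mature protein (precursor
#'   position minus transit-peptide length), or `NA` if not mapped.
#' @slot consequence one of `"missense"`, `"synonymous"`, `"nonsense"`,
#'   `"frameshift"`.
#' @exportClass ProteinChange
setClass("ProteinChange",
  representation(refAa = "character", position = "integer",
                 altAa = "character", maturePosition = "integer",
                 consequence = "character"),
  prototype(maturePosition = NA_integer_)
)

setValidity("ProteinChange", function(object) {
  if (!object@consequence %in% c("missense", "synonymous", "nonsense",
                                 "frameshift"))
    return("unknown consequence class")
  if (object@position < 1L) return("'position' must be >= 1")
  if (!is.na(object@maturePosition) && object@maturePosition < 1L)
    return("'maturePosition' must be >= 1 when set")
  TRUE
})

#' Ranked candidate report
#'
#' Novel (mutagenesis-derived) variants ranked as causal candidates:
#' largest outcross-SNP-free linkage region first, then highest frequency
#' value, with positional tie-breaks so the ranking is total and
#' deterministic.
#'
#' @slot candidates data.frame of ranked candidates with flank and region
#'   sizes in bp and a `rank` column.
#' @exportClass CandidateReport
setClass("CandidateReport", representation(candidates = "data.frame"))

#' Tetrad segregation-test result
#'
#' @slot tetradsTested number of tetrads examined.
#' @slot tetrads22 number segregating exactly 2 phenotype-positive : 2
#'   phenotype-negative.
#' @slot singleLocusConsistent `TRUE` iff every tetrad segregated 2:2, the
#'   signature of a single mutated locus.
#' @exportClass SegregationResult
setClass("SegregationResult",
  representation(tetradsTested = "integer", tetrads22 = "integer",
                 singleLocusConsistent = "logical")
)

setValidity("SegregationResult", function(object) {
  if (object@tetrads22 > object@tetradsTested)
    return("'tetrads22' cannot exceed 'tetradsTested'")
  if (!identical(object@singleLocusConsistent,
                 object@tetrads22 == object@tetradsTested))
    return("'singleLocusConsistent' must hold iff all tetrads are 2:2")
  TRUE
})

.DESIGN_KINDS <- c("preliminary", "outcross_pooling", "backcross")

#' An experiment design
#'
#' One of the three published genotyping designs: preliminary whole-genome
#' sequencing of the mutant against its background wild type; outcrossing
#' with phenotype pooling; or iterated selected backcrossing followed by
#' intersection with the preliminary experiment.
#'
#' @slot kind `"preliminary"`, `"outcross_pooling"` or `"backcross"`.
#' @slot overrides named list of design-specific parameter overrides (e.g.
#'   `meanCoverage`, `nOutcrossSnps`, `causativeGene`).
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(kind = "character", overrides = "list")
)

setValidity("ExperimentDesign", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% .DESIGN_KINDS)
    return(sprintf("'kind' must be one of: %s",
                   paste(.DESIGN_KINDS, collapse = ", ")))
  TRUE
})

#' Construct an ExperimentDesign
#'
#' @param kind design kind (see [ExperimentDesign-class]).
#' @param ... named parameter overrides.
#' @return an [ExperimentDesign-class].
#' @examples
#' ExperimentDesign("outcross_pooling", poolTetrads = 25L)
#' @export
ExperimentDesign <- function(kind, ...) {
  new("ExperimentDesign", kind = kind, overrides = list(...))
}
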