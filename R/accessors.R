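#' Accessors for TetradMap classes
#'
#' Small accessor functions for the package's S4 classes; user code should
#' use these rather than reaching into slots.
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("strainId", "StrainGenome", function(x) x@strainId)

#' @rdname accessors
setMethod("matingType", "StrainGenome", function(x) x@matingType)

#' @rdname accessors
setMethod("alleles", "StrainGenome", function(x) x@alleles)

#' @rdname accessors
setMethod("causativeSite", "StrainGenome", function(x) x@causativeSite)

#' @rdname accessors
setMethod("tetradProducts", "Tetrad", function(x) x@products)

#' @rdname accessors
setMethod("variantRecords", "VariantTable", function(x) x@records)

#' @rdname accessors
setMethod("provenance", "VariantTable", function(x) x@provenance)

#' @rdname accessors
setMethod("geneModels", "GenomeModel", function(x) x@genes)

#' @rdname accessors
setMethod("chromLengths", "GenomeModel", function(x)
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences)))

#' @rdname accessors
setMethod("mapRate", "GenomeModel", function(x) x@mapRate)

#' @rdname accessors
setMethod("genomeSequences", "GenomeModel", function(x) x@sequences)

#' @rdname accessors
setMethod("candidates", "CandidateReport", function(x) x@candidates)

#' @describeIn matchKey keys of all records of a table.
setMethod("matchKey", "VariantTable", function(x) matchKey(x@records))

#' @describeIn matchKey keys of rows of a variant record data.frame.
setMethod("matchKey", "data.frame", function(x) {
  if (!nrow(x)) return(character(0))
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
})

setMethod("show", "GenomeModel", function(object) {
  len <- chromLengths(object)
  cat(sprintf("GenomeModel: %d chromosome(s), %.2f Mbp total, %d gene(s), %g cM/Mbp\n",
              length(len), sum(len) / 1e6, length(object@genes),
              object@mapRate))
  cat(sprintf("  mating-type locus at %s:%d\n",
              object@mtLocus$chrom, object@mtLocus$pos))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s): %d CDS interval(s), %d nt, transit peptide %d aa\n",
              object@id, object@chrom, object@strand, length(object@cds),
              sum(IRanges::width(object@cds)), object@transitPeptideLen))
})

setMethod("show", "StrainGenome", function(object) {
  cat(sprintf("StrainGenome %s (mt%s): %d carried allele(s), causative site: %s\n",
              object@strainId, object@matingType, length(object@alleles),
              ifelse(is.na(object@causativeSite), "none",
                     object@causativeSite)))
})

setMethod("show", "Tetrad", function(object) {
  carry <- vapply(object@products,
                  function(p) !is.na(p@causativeSite), logical(1))
  cat(sprintf("Tetrad: 4 products, %d carrying the causative site\n",
              sum(carry)))
})

setMethod("show", "VariantTable", function(object) {
  df <- object@records
  cat(sprintf("VariantTable: %d record(s) from %d source(s)%s\n", nrow(df),
              length(unique(df$source)),
              ifelse(nzchar(object@provenance),
                     paste0(" [", object@provenance, "]"), "")))
  if (nrow(df)) print(utils::head(df, 6L))
  if (nrow(df) > 6L) cat(sprintf("  ... and %d more\n", nrow(df) - 6L))
})

setMethod("show", "CandidateReport", function(object) {
  cat(sprintf("CandidateReport: %d ranked candidate(s)\n",
              nrow(object@candidates)))
  if (nrow(object@candidates)) print(utils::head(object@candidates, 5L))
})

setMethod("show", "SegregationResult", function(object) {
  cat(sprintf("SegregationResult: %d/%d tetrads segregated 2:2 -> %s\n",
              object@tetrads22, object@tetradsTested,
              ifelse(object@singleLocusConsistent,
                     "consistent with a single mutated locus",
                     "NOT consistent with a single locus")))
})

setMethod("show", "ProteinChange", function(object) {
  mat <- if (!is.na(object@maturePosition))
    sprintf(" (mature %s%d%s)", object@refAa, object@maturePosition,
            object@altAa) else ""
  cat(sprintf("ProteinChange: %s%d%s [%s]%s\n", object@refAa,
              object@position, object@altAa, object@consequence, mat))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: seed=%s coverage=%g error=%g artifacts=%g/Mbp",
                     " Beta(%g,%g) mutations=%d tetrads=%d backcross=%d minAltReads=%d\n"),
              ifelse(is.na(object@seed), "NA", format(object@seed)),
              object@meanCoverage, object@baseErrorRate, object@artifactRate,
              object@artifactBeta[1], object@artifactBeta[2],
              object@nMutations, object@poolTetrads,
              object@backcrossGenerations, object@minAltReads))
})
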