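#' @rdname accessors
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @rdname accessors
#' @export
setGeneric("matingType", function(x) standardGeneric("matingType"))

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname accessors
#' @export
setGeneric("causativeSite", function(x) standardGeneric("causativeSite"))

#' @rdname accessors
#' @export
setGeneric("tetradProducts", function(x) standardGeneric("tetradProducts"))

#' @rdname accessors
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("mapRate", function(x) standardGeneric("mapRate"))

#' @rdname accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))

#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' Site key of one or many variants
#'
#' The site key `"chrom:pos:ref:alt"` defines variant identity across
#' samples: two records with equal keys are the same variant regardless of
#' their frequency values or source.
#'
#' @param x a [VariantTable-class] or a data.frame of variant records.
#' @return character vector of site keys, one per record.
#' @examples
#' matchKey(VariantTable(data.frame(chrom = "chr01", pos = 5L, ref = "A",
#'                                  alt = "G", frequency = 88, source = "m")))
#' @export
setGeneric("matchKey", function(x) standardGeneric("matchKey"))
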