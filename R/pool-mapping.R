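#' Bulked-segregant causal filter on a phenotype-split pool pair
#'
#' The pooled-progeny filter: variants of the phenotype-positive pool with
#' frequency values over the cutoff are filtered against every variant of
#' the phenotype-negative pool (at any frequency value — a variant seen in
#' any phenotype-negative progeny cannot cause the phenotype) and against
#' the wild-type reference tables, then reduced to protein-changing
#' variants.  A causative variant must be carried by every
#' phenotype-positive progeny and so is reported near 100\%.
#'
#' @param pp a [PoolPair-class].
#' @param genome a [GenomeModel-class] (or `DNAStringSet` with `genes`).
#' @param genes list of [GeneModel-class]; taken from `genome` when it is a
#'   [GenomeModel-class].
#' @param cfg a [TriageConfig-class].
#' @return the candidate causative [VariantTable-class] (a subset of the
#'   phenotype-positive pool table).
#' @export
poolCausalFilter <- function(pp, genome, genes = NULL,
                             cfg = TriageConfig()) {
  kept <- frequencyFilter(pp@tspTable, cfg)
  kept <- subtractVariants(kept, c(list(pp@wtTable), pp@wtRefs))
  selectNonsynonymous(kept, genome, genes)
}

#' Frequency-value distribution diagnostics
#'
#' Summarizes a call set's frequency-value distribution the way the
#' cumulative-histogram diagnostic does: the fraction of records inside a
#' band (lower bound open, upper bound closed), the fraction at exactly
#' 100\% (after 2-decimal rounding), and the cumulative distribution of
#' frequency values.
#'
#' @param table a non-empty [VariantTable-class].
#' @param band numeric `(lo, hi)`: the frequency band in percent (default
#'   the 35--65\% artifact bulk).
#' @return list with `fractionInBand`, `fractionAt100`, and `cumulative`
#'   (a data.frame of `frequency` and non-decreasing `fraction` ending at
#'   1).
#' @export
frequencyHistogram <- function(table, band = c(35, 65)) {
  f <- variantRecords(table)$frequency
  if (!length(f)) stop("cannot summarize an empty variant table")
  if (length(band) != 2L || band[1L] > band[2L])
    stop("'band' must be (lo, hi) with lo <= hi")
  fr <- sort(unique(f))
  list(fractionInBand = mean(f > band[1L] & f <= band[2L]),
       fractionAt100 = mean(round(f, 2) == 100),
       cumulative = data.frame(frequency = fr,
                               fraction = vapply(fr, function(x) mean(f <= x),
                                                 numeric(1))))
}
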