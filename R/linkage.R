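.ORIGINS <- c("background_wt", "outcross_wt", "novel")

#' Tag every pool variant with its origin
#'
#' Trio-style origin assignment: a record whose site key appears in the
#' background wild-type panel is tagged `background_wt`; one in the
#' outcross wild-type panel, `outcross_wt`; everything else is `novel`
#' (mutagenesis-derived).  Origin is decided by key membership alone;
#' every record receives exactly one origin.  Panels sharing a key are a
#' contamination error.
#'
#' @param poolTable a [VariantTable-class] (typically the full call list of
#'   the phenotype-positive pool).
#' @param backgroundPanel [VariantTable-class] of background wild-type
#'   variants.
#' @param outcrossPanel [VariantTable-class] of outcross wild-type
#'   variants.
#' @return data.frame of the pool records plus `key`, `origin`, and
#'   (unfilled) `leftFlank`, `rightFlank`, `regionSize` columns; see
#'   [cleanFlanks()].
#' @export
tagOrigin <- function(poolTable, backgroundPanel, outcrossPanel) {
  bgKeys <- unique(matchKey(backgroundPanel))
  ocKeys <- unique(matchKey(outcrossPanel))
  shared <- intersect(bgKeys, ocKeys)
  if (length(shared))
    stop("panel contamination: key(s) present in both wild-type panels: ",
         paste(utils::head(shared, 3L), collapse = ", "))
  df <- variantRecords(poolTable)
  df$key <- matchKey(df)
  df$origin <- ifelse(df$key %in% bgKeys, "background_wt",
                      ifelse(df$key %in% ocKeys, "outcross_wt", "novel"))
  df$leftFlank <- NA_real_
  df$rightFlank <- NA_real_
  df$regionSize <- NA_real_
  df
}

#' Size the outcross-SNP-free region around tagged variants
#'
#' For each tagged variant, the left (right) flank is the distance in bp to
#' the nearest `outcross_wt`-tagged variant at a smaller (larger) position
#' on the same chromosome.  With no outcross SNP on a side, the flank runs
#' through the chromosome terminus: `pos` on the left (the clean sequence
#' includes position 1), `length - pos` on the right, so a chromosome free
#' of outcross SNPs scores its full length.  The region size is the sum of
#' the two flanks — a
#' large region free of outcross SNPs is linkage evidence that the
#' phenotype selection dragged along the surrounding background-strain
#' haplotype.
#'
#' @param tagged data.frame from [tagOrigin()].
#' @param model a [GenomeModel-class] (for chromosome lengths).
#' @return `tagged` with `leftFlank`, `rightFlank`, `regionSize` filled in
#'   (bp).
#' @export
cleanFlanks <- function(tagged, model) {
  lens <- chromLengths(model)
  unknown <- setdiff(unique(tagged$chrom), names(lens))
  if (length(unknown))
    stop("tagged variants on chromosome(s) absent from the model: ",
         paste(unknown, collapse = ", "))
  for (cn in unique(tagged$chrom)) {
    onChrom <- which(tagged$chrom == cn)
    ocPos <- sort(tagged$pos[onChrom][tagged$origin[onChrom] == "outcross_wt"])
    for (i in onChrom) {
      p <- tagged$pos[i]
      left <- ocPos[ocPos < p]
      right <- ocPos[ocPos > p]
      tagged$leftFlank[i] <- if (length(left)) p - max(left) else p
      tagged$rightFlank[i] <- if (length(right)) min(right) - p
                              else lens[[cn]] - p
    }
  }
  tagged$regionSize <- tagged$leftFlank + tagged$rightFlank
  tagged
}

#' Flank sizes of a single candidate
#'
#' Single-variant version of [cleanFlanks()]: returns the candidate's row
#' with `leftFlank`, `rightFlank` and `regionSize` filled in.
#'
#' @param candidate one tagged row (one-row data.frame) or its site key.
#' @param tagged data.frame from [tagOrigin()].
#' @param model a [GenomeModel-class].
#' @return the candidate's one-row data.frame with flank fields set.
#' @export
cleanFlank <- function(candidate, tagged, model) {
  key <- if (is.character(candidate)) candidate else candidate$key
  filled <- cleanFlanks(tagged, model)
  row <- filled[filled$key == key, , drop = FALSE]
  if (!nrow(row)) stop("candidate key not found among tagged variants: ", key)
  row
}

#' Rank novel variants as causal candidates
#'
#' Keeps the `novel` (mutagenesis-derived) variants and ranks them by the
#' two lines of evidence the pooled-outcross design provides: the size of
#' the outcross-SNP-free linkage region (descending), then the frequency
#' value (descending; a causative variant must be at 100\%, a merely
#' linked one falls below).  Ties break on (chrom, pos) so the ranking is
#' total and deterministic.  The top-ranked candidate is the causal call.
#'
#' @param tagged data.frame from [tagOrigin()], with flanks filled by
#'   [cleanFlanks()] (rows with `NA` region sizes rank by frequency only).
#' @return a [CandidateReport-class].
#' @export
rankCandidates <- function(tagged) {
  novel <- tagged[tagged$origin == "novel", , drop = FALSE]
  if (!nrow(novel))
    stop("no novel variants to rank (all records match a wild-type panel)")
  rs <- ifelse(is.na(novel$regionSize), -Inf, novel$regionSize)
  o <- order(-rs, -novel$frequency, novel$chrom, novel$pos)
  novel <- novel[o, , drop = FALSE]
  novel$rank <- seq_len(nrow(novel))
  rownames(novel) <- NULL
  new("CandidateReport", candidates = novel)
}
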