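#' Frequency-value cutoff filter
#'
#' Keeps records whose frequency value is strictly over the cutoff
#' (default 80\%; callers reporting a real haploid variant lose at most a
#' few reads to ambiguous base calls, while most artifact calls sit in the
#' mid-frequency bulk).  `keepAtCutoff = TRUE` keeps records exactly at the
#' cutoff.
#'
#' @param table a [VariantTable-class].
#' @param cfg a [TriageConfig-class].
#' @return the filtered [VariantTable-class] (a subset of the input, order
#'   preserved).
#' @examples
#' vt <- VariantTable(data.frame(chrom = "chr01", pos = c(1L, 2L, 3L, 4L),
#'                               ref = "A", alt = "G",
#'                               frequency = c(100, 88, 79, 50),
#'                               source = "m"))
#' variantRecords(frequencyFilter(vt))$frequency  # 100 and 88 survive
#' @export
frequencyFilter <- function(table, cfg = TriageConfig()) {
  df <- variantRecords(table)
  keep <- if (cfg@keepAtCutoff) df$frequency >= cfg@frequencyCutoff
          else df$frequency > cfg@frequencyCutoff
  VariantTable(df[keep, , drop = FALSE], provenance = provenance(table))
}

#' Subtract reference variant sets
#'
#' Removes every record whose site key appears in any reference table at
#' any frequency value — presence alone disqualifies, because a variant
#' seen in a wild type (or in a phenotype-negative pool) cannot cause the
#' phenotype.
#'
#' @param table a [VariantTable-class].
#' @param references a [VariantTable-class] or list of them.
#' @return the filtered [VariantTable-class] (a subset of the input).
#' @export
subtractVariants <- function(table, references) {
  if (is(references, "VariantTable")) references <- list(references)
  refKeys <- unique(unlist(lapply(references, matchKey), use.names = FALSE))
  df <- variantRecords(table)
  keep <- !matchKey(df) %in% refKeys
  VariantTable(df[keep, , drop = FALSE], provenance = provenance(table))
}

#' Keep only variants that change a protein
#'
#' Retains records that overlap a CDS and alter the translated protein:
#' missense and nonsense substitutions/MNPs, and CDS-overlapping indels
#' (frameshift-inducing or in-frame).  Intergenic, intronic and synonymous
#' records are dropped.
#'
#' @param table a [VariantTable-class].
#' @param genome a [GenomeModel-class], or a [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param genes list of [GeneModel-class] objects (taken from the model
#'   when `genome` is a [GenomeModel-class]).
#' @return the filtered [VariantTable-class].
#' @export
selectNonsynonymous <- function(table, genome, genes = NULL) {
  if (is(genome, "GenomeModel")) {
    if (is.null(genes)) genes <- geneModels(genome)
  } else if (is.null(genes)) {
    stop("'genes' must be supplied when 'genome' is not a GenomeModel")
  }
  df <- variantRecords(table)
  if (!nrow(df))
    return(VariantTable(df, provenance = provenance(table)))
  chroms <- vapply(genes, function(g) g@chrom, character(1))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    vStart <- df$pos[i]
    vEnd <- vStart + nchar(df$ref[i]) - 1L
    for (gi in which(chroms == df$chrom[i])) {
      g <- genes[[gi]]
      hits <- IRanges::findOverlaps(IRanges::IRanges(vStart, vEnd), g@cds)
      if (!length(hits)) next
      keep[i] <- .changesProtein(df[i, ], g, genome)
      break
    }
  }
  VariantTable(df[keep, , drop = FALSE], provenance = provenance(table))
}

# does a CDS-overlapping variant alter the protein?
.changesProtein <- function(v, gene, genome) {
  if (nchar(v$ref) != nchar(v$alt)) return(TRUE)  # indel in CDS: frameshift or in-frame change
  cc <- genomicToCoding(v, gene, genome)
  if (is.null(cc)) return(TRUE)  # partial CDS overlap (e.g. MNP across a boundary): coding bases change
  pc <- applyCodingChange(cdsSequence(gene, genome), cc)
  pc@consequence != "synonymous"
}

#' Intersect variant tables from independent experiments
#'
#' Keeps the records whose site key appears in every table — the published
#' cross-experiment confirmation step.  Frequency values (and all other
#' fields) are reported from the first table.  The result is associative
#' and order-insensitive at key level.
#'
#' @param tables list of at least two [VariantTable-class] objects.
#' @return a [VariantTable-class].
#' @export
intersectExperiments <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least 2 tables to intersect")
  keySets <- lapply(tables, matchKey)
  common <- Reduce(intersect, keySets)
  df <- variantRecords(tables[[1L]])
  VariantTable(df[matchKey(df) %in% common, , drop = FALSE],
               provenance = sprintf("intersection of %d experiments",
                                    length(tables)))
}
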