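#' Parse an HGVS-style coding-change descriptor
#'
#' Supports the CDS substitution grammar `c.<pos><ref>><alt>` (e.g.
#' `"c.479C>T"`) and the equal-length delins grammar
#' `c.<start>_<end>del<ref>ins<alt>` (e.g. `"c.2044_2045delCCinsTT"`).
#' Positions are 1-based on the coding strand.  Other HGVS classes
#' (intronic/splice offsets, UTR positions, duplications, unequal-length
#' delins) raise an explicit unsupported error.
#'
#' @param text descriptor string.
#' @return a [CodingChange-class].
#' @examples
#' parseHgvsC("c.479C>T")
#' parseHgvsC("c.2044_2045delCCinsTT")
#' @export
parseHgvsC <- function(text) {
  text <- trimws(text)
  if (!grepl("^c\\.", text))
    stop("not a coding-sequence (c.) descriptor: ", text)
  body <- sub("^c\\.", "", text)
  if (grepl("[+*-]", body))
    stop("unsupported HGVS class (intronic/UTR offsets are not handled): ",
         text)
  m <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1L]]
  if (length(m) == 4L)
    return(CodingChange(as.integer(m[2L]), as.integer(m[2L]), m[3L], m[4L]))
  m <- regmatches(body,
                  regexec("^([0-9]+)_([0-9]+)del([ACGT]+)ins([ACGT]+)$",
                          body))[[1L]]
  if (length(m) == 5L) {
    start <- as.integer(m[2L]); end <- as.integer(m[3L])
    span <- end - start + 1L
    if (end < start)
      stop("descriptor end precedes start: ", text)
    if (nchar(m[4L]) != span || nchar(m[5L]) != span)
      stop("delins allele lengths must equal the position span: ", text)
    return(CodingChange(start, end, m[4L], m[5L]))
  }
  stop("cannot parse coding-change descriptor at token '", body, "'")
}

#' Format a CodingChange as an HGVS-style descriptor
#'
#' Inverse of [parseHgvsC()]: single-base substitutions print as
#' `c.<pos><ref>><alt>`, multi-base equal-length changes as
#' `c.<start>_<end>del<ref>ins<alt>`.
#'
#' @param change a [CodingChange-class].
#' @return descriptor string.
#' @export
formatHgvsC <- function(change) {
  if (change@cdsStart == change@cdsEnd && nchar(change@refNt) == 1L)
    sprintf("c.%d%s>%s", change@cdsStart, change@refNt, change@altNt)
  else
    sprintf("c.%d_%ddel%sins%s", change@cdsStart, change@cdsEnd,
            change@refNt, change@altNt)
}

#' Apply a coding change to a CDS and report the protein change
#'
#' Translates the affected codon(s) before and after the change with the
#' standard genetic code.  The residue index is `ceiling(cdsStart / 3)`
#' (precursor-protein numbering).  The consequence is classified as
#' `synonymous`, `missense`, `nonsense` (a stop gained), or `frameshift`
#' (alleles of unequal length whose difference is not a multiple of 3).
#'
#' @param cds coding sequence (character or [Biostrings::DNAString]);
#'   length must be a multiple of 3.
#' @param change a [CodingChange-class]; its reference allele must match
#'   the CDS at the stated positions (a mismatch signals the wrong
#'   transcript and is an error).
#' @return a [ProteinChange-class].
#' @examples
#' cds <- paste0(strrep("ATG", 159), "CCT", strrep("GCA", 40))
#' applyCodingChange(cds, parseHgvsC("c.479C>T"))  # Pro160Leu
#' @export
applyCodingChange <- function(cds, change) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L)
    stop("CDS translation impossible: length is not a multiple of 3")
  if (change@cdsEnd > nchar(cds))
    stop("coding change lies beyond the CDS end")
  codonStart <- ceiling(change@cdsStart / 3)
  refLen <- nchar(change@refNt); altLen <- nchar(change@altNt)

  observed <- substr(cds, change@cdsStart, change@cdsStart + refLen - 1L)
  if (observed != change@refNt)
    stop(sprintf(paste0("reference allele mismatch at c.%d: CDS has '%s', ",
                        "descriptor says '%s' (wrong transcript?)"),
                 change@cdsStart, observed, change@refNt))

  if (refLen != altLen) {
    if ((altLen - refLen) %% 3L == 0L)
      stop("unsupported coding-change class: in-frame length-changing delins")
    refCodon <- substr(cds, (codonStart - 1L) * 3L + 1L, codonStart * 3L)
    return(new("ProteinChange", refAa = .translateNt(refCodon),
               position = as.integer(codonStart), altAa = "fs",
               maturePosition = NA_integer_, consequence = "frameshift"))
  }

  codonEnd <- ceiling((change@cdsStart + refLen - 1L) / 3)
  winStart <- (codonStart - 1L) * 3L + 1L
  winEnd <- codonEnd * 3L
  refWin <- substr(cds, winStart, winEnd)
  altWin <- refWin
  offset <- change@cdsStart - winStart + 1L
  substr(altWin, offset, offset + altLen - 1L) <- change@altNt
  refAa <- .translateNt(refWin)
  altAa <- .translateNt(altWin)
  consequence <- if (refAa == altAa) "synonymous"
                 else if (grepl("\\*", altAa) && !grepl("\\*", refAa)) "nonsense"
                 else "missense"
  new("ProteinChange", refAa = refAa, position = as.integer(codonStart),
      altAa = altAa, maturePosition = NA_integer_,
      consequence = consequence)
}

#' Renumber a protein change in mature-protein coordinates
#'
#' Chloroplast-imported proteins lose their N-terminal transit peptide on
#' import; residue numbering of the mature protein subtracts the
#' transit-peptide length.
#'
#' @param pc a [ProteinChange-class].
#' @param transitPeptideLen transit-peptide length in residues (>= 0).
#' @return the [ProteinChange-class] with `maturePosition` set.
#' @examples
#' pc <- applyCodingChange(paste0(strrep("ATG", 159), "CCT",
#'                                strrep("GCA", 40)),
#'                         parseHgvsC("c.479C>T"))
#' toMature(pc, 31)  # Pro129Leu in the mature protein
#' @export
toMature <- function(pc, transitPeptideLen) {
  transitPeptideLen <- as.integer(transitPeptideLen)
  if (transitPeptideLen < 0L) stop("'transitPeptideLen' must be >= 0")
  if (pc@position <= transitPeptideLen)
    stop(sprintf("residue %d lies inside the %d-residue transit peptide",
                 pc@position, transitPeptideLen))
  new("ProteinChange", refAa = pc@refAa, position = pc@position,
      altAa = pc@altAa,
      maturePosition = pc@position - transitPeptideLen,
      consequence = pc@consequence)
}

# 1-based CDS coordinate of genomic positions `gpos` within `gene`;
# NA for positions outside the CDS
.genomicToCdsPos <- function(gene, gpos) {
  starts <- IRanges::start(gene@cds)
  ends <- IRanges::end(gene@cds)
  widths <- ends - starts + 1L
  before <- c(0L, cumsum(widths)[-length(widths)])
  total <- sum(widths)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(starts)) {
    inIv <- gpos >= starts[i] & gpos <= ends[i]
    plusPos <- before[i] + (gpos[inIv] - starts[i] + 1L)
    out[inIv] <- if (gene@strand == "+") plusPos else total - plusPos + 1L
  }
  out
}

# inverse: genomic position of CDS coordinate `cdsPos`
.cdsPosToGenomic <- function(gene, cdsPos) {
  starts <- IRanges::start(gene@cds)
  ends <- IRanges::end(gene@cds)
  widths <- ends - starts + 1L
  total <- sum(widths)
  p <- if (gene@strand == "+") cdsPos else total - cdsPos + 1L
  before <- c(0L, cumsum(widths)[-length(widths)])
  i <- findInterval(p, before + 1L)
  starts[i] + (p - before[i] - 1L)
}

#' Extract the coding sequence of a gene
#'
#' Concatenates the CDS intervals and reverse-complements for minus-strand
#' genes, yielding the coding-strand sequence.
#'
#' @param gene a [GeneModel-class].
#' @param genome a [GenomeModel-class] or named
#'   [Biostrings::DNAStringSet].
#' @return the CDS as a character string.
#' @export
cdsSequence <- function(gene, genome) {
  seqs <- if (is(genome, "GenomeModel")) genomeSequences(genome) else genome
  chromSeq <- seqs[[gene@chrom]]
  parts <- as.character(Biostrings::extractAt(chromSeq, gene@cds))
  cds <- paste(parts, collapse = "")
  if (gene@strand == "-") .revcomp(cds) else cds
}

#' Project a genomic variant into coding coordinates
#'
#' Maps a genomic SNP/MNP (or the anchor base of an indel) into CDS
#' coordinates of a gene, respecting CDS intervals and strand; alleles are
#' reverse-complemented for minus-strand genes.  The genomic reference
#' allele is checked against the genome sequence.
#'
#' @param v one variant record: a one-row data.frame or list with `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param gene a [GeneModel-class].
#' @param genome a [GenomeModel-class] or named
#'   [Biostrings::DNAStringSet].
#' @return a [CodingChange-class], or `NULL` when the variant has no
#'   (fully determined) coding effect: wrong chromosome, intergenic or
#'   intronic position, or not fully contained in the CDS.
#' @export
genomicToCoding <- function(v, gene, genome) {
  if (v$chrom != gene@chrom) return(NULL)
  seqs <- if (is(genome, "GenomeModel")) genomeSequences(genome) else genome
  refLen <- nchar(v$ref)
  gpos <- v$pos:(v$pos + refLen - 1L)
  observed <- as.character(Biostrings::extractAt(
    seqs[[v$chrom]], IRanges::IRanges(v$pos, v$pos + refLen - 1L)))
  if (observed != v$ref)
    stop(sprintf("reference allele mismatch at %s:%d: genome has '%s', record says '%s'",
                 v$chrom, v$pos, observed, v$ref))
  cdsPos <- .genomicToCdsPos(gene, gpos)
  if (anyNA(cdsPos)) return(NULL)
  if (refLen > 1L) {
    span <- range(cdsPos)
    if (span[2L] - span[1L] + 1L != refLen)
      stop("variant spans a CDS junction; not supported")
  }
  if (nchar(v$ref) == nchar(v$alt)) {
    if (gene@strand == "+")
      CodingChange(min(cdsPos), max(cdsPos), v$ref, v$alt)
    else
      CodingChange(min(cdsPos), max(cdsPos), .revcomp(v$ref),
                   .revcomp(v$alt))
  } else {
    # indel: anchor at the first affected CDS base; alleles strand-adjusted
    if (gene@strand == "+")
      new("CodingChange", cdsStart = min(cdsPos), cdsEnd = max(cdsPos),
          refNt = v$ref, altNt = v$alt)
    else
      new("CodingChange", cdsStart = min(cdsPos), cdsEnd = max(cdsPos),
          refNt = .revcomp(v$ref), altNt = .revcomp(v$alt))
  }
}

#' Annotate a variant record against a gene
#'
#' Convenience wrapper: projects the variant into coding coordinates,
#' applies it to the CDS, and (when the gene has a transit peptide) adds
#' mature-protein numbering.
#'
#' @inheritParams genomicToCoding
#' @return a [ProteinChange-class], or `NULL` if the variant has no coding
#'   effect.
#' @export
annotateVariant <- function(v, gene, genome) {
  cc <- genomicToCoding(v, gene, genome)
  if (is.null(cc)) return(NULL)
  pc <- applyCodingChange(cdsSequence(gene, genome), cc)
  if (gene@transitPeptideLen > 0L &&
      pc@position > gene@transitPeptideLen)
    pc <- toMature(pc, gene@transitPeptideLen)
  pc
}
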