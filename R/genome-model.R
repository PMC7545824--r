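#' Build a toy genome model
#'
#' Generates a haploid multi-chromosome reference genome for simulation:
#' random chromosome sequences, gene models written into them as clean open
#' reading frames (ATG start, no internal stop, terminal stop codon), a
#' uniform genetic-map rate, and a single mating-type locus (placed at the
#' midpoint of the last chromosome) so mating type segregates as a
#' Mendelian trait.
#'
#' Genes can be placed at random (`nGenes` of length `geneLength` each) or
#' specified explicitly through the `genes` data.frame, which allows tests
#' and analyses to control gene positions exactly.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLength chromosome length(s) in bp (recycled).
#' @param nGenes number of genes to place at random (ignored when `genes`
#'   is given).
#' @param geneLength CDS length in nt for randomly placed genes; must be a
#'   multiple of 3.
#' @param mapRate genetic-map rate in cM/Mbp.
#' @param genes optional data.frame with columns `id`, `chrom`, `start`,
#'   `cdsLength`, `strand` and optionally `transitPeptideLen`, describing
#'   single-interval CDS genes explicitly.
#' @param seed optional integer seed; the same configuration and seed give
#'   an identical model.
#' @return a [GenomeModel-class].
#' @examples
#' m <- buildGenomeModel(nChromosomes = 2, chromLength = 1e5, nGenes = 4,
#'                       seed = 1)
#' chromLengths(m)
#' @export
buildGenomeModel <- function(nChromosomes = 3L, chromLength = 4e6,
                             nGenes = 30L, geneLength = 1500L, mapRate = 6,
                             genes = NULL, seed = NULL) {
  .seedIfGiven(seed)
  nChromosomes <- as.integer(nChromosomes)
  if (nChromosomes < 1L) stop("need at least one chromosome")
  lens <- as.integer(rep_len(chromLength, nChromosomes))
  if (any(lens <= 0L)) stop("chromosome lengths must be > 0")
  names(lens) <- sprintf("chr%02d", seq_len(nChromosomes))

  seqs <- lapply(lens, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""))

  if (is.null(genes)) {
    if (nGenes < 1L) stop("need at least one gene")
    geneLength <- as.integer(geneLength)
    if (geneLength %% 3L != 0L)
      stop("configuration error: CDS length not divisible by 3")
    genes <- .placeRandomGenes(lens, as.integer(nGenes), geneLength)
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "start", "cdsLength", "strand")
    miss <- setdiff(need, names(genes))
    if (length(miss))
      stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
    if (!"transitPeptideLen" %in% names(genes)) genes$transitPeptideLen <- 0L
    if (any(genes$cdsLength %% 3L != 0L))
      stop("configuration error: CDS length not divisible by 3")
  }

  geneObjs <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(lens))
      stop(sprintf("gene '%s' placed on unknown chromosome '%s'",
                   g$id, g$chrom))
    gstart <- as.integer(g$start)
    gend <- gstart + as.integer(g$cdsLength) - 1L
    if (gstart < 1L || gend > lens[[g$chrom]])
      stop(sprintf("gene '%s' interval [%d, %d] extends beyond chromosome '%s'",
                   g$id, gstart, gend, g$chrom))
    orf <- .randomOrf(as.integer(g$cdsLength))
    ins <- if (g$strand == "-") .revcomp(orf) else orf
    substr(seqs[[g$chrom]], gstart, gend) <- ins
    geneObjs[[i]] <- GeneModel(g$id, g$chrom,
                               IRanges::IRanges(gstart, gend),
                               strand = g$strand,
                               transitPeptideLen = g$transitPeptideLen)
  }

  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(lens)
  mtChrom <- names(lens)[nChromosomes]
  new("GenomeModel", sequences = dss, genes = geneObjs, mapRate = mapRate,
      mtLocus = list(chrom = mtChrom, pos = as.integer(lens[[mtChrom]] %/% 2L)))
}

# random sense ORF: ATG + non-stop codons + TAA
.randomOrf <- function(len) {
  nCodon <- len %/% 3L
  if (nCodon < 2L) stop("CDS too short for an open reading frame")
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste0("ATG",
         paste(sample(sense, nCodon - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

.placeRandomGenes <- function(lens, nGenes, geneLength) {
  chroms <- character(nGenes); starts <- integer(nGenes)
  taken <- lapply(lens, function(.) IRanges::IRanges())
  probs <- as.numeric(lens) / sum(as.numeric(lens))
  for (i in seq_len(nGenes)) {
    ok <- FALSE
    for (try in 1:200) {
      cn <- sample(names(lens), 1L, prob = probs)
      if (lens[[cn]] < geneLength + 2L) next
      st <- sample.int(lens[[cn]] - geneLength + 1L, 1L)
      cand <- IRanges::IRanges(st, st + geneLength - 1L)
      if (!length(IRanges::findOverlaps(cand, taken[[cn]]))) {
        taken[[cn]] <- c(taken[[cn]], cand)
        chroms[i] <- cn; starts[i] <- st; ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place genes without overlap; genome too small")
  }
  data.frame(id = sprintf("gene%03d", seq_len(nGenes)), chrom = chroms,
             start = starts, cdsLength = geneLength,
             strand = sample(c("+", "-"), nGenes, replace = TRUE),
             transitPeptideLen = 0L, stringsAsFactors = FALSE)
}

#' Look up a gene model by id
#'
#' @param model a [GenomeModel-class].
#' @param id gene identifier.
#' @return the [GeneModel-class]; error if absent.
#' @export
getGene <- function(model, id) {
  for (g in model@genes) if (g@id == id) return(g)
  stop(sprintf("gene '%s' not found in the genome model", id))
}

#' Write the toy genome as FASTA
#'
#' @param model a [GenomeModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(model, path) {
  Biostrings::writeXStringSet(model@sequences, filepath = path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' One CDS feature per CDS interval, carrying the gene id and the
#' transit-peptide length as attributes.
#'
#' @param model a [GenomeModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(model, path) {
  rows <- lapply(model@genes, function(g) {
    w <- IRanges::width(g@cds)
    # coding-order cumulative length determines each interval's phase
    ord <- if (g@strand == "+") seq_along(w) else rev(seq_along(w))
    before <- c(0L, cumsum(w[ord]))[seq_along(w)]
    phase <- integer(length(w))
    phase[ord] <- (3L - before %% 3L) %% 3L
    data.frame(chrom = g@chrom, start = IRanges::start(g@cds),
               end = IRanges::end(g@cds), strand = g@strand, ID = g@id,
               phase = phase,
               transit_peptide_len = g@transitPeptideLen,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$transit_peptide_len <- df$transit_peptide_len
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads CDS features written by [writeGeneModelsGff3()] (or any GFF3 whose
#' CDS features carry an `ID` attribute; a `transit_peptide_len` attribute
#' is honoured when present).
#'
#' @param path GFF3 file.
#' @return list of [GeneModel-class] objects.
#' @export
readGeneModelsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  tpl <- S4Vectors::mcols(gr)$transit_peptide_len
  if (is.null(tpl)) tpl <- rep(0L, length(gr))
  tpl <- as.integer(tpl)
  lapply(split(seq_along(gr), ids), function(i) {
    sub <- gr[i]
    o <- order(GenomicRanges::start(sub))
    GeneModel(ids[i][1L], as.character(GenomicRanges::seqnames(sub))[1L],
              IRanges::IRanges(GenomicRanges::start(sub)[o],
                               GenomicRanges::end(sub)[o]),
              strand = as.character(GenomicRanges::strand(sub))[1L],
              transitPeptideLen = tpl[i][1L])
  })
}
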