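#' Build a site key
#'
#' @param chrom,pos,ref,alt variant fields (vectorized).
#' @return character keys `"chrom:pos:ref:alt"`.
#' @export
siteKey <- function(chrom, pos, ref, alt) {
  paste(chrom, as.integer(pos), ref, alt, sep = ":")
}

#' Parse site keys back into variant fields
#'
#' @param keys character vector of `"chrom:pos:ref:alt"` keys.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`.
#' @export
parseSiteKeys <- function(keys) {
  if (!length(keys))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      key = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed site key(s): ", paste(keys[bad][1L], collapse = ", "))
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]), ref = m[, 3L],
             alt = m[, 4L], key = keys, stringsAsFactors = FALSE)
}

# set the RNG only when an explicit seed is supplied; NULL/NA means "use the
# current stream", so one top-level seed drives a whole simulation run
.seedIfGiven <- function(seed) {
  if (!is.null(seed) && length(seed) == 1L && !is.na(seed))
    set.seed(as.integer(seed))
  invisible(NULL)
}

.otherMatingType <- function(mt) if (mt == "+") "-" else "+"

.BASES <- c("A", "C", "G", "T")

# reference bases of `model` at (chrom, pos), vectorized
.refBases <- function(model, chrom, pos) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    out[i] <- as.character(Biostrings::extractAt(
      model@sequences[[cn]], IRanges::IRanges(pos[i], pos[i])))
  }
  out
}

# map linear offsets in [1, sum(lengths)] to (chrom, pos)
.linearToChromPos <- function(offsets, lens) {
  ends <- cumsum(as.numeric(lens))
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(offsets - 1, ends) + 1L
  data.frame(chrom = names(lens)[idx],
             pos = as.integer(offsets - starts[idx]),
             stringsAsFactors = FALSE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.translateNt <- function(x) {
  if (!nchar(x)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "error"))
}

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

# "P" -> "Pro", "PQ" -> "ProGln"
.aa3 <- function(aa) {
  vapply(strsplit(aa, ""), function(ch)
    paste(.AA3[ch], collapse = ""), character(1))
}
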