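.TSV_HEADER <- c("chrom", "pos", "ref", "alt", "frequency", "strain_or_pool")

#' Read a variant table
#'
#' Two on-disk formats are supported: single-sample VCF 4.2 with the
#' frequency value (percent of supporting mapped reads) in a per-sample
#' FORMAT field `VF`, and a fixed TSV dialect with columns `chrom`, `pos`,
#' `ref`, `alt`, `frequency`, `strain_or_pool`.  Records missing a
#' frequency are an error naming the record; malformed lines are an error
#' naming the line number.
#'
#' @param path input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return a [VariantTable-class].
#' @export
readVariants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf") .readVcf(path) else .readTsv(path)
}

.readTsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(.TSV_HEADER %in% header))
    stop("TSV header must contain columns: ",
         paste(.TSV_HEADER, collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body))
    return(VariantTable(emptyVariantRecords(), provenance = path))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(fields) != length(header)
  if (any(bad))
    stop(sprintf("malformed TSV line %d in %s",
                 which(bad)[1L] + 1L, path))
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  freq <- suppressWarnings(as.numeric(m[, "frequency"]))
  if (anyNA(freq))
    stop(sprintf("missing or non-numeric frequency at line %d in %s",
                 which(is.na(freq))[1L] + 1L, path))
  if (any(freq < 0 | freq > 100))
    stop(sprintf("frequency out of [0, 100] at line %d in %s",
                 which(freq < 0 | freq > 100)[1L] + 1L, path))
  pos <- suppressWarnings(as.integer(m[, "pos"]))
  if (anyNA(pos))
    stop(sprintf("malformed position at line %d in %s",
                 which(is.na(pos))[1L] + 1L, path))
  VariantTable(data.frame(chrom = m[, "chrom"], pos = pos,
                          ref = m[, "ref"], alt = m[, "alt"],
                          frequency = freq, source = m[, "strain_or_pool"],
                          stringsAsFactors = FALSE),
               provenance = path)
}

.readVcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  colLine <- grep("^#CHROM\t", lines)
  if (!length(colLine)) stop("not a VCF file (no #CHROM header): ", path)
  cols <- strsplit(lines[colLine[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L)
    stop("VCF must carry one sample column with the VF FORMAT field: ", path)
  sample <- cols[10L]
  body <- lines[-seq_len(colLine[1L])]
  body <- body[nzchar(body)]
  if (!length(body))
    return(VariantTable(emptyVariantRecords(), provenance = path))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(fields) < 10L
  if (any(bad))
    stop(sprintf("malformed VCF line %d in %s",
                 which(bad)[1L] + colLine[1L], path))
  m <- matrix(unlist(lapply(fields, `[`, 1:10)), ncol = 10L, byrow = TRUE)
  fmt <- strsplit(m[, 9L], ":", fixed = TRUE)
  smp <- strsplit(m[, 10L], ":", fixed = TRUE)
  freq <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    vfIdx <- match("VF", fmt[[i]])
    if (is.na(vfIdx) || vfIdx > length(smp[[i]]))
      stop(sprintf("record %s:%s lacks the VF frequency field in %s",
                   m[i, 1L], m[i, 2L], path))
    freq[i] <- suppressWarnings(as.numeric(smp[[i]][vfIdx]))
    if (is.na(freq[i]))
      stop(sprintf("record %s:%s has a non-numeric VF value in %s",
                   m[i, 1L], m[i, 2L], path))
  }
  if (any(freq < 0 | freq > 100))
    stop("VF frequency out of [0, 100] in ", path)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos))
    stop(sprintf("malformed VCF line %d in %s",
                 which(is.na(pos))[1L] + colLine[1L], path))
  VariantTable(data.frame(chrom = m[, 1L], pos = pos, ref = m[, 4L],
                          alt = m[, 5L], frequency = freq,
                          source = rep(sample, nrow(m)),
                          stringsAsFactors = FALSE),
               provenance = path)
}

#' Write a variant table
#'
#' Output is byte-stable for identical input: records are sorted, the
#' frequency value is always printed with 2 decimals, lines end in LF.
#' VCF output is VCF 4.2 with a single sample column and the frequency in
#' the FORMAT field `VF`; a table with multiple sources cannot be written
#' as VCF.
#'
#' @param table a [VariantTable-class].
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(table, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  df <- variantRecords(table)
  con <- file(path, open = "wb")  # binary: LF line endings on any platform
  on.exit(close(con))
  if (format == "tsv") {
    lines <- c(paste(.TSV_HEADER, collapse = "\t"),
               if (nrow(df)) paste(df$chrom, df$pos, df$ref, df$alt,
                                   sprintf("%.2f", df$frequency), df$source,
                                   sep = "\t"))
  } else {
    sample <- unique(df$source)
    if (length(sample) > 1L)
      stop("VCF output is single-sample; the table has sources: ",
           paste(sample, collapse = ", "))
    if (!length(sample)) sample <- "sample"
    lines <- c(
      "##fileformat=VCFv4.2",
      paste0("##FORMAT=<ID=VF,Number=1,Type=Float,Description=",
             "\"Variant frequency: percent of mapped reads supporting the variant\">"),
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", sample), collapse = "\t"),
      if (nrow(df)) paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", ".",
                          ".", "VF", sprintf("%.2f", df$frequency),
                          sep = "\t"))
  }
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
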