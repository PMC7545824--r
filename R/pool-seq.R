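#' All segregating sites across a set of strains
#'
#' @param strains list of [StrainGenome-class] objects.
#' @return sorted character vector of site keys carried by at least one
#'   strain.
#' @export
segregatingSites <- function(strains) {
  keys <- unique(unlist(lapply(strains, alleles), use.names = FALSE))
  if (!length(keys)) return(character(0))
  ps <- parseSiteKeys(keys)
  keys[order(ps$chrom, ps$pos, ps$ref, ps$alt)]
}

#' Allele-level frequency table of a pool
#'
#' Exact carrier fractions (in percent) of each site across the pool
#' members — pooled sequencing with infinite coverage and no noise.  A
#' causative variant in a phenotype-selected pool has frequency exactly
#' 100 here.
#'
#' @param pool list of [StrainGenome-class] objects.
#' @param sites site keys to report (default: all sites segregating in the
#'   pool).
#' @param source source label for the records.
#' @return a [VariantTable-class]; sites carried by no pool member are
#'   omitted.
#' @export
alleleFrequencyTable <- function(pool, sites = NULL, source = "pool") {
  if (!length(pool)) stop("the pool is empty")
  if (is.null(sites)) sites <- segregatingSites(pool)
  ps <- parseSiteKeys(sites)
  carriers <- .carrierCounts(pool, sites)
  freq <- round(100 * carriers / length(pool), 2)
  keep <- carriers > 0L
  VariantTable(data.frame(chrom = ps$chrom[keep], pos = ps$pos[keep],
                          ref = ps$ref[keep], alt = ps$alt[keep],
                          frequency = freq[keep],
                          source = rep(source, sum(keep)),
                          stringsAsFactors = FALSE),
               provenance = sprintf("allele-level frequencies of %d pooled strains",
                                    length(pool)))
}

.carrierCounts <- function(pool, sites) {
  n <- integer(length(sites))
  for (p in pool) n <- n + (sites %in% p@alleles)
  n
}

#' Simulate pooled whole-genome sequencing of a pool of strains
#'
#' Per site, read depth is Poisson with mean `meanCoverage`; each read is
#' drawn from a uniformly chosen pool member and miscalled with probability
#' `baseErrorRate` (an erroneous read reports one of the three other bases
#' uniformly, so it supports the specific alternate allele with probability
#' `baseErrorRate / 3`).  The reported frequency value is
#' `100 * altReads / depth`, rounded to 2 decimals.  Mimicking the caller's
#' minimum-count rule, a site is reported only when at least `minAltReads`
#' reads support the variant; sites with zero depth are absent.  Artifact
#' variant calls are added at `artifactRate` per Mbp with frequency values
#' drawn from `100 * Beta(a, b)` — the mid-frequency artifact bulk seen in
#' real call sets.
#'
#' @param pool list of [StrainGenome-class] objects (a single strain is a
#'   pool of one).
#' @param model a [GenomeModel-class] (for artifact placement and reference
#'   alleles).
#' @param cfg a [SimConfig-class].
#' @param sites site keys to interrogate (default: sites segregating in the
#'   pool).  Pass the union over both pools of an experiment so that
#'   base-call noise can create records at sites the pool does not carry.
#' @param source source label for the resulting table.
#' @return a [VariantTable-class].
#' @export
simulatePoolSequencing <- function(pool, model, cfg = SimConfig(),
                                   sites = NULL, source = "pool") {
  if (!length(pool)) stop("the pool is empty")
  .seedIfGiven(cfg@seed)
  if (is.null(sites)) sites <- segregatingSites(pool)
  ps <- parseSiteKeys(sites)
  n <- length(pool)
  e <- cfg@baseErrorRate
  minAlt <- max(1L, cfg@minAltReads)

  if (nrow(ps)) {
    carrierFrac <- .carrierCounts(pool, sites) / n
    pAlt <- carrierFrac * (1 - e) + (1 - carrierFrac) * (e / 3)
    depth <- rpois(nrow(ps), cfg@meanCoverage)
    altReads <- rbinom(nrow(ps), depth, pAlt)
    keep <- depth > 0L & altReads >= minAlt
    rec <- data.frame(chrom = ps$chrom[keep], pos = ps$pos[keep],
                      ref = ps$ref[keep], alt = ps$alt[keep],
                      frequency = round(100 * altReads[keep] / depth[keep], 2),
                      source = rep(source, sum(keep)),
                      stringsAsFactors = FALSE)
  } else {
    rec <- emptyVariantRecords()
  }

  lens <- chromLengths(model)
  nArt <- rpois(1L, cfg@artifactRate * sum(as.numeric(lens)) / 1e6)
  if (nArt > 0L) {
    off <- sample(sum(as.numeric(lens)), nArt, replace = FALSE)
    cp <- .linearToChromPos(off, lens)
    ref <- .refBases(model, cp$chrom, cp$pos)
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    freq <- round(100 * rbeta(nArt, cfg@artifactBeta[1], cfg@artifactBeta[2]), 2)
    freq <- pmin(pmax(freq, 0.01), 99.99)
    art <- data.frame(chrom = cp$chrom, pos = cp$pos, ref = ref, alt = alt,
                      frequency = freq, source = rep(source, nArt),
                      stringsAsFactors = FALSE)
    art <- art[!siteKey(art$chrom, art$pos, art$ref, art$alt) %in%
                 siteKey(rec$chrom, rec$pos, rec$ref, rec$alt), ,
               drop = FALSE]
    rec <- rbind(rec, art)
  }
  VariantTable(rec, provenance = sprintf(
    "simulated pooled sequencing of %d strain(s), mean coverage %g", n,
    cfg@meanCoverage))
}

.CONFIG_KEYS <- c(seed = "seed", mean_coverage = "meanCoverage",
                  base_error_rate = "baseErrorRate",
                  artifact_variant_rate = "artifactRate",
                  artifact_frequency_beta_a = "artifactBetaA",
                  artifact_frequency_beta_b = "artifactBetaB",
                  n_mutations = "nMutations", pool_tetrads = "poolTetrads",
                  backcross_generations = "backcrossGenerations",
                  min_alt_reads = "minAltReads")

#' Read a simulation configuration from a flat key=value file
#'
#' Lines are `key=value`; blank lines and `#` comments are ignored.
#' Unknown keys are an error (fail fast on typos).
#'
#' @param path config file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  unknown <- setdiff(keys, names(.CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  v <- as.list(as.numeric(vals))
  names(v) <- .CONFIG_KEYS[keys]
  get0 <- function(nm, dflt) if (!is.null(v[[nm]])) v[[nm]] else dflt
  SimConfig(seed = get0("seed", NA_integer_),
            meanCoverage = get0("meanCoverage", 30),
            baseErrorRate = get0("baseErrorRate", 0.005),
            artifactRate = get0("artifactRate", 0.5),
            artifactBeta = c(get0("artifactBetaA", 8),
                             get0("artifactBetaB", 8)),
            nMutations = get0("nMutations", 60),
            poolTetrads = get0("poolTetrads", 25),
            backcrossGenerations = get0("backcrossGenerations", 5),
            minAltReads = get0("minAltReads", 2))
}

#' Write a simulation configuration as a flat key=value file
#'
#' @param cfg a [SimConfig-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSimConfig <- function(cfg, path) {
  writeLines(.configLines(cfg), path)
  invisible(path)
}

.configLines <- function(cfg) {
  c(sprintf("seed=%s", ifelse(is.na(cfg@seed), "NA", format(cfg@seed))),
    sprintf("mean_coverage=%g", cfg@meanCoverage),
    sprintf("base_error_rate=%g", cfg@baseErrorRate),
    sprintf("artifact_variant_rate=%g", cfg@artifactRate),
    sprintf("artifact_frequency_beta_a=%g", cfg@artifactBeta[1]),
    sprintf("artifact_frequency_beta_b=%g", cfg@artifactBeta[2]),
    sprintf("n_mutations=%d", cfg@nMutations),
    sprintf("pool_tetrads=%d", cfg@poolTetrads),
    sprintf("backcross_generations=%d", cfg@backcrossGenerations),
    sprintf("min_alt_reads=%d", cfg@minAltReads))
}
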