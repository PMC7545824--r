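#' Single-locus tetrad segregation test
#'
#' Counts tetrads in which exactly two of the four products are
#' phenotype-positive (carry the causative site).  A fully penetrant
#' single-locus trait segregates 2:2 in every tetrad, so the result is
#' declared consistent with a single mutated locus iff all tetrads are
#' 2:2.
#'
#' @param tetrads non-empty list of [Tetrad-class] objects.
#' @return a [SegregationResult-class].
#' @export
segregationTest <- function(tetrads) {
  if (!length(tetrads)) stop("no tetrads to test")
  is22 <- vapply(tetrads, function(tt) {
    carry <- vapply(tetradProducts(tt),
                    function(p) !is.na(causativeSite(p)), logical(1))
    sum(carry) == 2L
  }, logical(1))
  new("SegregationResult", tetradsTested = length(tetrads),
      tetrads22 = sum(is22),
      singleLocusConsistent = all(is22))
}

#' Colonies screened per mutant isolated
#'
#' The screen's yield arithmetic: how many colonies had to be screened, on
#' average, to isolate one phenotype-positive mutant (integer-rounded).
#'
#' @param coloniesScreened number of colonies screened.
#' @param mutantsIsolated number of mutants isolated.
#' @return integer colonies per mutant.
#' @examples
#' screeningYield(12000, 157)  # 76
#' @export
screeningYield <- function(coloniesScreened, mutantsIsolated) {
  if (mutantsIsolated <= 0) stop("'mutantsIsolated' must be > 0")
  as.integer(round(coloniesScreened / mutantsIsolated))
}

.designDefault <- function(overrides, name, default) {
  if (!is.null(overrides[[name]])) overrides[[name]] else default
}

#' Run a genotyping experiment design end to end
#'
#' Simulates the inputs of one of the three published designs and executes
#' its filter cascade:
#'
#' * `preliminary` — whole-genome sequencing of the mutant (coverage 20)
#'   against the background wild type: frequency cutoff, wild-type
#'   subtraction, non-synonymous selection.
#' * `outcross_pooling` — outcross to the divergent wild type, phenotype
#'   pooling (coverage 30), the pools-based causal filter, origin tagging
#'   against both wild-type call sets, clean-flank sizing, ranking.
#' * `backcross` — iterated selected backcrossing (default 5 generations),
#'   the preliminary cascade on both the original mutant and the
#'   final-generation strain, and their intersection.
#'
#' Every stage's input/output record counts are logged, so the count
#' trajectory of a run can be inspected like the published 60/55 → 21/20 →
#' 6/3/5 trajectories.  With `outDir` set, the candidate report (TSV), the
#' count trajectory (TSV) and a human-readable summary with a
#' reproducibility block (seed and full configuration) are written;
#' identical seed and configuration give byte-identical files.
#'
#' @param design an [ExperimentDesign-class] (or a design kind string).
#' @param cfg a [SimConfig-class]; `cfg@seed` (when not `NA`) fixes every
#'   stochastic choice of the run.
#' @param model optional pre-built [GenomeModel-class]; one is built (from
#'   the current RNG stream) when omitted.  Passing a fixed model makes
#'   replicate runs share one reference genome.
#' @param outDir optional output directory for report files.
#' @return list with `report` ([CandidateReport-class]), `counts` (the
#'   stage-count trajectory), `truth` (the planted causative key and
#'   strains), `tables` (the simulated variant tables) and `design`.
#' @export
runPipeline <- function(design, cfg = SimConfig(), model = NULL,
                        outDir = NULL) {
  if (is.character(design)) design <- ExperimentDesign(design)
  .seedIfGiven(cfg@seed)
  ov <- design@overrides
  if (is.null(model))
    model <- buildGenomeModel(
      nChromosomes = .designDefault(ov, "nChromosomes", 3L),
      chromLength = .designDefault(ov, "chromLength", 4e6),
      nGenes = .designDefault(ov, "nGenes", 30L),
      mapRate = .designDefault(ov, "mapRate", 6))
  lens <- chromLengths(model)
  totalMbp <- sum(as.numeric(lens)) / 1e6

  counts <- data.frame(stage = character(0), records_in = integer(0),
                       records_out = integer(0), stringsAsFactors = FALSE)
  logStage <- function(stage, nIn, nOut) {
    message(sprintf("[%s] %s: %d -> %d records", design@kind, stage, nIn,
                    nOut))
    counts <<- rbind(counts, data.frame(stage = stage, records_in = nIn,
                                        records_out = nOut,
                                        stringsAsFactors = FALSE))
  }
  cascade <- function(table, references, label) {
    cut <- frequencyFilter(table, TriageConfig())
    logStage(paste0(label, ":frequency_cutoff"), nrow(variantRecords(table)),
             nrow(variantRecords(cut)))
    sub <- subtractVariants(cut, references)
    logStage(paste0(label, ":wild_type_subtraction"),
             nrow(variantRecords(cut)), nrow(variantRecords(sub)))
    ns <- selectNonsynonymous(sub, model)
    logStage(paste0(label, ":nonsynonymous"), nrow(variantRecords(sub)),
             nrow(variantRecords(ns)))
    ns
  }

  nOutcross <- .designDefault(ov, "nOutcrossSnps",
                              as.integer(round(100 * totalMbp)))
  nBackground <- .designDefault(ov, "nBackgroundSnps", 0L)
  useOutcross <- design@kind == "outcross_pooling"
  sp <- spawnStrains(model,
                     nOutcrossSnps = if (useOutcross) nOutcross else 0L,
                     nBackgroundSnps = nBackground)
  causativeGene <- .designDefault(ov, "causativeGene", {
    ids <- vapply(geneModels(model), function(g) g@id, character(1))
    sample(ids, 1L)
  })
  mutant <- mutagenize(sp$background, model, cfg@nMutations, causativeGene,
                       mutantId = "mutant")
  truth <- list(causativeKey = causativeSite(mutant),
                causativeGene = causativeGene, mutant = mutant,
                background = sp$background, outcross = sp$outcross)

  strainCfg <- cfg
  strainCfg@meanCoverage <- .designDefault(ov, "meanCoverage", 20)
  strainCfg@seed <- NA_real_
  poolCfg <- cfg
  poolCfg@meanCoverage <- .designDefault(ov, "meanCoverage", 30)
  poolCfg@seed <- NA_real_

  tables <- list()
  if (design@kind == "preliminary") {
    tables$mutant <- simulatePoolSequencing(list(mutant), model, strainCfg,
                                            source = "mutant")
    tables$background <- simulatePoolSequencing(list(sp$background), model,
                                                strainCfg,
                                                source = "background_wt")
    final <- cascade(tables$mutant, list(tables$background), "preliminary")
    tagged <- cleanFlanks(tagOrigin(final, VariantTable(), VariantTable()),
                          model)
    report <- rankCandidates(tagged)
  } else if (design@kind == "outcross_pooling") {
    pools <- runOutcrossPools(mutant, sp$outcross, cfg@poolTetrads, model)
    sites <- segregatingSites(c(pools$tspPool, pools$wtPool))
    tables$tspPool <- simulatePoolSequencing(pools$tspPool, model, poolCfg,
                                             sites = sites,
                                             source = "tsp_pool")
    tables$wtPool <- simulatePoolSequencing(pools$wtPool, model, poolCfg,
                                            sites = sites,
                                            source = "wt_pool")
    tables$background <- simulatePoolSequencing(list(sp$background), model,
                                                poolCfg,
                                                source = "background_wt")
    tables$outcross <- simulatePoolSequencing(list(sp$outcross), model,
                                              poolCfg,
                                              source = "outcross_wt")
    pp <- PoolPair(tables$tspPool, tables$wtPool,
                   wtRefs = list(tables$background, tables$outcross))
    final <- poolCausalFilter(pp, model)
    logStage("pool_causal_filter", nrow(variantRecords(tables$tspPool)),
             nrow(variantRecords(final)))
    tagged <- cleanFlanks(tagOrigin(tables$tspPool, tables$background,
                                    tables$outcross), model)
    candidateRows <- tagged[tagged$key %in% matchKey(final), , drop = FALSE]
    report <- rankCandidates(candidateRows)
    tables$tagged <- tagged
  } else {  # backcross
    bc <- runBackcrossScheme(mutant, sp$background,
                             cfg@backcrossGenerations, model)
    tables$mutant <- simulatePoolSequencing(list(mutant), model, strainCfg,
                                            source = "mutant")
    tables$backcross <- simulatePoolSequencing(list(bc), model, strainCfg,
                                               source = sprintf(
                                                 "backcross_gen%d",
                                                 cfg@backcrossGenerations))
    tables$background <- simulatePoolSequencing(list(sp$background), model,
                                                strainCfg,
                                                source = "background_wt")
    prelim <- cascade(tables$mutant, list(tables$background), "preliminary")
    bcFinal <- cascade(tables$backcross, list(tables$background),
                       "backcross")
    final <- intersectExperiments(list(bcFinal, prelim))
    logStage("experiment_intersection",
             nrow(variantRecords(bcFinal)), nrow(variantRecords(final)))
    tagged <- cleanFlanks(tagOrigin(final, VariantTable(), VariantTable()),
                          model)
    report <- rankCandidates(tagged)
    truth$backcrossStrain <- bc
  }

  result <- list(report = report, counts = counts, truth = truth,
                 tables = tables, design = design)
  if (!is.null(outDir)) writeRunReport(result, cfg, outDir)
  result
}

#' Write a pipeline run report to disk
#'
#' Writes `candidates.tsv` (the ranked candidate table),
#' `count_trajectory.tsv` (the per-stage record counts) and `summary.txt`
#' (human-readable summary with the seed and full configuration, so a run
#' can be reproduced exactly).
#'
#' @param result list returned by [runPipeline()].
#' @param cfg the [SimConfig-class] the run used.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunReport <- function(result, cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cand <- candidates(result$report)
  num <- vapply(cand, is.numeric, logical(1)) &
    names(cand) %in% c("frequency", "leftFlank", "rightFlank", "regionSize")
  cand[num] <- lapply(cand[num], function(x) sprintf("%.2f", x))
  .writeTsvStable(cand, file.path(outDir, "candidates.tsv"))
  .writeTsvStable(result$counts, file.path(outDir, "count_trajectory.tsv"))
  top <- candidates(result$report)[1L, ]
  lines <- c(
    sprintf("design: %s", result$design@kind),
    sprintf("top candidate: %s (frequency %.2f, region %.0f bp)",
            top$key, top$frequency, top$regionSize),
    sprintf("planted causative variant: %s", result$truth$causativeKey),
    sprintf("recovered: %s",
            identical(top$key, result$truth$causativeKey)),
    "",
    "# reproducibility",
    .configLines(cfg))
  con <- file(file.path(outDir, "summary.txt"), open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(outDir)
}

.writeTsvStable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df))
    lines <- c(lines, do.call(paste, c(lapply(df, as.character),
                                       sep = "\t")))
  writeLines(lines, con, useBytes = TRUE)
}
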