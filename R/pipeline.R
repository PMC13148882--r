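#' Read a pipeline run configuration
#'
#' Configurations are plain YAML key-value documents. Recognized keys:
#' \describe{
#'   \item{calls}{path to a call table, or}
#'   \item{simulate}{a block with loci, ancestral_q (map source -> list of
#'     per-locus q), weights (map source -> proportion) and n;}
#'   \item{seed}{integer seed used for simulation;}
#'   \item{loci}{loci to analyze (default: all typed);}
#'   \item{panel}{path to a reference panel (default: the packaged global
#'     panel);}
#'   \item{cohort_label}{label for the cohort in distance outputs;}
#'   \item{compare}{method/count_policy/yates options for panel tests;}
#'   \item{distance_populations}{optional subset of panel populations;}
#'   \item{mds_k}{MDS dimensions (default 2);}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param path YAML file.
#' @return named list usable by [runPipeline()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ## YAML 1.1 resolves bare y/n as booleans, which would silently turn the
  ## common key "n" into FALSE; keep those two as literal strings.
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) == "y") x else TRUE,
    "bool#no" = function(x) if (tolower(x) == "n") x else FALSE))
}

#' Run the full null-marker analysis pipeline
#'
#' Orchestrates frequency estimation, panel comparisons, Nei distances, MDS
#' and UPGMA in one deterministic pass, writing TSV/Newick artifacts plus a
#' MANIFEST and a structured log with md5 checksums (no timestamps: two runs
#' with identical config and seed are byte-identical). On a stage failure
#' the MANIFEST records the completion state of every stage before the error
#' is rethrown.
#'
#' @param config named list (see [readRunConfig()]) or path to a YAML file.
#' @param outDir output directory; overrides \code{config$out_dir}.
#' @return invisibly, a list with the artifact paths and in-memory results.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- outDir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  manifest <- data.frame(artifact = character(), path = character(),
                         md5 = character(), status = character(),
                         stringsAsFactors = FALSE)
  note <- function(...) logLines <<- c(logLines, sprintf(...))
  register <- function(name, path, status = "ok") {
    md5 <- if (file.exists(path)) unname(md5sum(path)) else ""
    manifest <<- rbind(manifest,
                       data.frame(artifact = name, path = basename(path),
                                  md5 = md5, status = status,
                                  stringsAsFactors = FALSE))
    note("stage=%s status=%s output=%s md5=%s", name, status,
         basename(path), md5)
  }
  finish <- function() {
    write.table(manifest, file.path(outDir, "MANIFEST.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(logLines, file.path(outDir, "pipeline_log.txt"))
  }
  results <- list()
  on.exit(finish())

  seed <- as.integer(config$seed %||% 1L)
  note("config seed=%d", seed)

  ## --- cohort ---------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$calls)) {
      readCalls(config$calls, sep = config$sep %||% "\t")
    } else if (!is.null(config$simulate)) {
      sim <- config$simulate
      spec <- admixtureSpec(loci = unlist(sim$loci),
                            ancestralQ = lapply(sim$ancestral_q, unlist),
                            weights = unlist(sim$weights),
                            n = sim$n, seed = seed)
      simulateCohort(spec, model = sim$model %||% "panmictic")
    } else stop("config needs either 'calls' or 'simulate'")
  }, error = function(e) {
    register("cohort", "", status = "failed")
    stop("cohort stage failed: ", conditionMessage(e), call. = FALSE)
  })
  lociUse <- unlist(config$loci) %||% loci(cohort)
  note("cohort n=%d loci=%s", ncol(cohort), paste(lociUse, collapse = ","))

  ## --- frequency tables ----------------------------------------------
  freqPath <- file.path(outDir, "allele_frequencies.tsv")
  gs <- genotypeSummary(cohort, lociUse)
  write.table(gs, freqPath, sep = "\t", quote = FALSE, row.names = FALSE)
  register("allele_frequencies", freqPath)
  results$frequencies <- gs

  combPath <- file.path(outDir, "genotype_combinations.tsv")
  if (length(lociUse) >= 2) {
    comb <- combinationFrequencies(cohort, lociUse[1], lociUse[2])
  } else {
    comb <- data.frame(combination = character(), count = integer(),
                       frequency = numeric(), percent = character())
    note("stage=genotype_combinations note=single-locus cohort, empty table")
  }
  write.table(comb, combPath, sep = "\t", quote = FALSE, row.names = FALSE)
  register("genotype_combinations", combPath)
  results$combinations <- comb

  ## --- panel comparisons ----------------------------------------------
  panel <- if (!is.null(config$panel)) readPanel(config$panel) else table3Panel()
  cmpPath <- file.path(outDir, "panel_comparisons.tsv")
  cmpCfg <- config$compare %||% list()
  cmpAll <- lapply(intersect(lociUse, loci(panel)), function(l) {
    lf <- phenotypeFrequencies(cohort, l)
    res <- withCallingHandlers(
      comparePanel(lf, panel, l,
                   method = cmpCfg$method %||% "auto",
                   countPolicy = cmpCfg$count_policy %||% "round_nearest",
                   yates = isTRUE(cmpCfg$yates)),
      message = function(m) {
        note("stage=panel_comparisons locus=%s note=%s", l,
             trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    if (nrow(res)) cbind(locus = l, res) else NULL
  })
  cmpAll <- do.call(rbind, cmpAll)
  if (is.null(cmpAll)) {
    cmpAll <- data.frame(locus = character(), population = character())
    note("stage=panel_comparisons note=no comparable panel rows, comparisons skipped")
  }
  write.table(cmpAll, cmpPath, sep = "\t", quote = FALSE, row.names = FALSE)
  register("panel_comparisons", cmpPath)
  results$comparisons <- cmpAll

  ## --- distances -------------------------------------------------------
  distPath <- file.path(outDir, "nei_distance_matrix.tsv")
  fn <- sapply(lociUse, function(l) phenotypeFrequencies(cohort, l)@fNull)
  panelPlus <- addPopulation(panel, config$cohort_label %||% "Focal cohort",
                             nullFreq = setNames(fn, lociUse),
                             n = ncol(cohort), region = "Focal",
                             before = TRUE)
  dm <- neiDistanceMatrix(panelPlus,
                          whichLoci = intersect(lociUse, loci(panelPlus)),
                          subset = unlist(config$distance_populations) %||%
                            NULL)
  dmOut <- data.frame(population = rownames(dm),
                      apply(dm, 2, fmtNum),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write.table(dmOut, distPath, sep = "\t", quote = FALSE, row.names = FALSE)
  register("nei_distance_matrix", distPath)
  results$distance <- dm

  ## --- ordination ------------------------------------------------------
  mdsPath <- file.path(outDir, "mds_coordinates.tsv")
  mds <- classicalMds(dm, k = config$mds_k %||% 2L)
  writeCoordinates(mds, mdsPath)
  register("mds_coordinates", mdsPath)
  results$mds <- mds

  nwkPath <- file.path(outDir, "upgma_tree.nwk")
  dend <- upgma(dm)
  writeNewick(dend, nwkPath)
  register("upgma_tree", nwkPath)
  results$upgma <- dend

  results$paths <- file.path(outDir, manifest$path)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
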