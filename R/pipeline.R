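# io_cli module, pipeline half: end-to-end orchestration
# (generate -> solve -> scan -> prioritize -> benchmark) with a checksum
# manifest.

.stageLog <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full demonstration pipeline
#'
#' Generates the paired minicell ME/M models and a simulated paired
#' RNA-Seq/Ribo-Seq dataset, then runs growth maximization, FVA, gene
#' essentiality, a substrate scan, replicate QC, TE and pathway
#' prioritization, and the subsystem-level model-vs-omics benchmark.
#' Every artifact is written under `config$outdir` and listed with its
#' MD5 checksum in `manifest.json`; a fixed seed reproduces identical
#' artifacts (and therefore an identical manifest).
#'
#' @param config a `"RunConfig"` from [runConfig()].
#' @param verbose log one line per stage.
#' @return invisibly, list with `status` (0 on success), `manifest` and
#'   `outdir`. On stage failure the manifest records the failed stage and
#'   `status` is 1; artifacts of completed stages are retained.
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  files <- character(0)
  stages <- list()
  failed <- NULL

  runStage <- function(name, fn) {
    if (!is.null(failed)) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- list(stage = name, message = conditionMessage(res))
      stages[[name]] <<- list(status = "failed",
                              message = conditionMessage(res))
      .stageLog(verbose, name, "FAILED: ", conditionMessage(res))
    } else {
      stages[[name]] <<- list(
        status = "ok",
        seconds = round(as.numeric(Sys.time() - t0), 3))
      .stageLog(verbose, name, "ok")
    }
    invisible(NULL)
  }

  env <- new.env()
  runStage("generate-model", function() {
    mc <- makeMinicell(minicellParams())
    env$mc <- mc
    writeMEModel(mc$me, out("me_model.json"))
    writeMEModel(mc$m, out("m_model.json"))
    files <<- c(files, "me_model.json", "m_model.json")
  })
  runStage("solve", function() {
    env$solME <- maximizeGrowth(env$mc$me, bisectTol = config$bisectTol,
                                tol = config$solverTol)
    env$solM <- maximizeGrowth(env$mc$m, bisectTol = config$bisectTol,
                               tol = config$solverTol)
    writeTsv(data.frame(reaction = names(fluxes(env$solME)),
                        flux = unname(fluxes(env$solME))),
             out("growth_me.tsv"))
    writeRunMetadata(list(seed = config$seed,
                          bisect_tol = config$bisectTol,
                          solver_tol = config$solverTol,
                          mu_star_me = muStar(env$solME),
                          mu_star_m = muStar(env$solM),
                          status = solutionStatus(env$solME)),
                     out("growth_meta.json"))
    files <<- c(files, "growth_me.tsv", "growth_meta.json")
  })
  runStage("fva", function() {
    fme <- fluxVariability(env$mc$me, muStar(env$solME),
                           fraction = config$fvaFraction,
                           tol = config$solverTol)
    fm <- fluxVariability(env$mc$m, muStar(env$solM),
                          fraction = config$fvaFraction,
                          tol = config$solverTol)
    fme$model <- "me"
    fm$model <- "m"
    writeTsv(rbind(fme, fm), out("fva.tsv"))
    files <<- c(files, "fva.tsv")
  })
  runStage("essentiality", function() {
    ess <- vapply(genes(env$mc$me), function(g) {
      geneEssentiality(env$mc$me, g, tol = config$solverTol)
    }, logical(1))
    writeTsv(data.frame(gene = names(ess), essential = unname(ess)),
             out("essentiality.tsv"))
    files <<- c(files, "essentiality.tsv")
  })
  runStage("scan", function() {
    scMe <- substrateScan(env$mc$me, env$mc$params$uptakeExchangeId,
                          config$uptakeValues,
                          bisectTol = config$bisectTol,
                          tol = config$solverTol)
    scM <- substrateScan(env$mc$m, env$mc$params$uptakeExchangeId,
                         config$uptakeValues,
                         bisectTol = config$bisectTol,
                         tol = config$solverTol)
    writeTsv(scMe, out("scan_me.tsv"))
    writeTsv(scM, out("scan_m.tsv"))
    files <<- c(files, "scan_me.tsv", "scan_m.tsv")
  })
  runStage("generate-omics", function() {
    design <- defaultOmicsDesign(seed = config$seed + 101L,
                                 teEffects = config$plantedEffects)
    env$sim <- simulateCounts(design)
    env$pathways <- design@pathways
    writeCounts(env$sim$rna, out("counts_rna.tsv"))
    writeCounts(env$sim$ribo, out("counts_ribo.tsv"))
    writePathwayMap(design@pathways, out("pathways.tsv"))
    writeRunMetadata(list(seed = design@seed,
                          planted = as.list(config$plantedEffects)),
                     out("omics_truth.json"))
    files <<- c(files, "counts_rna.tsv", "counts_ribo.tsv",
                "pathways.tsv", "omics_truth.json")
  })
  runStage("prioritize", function() {
    cr <- cpmNormalize(env$sim$rna)
    cb <- cpmNormalize(env$sim$ribo)
    qc <- replicateQC(cr, config$pccFloor, config$alpha)
    qcb <- replicateQC(cb, config$pccFloor, config$alpha)
    writeRunMetadata(list(rna = list(pass = qc$pass),
                          ribo = list(pass = qcb$pass)),
                     out("qc.json"))
    te <- geneTE(cr, cb)
    writeTsv(te, out("te.tsv"))
    pr <- pathwayPrioritization(te, cr, cb, env$pathways,
                                alpha = config$alpha,
                                minGenes = config$minGenes)
    writeTsv(pr, out("prioritization.tsv"))
    files <<- c(files, "qc.json", "te.tsv", "prioritization.tsv")
  })
  runStage("benchmark", function() {
    me <- env$mc$me
    coupled <- simulateCoupledOmics(me, env$solME,
                                    seed = config$seed + 202L)
    cb <- cpmNormalize(coupled$ribo)
    gmap <- geneSubsystems(me)
    omics <- aggregateSubsystem(
      SummarizedExperiment::assay(cb, "cpm"), gmap, mode = "cpm")
    profMe <- aggregateSubsystem(translationFluxes(me, env$solME), gmap,
                                 mode = "translation_flux")
    rsub <- reactionSubsystems(env$mc$m)
    profM <- aggregateSubsystem(fluxes(env$solM), rsub,
                                mode = "reaction_flux")
    bMe <- correlateProfiles(profMe, omics)
    bM <- correlateProfiles(profM, omics)
    writeRunMetadata(list(
      me = list(pcc = bMe$pcc, p = bMe$p, slope = bMe$slope,
                intercept = bMe$intercept, n = bMe$n),
      m = list(pcc = bM$pcc, p = bM$p, slope = bM$slope,
               intercept = bM$intercept, n = bM$n)),
      out("benchmark.json"))
    files <<- c(files, "benchmark.json")
  })

  sums <- if (length(files)) {
    as.list(tools::md5sum(file.path(config$outdir, files)))
  } else {
    list()
  }
  names(sums) <- files
  manifest <- list(
    package = "meomics",
    version = as.character(packageVersion("meomics")),
    seed = config$seed,
    stages = stages,
    failed = if (is.null(failed)) NULL else failed,
    artifacts = sums)
  writeRunMetadata(manifest, out("manifest.json"))
  invisible(list(status = if (is.null(failed)) 0L else 1L,
                 manifest = manifest, outdir = config$outdir))
}
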