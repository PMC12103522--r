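# io module: versioned JSON model format, TSV count tables and pathway
# maps, result writers with run-metadata sidecars, run configuration.

.ME_FORMAT_VERSION <- "1.0"

#' Write an MEModel to the versioned JSON format
#'
#' The document carries `format_version`, `metabolites`, `reactions` (each
#' with `id`, `subsystem`, bounds and `entries` as `[metabolite, a, b]`
#' triples), `genes`, `translation_of`, `growth_reaction_id`,
#' `expression_subsystems` and `mu_max_hint`. Serialization is
#' deterministic: the same model always yields byte-identical output.
#'
#' @param model an [MEModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readMEModel()]
#' @export
writeMEModel <- function(model, path) {
  stopifnot(is(model, "MEModel"))
  sto <- model@stoichiometry
  rxns <- lapply(seq_len(nrow(model@reactions)), function(i) {
    r <- model@reactions[i, ]
    e <- sto[sto$reaction == r$id, , drop = FALSE]
    list(id = r$id, subsystem = r$subsystem,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         entries = lapply(seq_len(nrow(e)), function(k) {
           list(e$metabolite[k], e$a[k], e$b[k])
         }))
  })
  doc <- list(
    format_version = .ME_FORMAT_VERSION,
    metabolites = model@metabolites,
    reactions = rxns,
    genes = model@genes,
    translation_of = as.list(model@translationOf),
    growth_reaction_id = model@growthReactionId,
    expression_subsystems = model@expressionSubsystems,
    mu_max_hint = model@muMaxHint)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

.need <- function(doc, field) {
  if (is.null(doc[[field]])) {
    stop("model document is missing required field '", field, "'",
         call. = FALSE)
  }
  doc[[field]]
}

#' Read an MEModel from the versioned JSON format
#'
#' All structural invariants (bounds ordering, metabolite references,
#' growth reaction and translation map existence, positive bisection
#' ceiling) are validated on load; violations raise an error naming the
#' offending field or identifier.
#'
#' @param path JSON file written by [writeMEModel()].
#' @return A validated [MEModel-class].
#' @export
readMEModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ver <- .need(doc, "format_version")
  if (!identical(ver, .ME_FORMAT_VERSION)) {
    stop("unknown model format_version '", ver, "' (supported: ",
         .ME_FORMAT_VERSION, ")", call. = FALSE)
  }
  rlist <- .need(doc, "reactions")
  rxn <- do.call(rbind, lapply(rlist, function(r) {
    data.frame(id = .need(r, "id"), lower_bound = .need(r, "lower_bound"),
               upper_bound = .need(r, "upper_bound"),
               subsystem = .need(r, "subsystem"), stringsAsFactors = FALSE)
  }))
  sto <- do.call(rbind, lapply(rlist, function(r) {
    if (!length(r$entries)) return(NULL)
    do.call(rbind, lapply(r$entries, function(e) {
      data.frame(reaction = r$id, metabolite = as.character(e[[1]]),
                 a = as.numeric(e[[2]]), b = as.numeric(e[[3]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  tl <- unlist(doc$translation_of %||% list())
  if (is.null(tl)) tl <- setNames(character(0), character(0))
  MEModel(metabolites = unlist(.need(doc, "metabolites")),
          reactions = rxn, stoichiometry = sto,
          genes = unlist(doc$genes %||% list()) %||% character(0),
          translationOf = tl,
          growthReactionId = .need(doc, "growth_reaction_id"),
          expressionSubsystems =
            unlist(doc$expression_subsystems %||% list()) %||% character(0),
          muMaxHint = .need(doc, "mu_max_hint"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write counts to TSV
#'
#' First column `gene`, one column per sample named `assay_replicate`.
#'
#' @param counts `SummarizedExperiment` with a `counts` assay.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path) {
  m <- .assayMatrix(counts, "counts")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read counts from TSV
#'
#' Expects the layout written by [writeCounts()]: a `gene` column and
#' sample columns named `assay_replicate` with assay `rna` or `ribo`.
#' Parsing is strict: negative, fractional or missing counts and
#' duplicated gene ids raise errors locating the offending cell.
#'
#' @param path TSV file.
#' @return A count `SummarizedExperiment` (see [countMatrix()]).
#' @export
loadCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") {
    stop("first column must be 'gene', got '", names(df)[1], "'",
         call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene id(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  samples <- names(df)[-1]
  m <- regmatches(samples, regexec("^(rna|ribo)_([0-9]+)$", samples))
  bad <- samples[vapply(m, length, integer(1)) == 0]
  if (length(bad)) {
    stop("sample column(s) not named assay_replicate: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- as.matrix(df[, -1, drop = FALSE])
  rownames(cm) <- df$gene
  for (j in seq_len(ncol(cm))) {
    v <- cm[, j]
    badRow <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(badRow)) {
      stop("invalid count at row ", badRow[1], " (gene ",
           rownames(cm)[badRow[1]], "), column ", samples[j], call. = FALSE)
    }
  }
  storage.mode(cm) <- "integer"
  countMatrix(cm,
              assay = vapply(m, `[`, character(1), 2L),
              replicate = as.integer(vapply(m, `[`, character(1), 3L)))
}

#' Read or write a gene-to-pathway map (TSV, one row per pair)
#'
#' @param path TSV file with columns `gene` and `pathway`.
#' @return `loadPathwayMap`: named list of gene-id vectors.
#' @export
loadPathwayMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(df))) {
    stop("pathway map needs columns 'gene' and 'pathway'", call. = FALSE)
  }
  split(df$gene, df$pathway)
}

#' @rdname loadPathwayMap
#' @param pathways named list of gene-id vectors.
#' @export
writePathwayMap <- function(pathways, path) {
  df <- data.frame(
    gene = unlist(pathways, use.names = FALSE),
    pathway = rep(names(pathways), lengths(pathways)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run-metadata sidecar
#'
#' @param meta named list (seed, tolerances, bounds, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunMetadata <- function(meta, path) {
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' One seed drives the whole pipeline; per-stage child seeds are derived
#' deterministically from it so module-level reruns reproduce pipeline
#' results.
#'
#' @param seed integer master seed.
#' @param outdir output directory for artifacts.
#' @param solverTol LP feasibility tolerance.
#' @param bisectTol growth bisection tolerance (1/h).
#' @param alpha significance level for prioritization and QC.
#' @param pccFloor replicate-correlation floor.
#' @param minGenes minimum included genes per testable pathway.
#' @param fvaFraction fraction of the growth optimum at which FVA fixes
#'   the growth flux.
#' @param uptakeValues substrate-scan uptake grid.
#' @param plantedEffects named per-pathway TE effects for the simulated
#'   omics stage.
#' @return validated list of class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1L, outdir = tempfile("meomics_run_"),
                      solverTol = 1e-9, bisectTol = 1e-6, alpha = 0.05,
                      pccFloor = 0.9, minGenes = 3L, fvaFraction = 1.0,
                      uptakeValues = seq(1, 20, by = 1),
                      plantedEffects = c(pw01 = 2)) {
  uptakeValues <- as.numeric(unlist(uptakeValues))
  plantedEffects <- unlist(plantedEffects)
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              solverTol = solverTol, bisectTol = bisectTol, alpha = alpha,
              pccFloor = pccFloor, minGenes = as.integer(minGenes),
              fvaFraction = fvaFraction, uptakeValues = uptakeValues,
              plantedEffects = plantedEffects)
  if (cfg$solverTol <= 0 || cfg$bisectTol <= 0) {
    stop("config validation: tolerances must be positive", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config validation: alpha must be in (0, 1)", call. = FALSE)
  }
  if (cfg$pccFloor <= 0 || cfg$pccFloor >= 1) {
    stop("config validation: pccFloor must be in (0, 1)", call. = FALSE)
  }
  if (cfg$fvaFraction <= 0 || cfg$fvaFraction > 1) {
    stop("config validation: fvaFraction must be in (0, 1]", call. = FALSE)
  }
  if (cfg$minGenes < 2L) {
    stop("config validation: minGenes must be >= 2", call. = FALSE)
  }
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param path JSON file.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  doc <- unclass(cfg)
  # jsonlite drops the names of atomic vectors; effects must stay keyed
  doc$plantedEffects <- as.list(doc$plantedEffects)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname runConfig
#' @param cfg a `"RunConfig"` object.
#' @export
readRunConfig <- function(path) {
  doc <- jsonlite::fromJSON(path)
  do.call(runConfig, doc)
}
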