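#' @import methods
#' @importFrom stats rnorm rnbinom setNames cor cor.test t.test wilcox.test
#'   lm coef confint p.adjust complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

#' MEModel: a growth-rate-parameterized stoichiometric model
#'
#' An `MEModel` couples a metabolic network to its expression machinery by
#' letting each stoichiometric coefficient depend affinely on the growth rate
#' \eqn{\mu}: the coefficient of metabolite \eqn{m} in reaction \eqn{r} at
#' growth rate \eqn{\mu} is \eqn{a + b\mu}. Pure metabolic stoichiometry has
#' \eqn{b = 0}; enzyme usage of a reaction running at flux \eqn{v} with
#' effective catalytic rate \eqn{k_{\mathrm{eff}}} appears as
#' \eqn{b = -1/k_{\mathrm{eff}}} on the enzyme species (the enzyme pool
#' \eqn{v/k_{\mathrm{eff}}} is diluted by growth at rate \eqn{\mu}); ribosome
#' occupancy during translation of a protein of length \eqn{L} appears as
#' \eqn{b = -L/c} where \eqn{c} is the ribosome elongation capacity in amino
#' acids per hour.
#'
#' At a fixed \eqn{\mu} the model is an ordinary linear feasibility problem
#' \eqn{S(\mu) v = 0}, \eqn{lb \le v \le ub}, \eqn{v_{\mathrm{growth}} = \mu}.
#'
#' @slot metabolites character vector of metabolite identifiers.
#' @slot reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound` (mmol/gDW/h), `subsystem`.
#' @slot stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `a` (dimensionless), `b` (per 1/h); the coefficient at growth rate mu
#'   is `a + b * mu`. Several rows for the same (reaction, metabolite) pair
#'   are summed.
#' @slot genes character vector of gene identifiers.
#' @slot translationOf named character: for each gene, the identifier of its
#'   translation reaction.
#' @slot growthReactionId identifier of the biomass/growth reaction whose
#'   flux is the growth rate mu (1/h).
#' @slot expressionSubsystems subsystem labels that belong to the expression
#'   machinery (translation, proteome budget, ...); [stripExpression()]
#'   removes reactions in these subsystems.
#' @slot muMaxHint upper bracket (1/h) for growth-maximization bisection.
#'
#' @seealso [MEModel()], [maximizeGrowth()], [stripExpression()]
#' @export
setClass("MEModel",
  representation(
    metabolites = "character",
    reactions = "data.frame",
    stoichiometry = "data.frame",
    genes = "character",
    translationOf = "character",
    growthReactionId = "character",
    expressionSubsystems = "character",
    muMaxHint = "numeric"
  )
)

.validMEModel <- function(object) {
  msg <- character(0)
  rxn <- object@reactions
  sto <- object@stoichiometry
  need <- c("id", "lower_bound", "upper_bound", "subsystem")
  if (!all(need %in% names(rxn))) {
    return(paste("reactions must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(c("reaction", "metabolite", "a", "b") %in% names(sto))) {
    return("stoichiometry must have columns: reaction, metabolite, a, b")
  }
  if (anyDuplicated(object@metabolites)) {
    msg <- c(msg, "duplicated metabolite identifiers")
  }
  if (anyDuplicated(rxn$id)) {
    msg <- c(msg, "duplicated reaction identifiers")
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    msg <- c(msg, paste("lower_bound > upper_bound for:",
                        paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(rxn$lower_bound)) || !all(is.finite(rxn$upper_bound))) {
    msg <- c(msg, "reaction bounds must be finite")
  }
  badm <- setdiff(sto$metabolite, object@metabolites)
  if (length(badm)) {
    msg <- c(msg, paste("stoichiometry references unknown metabolites:",
                        paste(unique(badm), collapse = ", ")))
  }
  badr <- setdiff(sto$reaction, rxn$id)
  if (length(badr)) {
    msg <- c(msg, paste("stoichiometry references unknown reactions:",
                        paste(unique(badr), collapse = ", ")))
  }
  if (!all(is.finite(sto$a)) || !all(is.finite(sto$b))) {
    msg <- c(msg, "stoichiometric coefficients must be finite")
  }
  if (length(object@growthReactionId) != 1L ||
      !(object@growthReactionId %in% rxn$id)) {
    msg <- c(msg, "growth_reaction_id must name an existing reaction")
  }
  if (length(object@translationOf)) {
    if (is.null(names(object@translationOf)) ||
        !all(names(object@translationOf) %in% object@genes)) {
      msg <- c(msg, "translation_of must be named by known genes")
    }
    badt <- setdiff(object@translationOf, rxn$id)
    if (length(badt)) {
      msg <- c(msg, paste("translation_of maps to unknown reactions:",
                          paste(badt, collapse = ", ")))
    }
  }
  if (length(object@muMaxHint) != 1L || !is.finite(object@muMaxHint) ||
      object@muMaxHint <= 0) {
    msg <- c(msg, "mu_max_hint must be a single positive number")
  }
  if (object@growthReactionId %in% rxn$id) {
    gsub_ <- rxn$subsystem[match(object@growthReactionId, rxn$id)]
    if (gsub_ %in% object@expressionSubsystems) {
      msg <- c(msg, "growth reaction must not belong to an expression subsystem")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("MEModel", .validMEModel)

#' Construct an MEModel
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `subsystem`.
#' @param stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `a`, `b`.
#' @param genes character vector of gene ids (may be empty).
#' @param translationOf named character mapping genes to their translation
#'   reactions.
#' @param growthReactionId id of the growth (biomass) reaction.
#' @param expressionSubsystems subsystem labels treated as expression
#'   machinery.
#' @param muMaxHint upper bisection bracket for the growth rate (1/h).
#' @return A validated [MEModel-class] object.
#' @examples
#' toy <- MEModel(
#'   metabolites = "m",
#'   reactions = data.frame(
#'     id = c("in", "grow"), lower_bound = c(0, 0),
#'     upper_bound = c(5, 1000), subsystem = c("Uptake", "Biomass")),
#'   stoichiometry = data.frame(
#'     reaction = c("in", "grow"), metabolite = c("m", "m"),
#'     a = c(1, -10), b = c(0, 0)),
#'   growthReactionId = "grow", muMaxHint = 2)
#' maximizeGrowth(toy)
#' @export
MEModel <- function(metabolites, reactions, stoichiometry,
                    genes = character(0),
                    translationOf = setNames(character(0), character(0)),
                    growthReactionId, expressionSubsystems = character(0),
                    muMaxHint = 2) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  rownames(reactions) <- NULL
  rownames(stoichiometry) <- NULL
  new("MEModel",
      metabolites = as.character(metabolites),
      reactions = reactions,
      stoichiometry = stoichiometry,
      genes = as.character(genes),
      translationOf = translationOf,
      growthReactionId = growthReactionId,
      expressionSubsystems = as.character(expressionSubsystems),
      muMaxHint = as.numeric(muMaxHint))
}

setMethod("show", "MEModel", function(object) {
  cat("MEModel with", length(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      length(object@genes), "genes\n")
  cat("  growth reaction:", object@growthReactionId,
      " mu_max_hint:", object@muMaxHint, "\n")
  nmu <- sum(object@stoichiometry$b != 0)
  cat("  mu-dependent coefficients:", nmu, "of", nrow(object@stoichiometry),
      "\n")
  if (length(object@expressionSubsystems)) {
    cat("  expression subsystems:",
        paste(object@expressionSubsystems, collapse = ", "), "\n")
  }
})

#' GrowthSolution: result of growth maximization
#'
#' @slot muStar optimal growth rate (1/h); `NA` when infeasible at the floor.
#' @slot fluxes named numeric flux vector (mmol/gDW/h) at `muStar`.
#' @slot status `"optimal"` or `"infeasible_at_floor"`.
#' @slot notes character; diagnostic flags (e.g. non-monotone feasibility
#'   observed during bisection).
#' @export
setClass("GrowthSolution",
  representation(muStar = "numeric", fluxes = "numeric", status = "character",
                 notes = "character"))

setMethod("show", "GrowthSolution", function(object) {
  cat("GrowthSolution: status =", object@status, "\n")
  if (object@status == "optimal") {
    cat("  mu* =", format(object@muStar, digits = 8), "1/h;",
        length(object@fluxes), "fluxes\n")
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' OmicsDesign: seeded design for paired RNA-Seq/Ribo-Seq simulation
#'
#' Gene baseline abundances are hierarchical: each pathway draws a baseline
#' log-abundance from Normal(`meanlog`, `sdlogBetween`) and its genes scatter
#' around it with `sdlogWithin` (natural-log scale). Genes outside any
#' pathway draw from the marginal Normal(`meanlog`,
#' sqrt(`sdlogBetween`^2 + `sdlogWithin`^2)). This mimics co-regulated
#' (operonic) bacterial pathways: the population of pathway means spans
#' several orders of magnitude while genes within one pathway stay within a
#' fold-change band.
#'
#' Per-gene translational efficiency is
#' `TE_g = teEffects[pathway(g)] * Lognormal(0, sdlogTE)`; RNA counts are
#' negative binomial around `abundance * depth`, Ribo counts around
#' `abundance * TE * depth` (each assay renormalized to its library size, as
#' sequencing is compositional).
#'
#' @slot nGenes number of genes.
#' @slot geneIds gene identifiers (length `nGenes`).
#' @slot pathways named list mapping pathway labels to gene-id vectors
#'   (disjoint subsets of the gene universe).
#' @slot nReplicates biological replicates per assay (>= 2).
#' @slot depth expected sequencing depth per sample (reads).
#' @slot meanlog,sdlogBetween,sdlogWithin log-normal abundance parameters
#'   (natural-log scale).
#' @slot dispersion NB dispersion (1/size); scalar or per gene.
#' @slot teEffects named numeric: multiplicative TE effect per pathway
#'   (1 = null).
#' @slot sdlogTE gene-level TE noise (natural-log sd).
#' @slot depthFactorSdlog library-size variation between replicates
#'   (natural-log sd).
#' @slot abundance optional per-gene relative abundance overriding the
#'   log-normal draw (length 0 or `nGenes`).
#' @slot seed RNG seed.
#' @export
setClass("OmicsDesign",
  representation(
    nGenes = "integer", geneIds = "character", pathways = "list",
    nReplicates = "integer", depth = "numeric",
    meanlog = "numeric", sdlogBetween = "numeric", sdlogWithin = "numeric",
    dispersion = "numeric", teEffects = "numeric", sdlogTE = "numeric",
    depthFactorSdlog = "numeric", abundance = "numeric", seed = "integer"))

.validOmicsDesign <- function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@geneIds) != object@nGenes ||
      anyDuplicated(object@geneIds)) {
    msg <- c(msg, "geneIds must be nGenes unique identifiers")
  }
  pg <- unlist(object@pathways, use.names = FALSE)
  if (length(setdiff(pg, object@geneIds))) {
    msg <- c(msg, paste("pathways reference unknown genes:",
                        paste(setdiff(pg, object@geneIds), collapse = ", ")))
  }
  if (anyDuplicated(pg)) {
    msg <- c(msg, "generator pathways must be disjoint gene sets")
  }
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (any(object@dispersion <= 0)) msg <- c(msg, "dispersion must be positive")
  if (!(length(object@dispersion) %in% c(1L, object@nGenes))) {
    msg <- c(msg, "dispersion must have length 1 or nGenes")
  }
  if (length(object@teEffects)) {
    if (is.null(names(object@teEffects)) ||
        !all(names(object@teEffects) %in% names(object@pathways))) {
      msg <- c(msg, "teEffects must be named by known pathways")
    }
    if (any(object@teEffects <= 0)) msg <- c(msg, "teEffects must be positive")
  }
  if (object@sdlogBetween < 0 || object@sdlogWithin < 0 ||
      object@sdlogTE < 0 || object@depthFactorSdlog < 0) {
    msg <- c(msg, "log-scale sd parameters must be nonnegative")
  }
  if (!(length(object@abundance) %in% c(0L, object@nGenes))) {
    msg <- c(msg, "abundance override must have length 0 or nGenes")
  }
  if (length(object@abundance) && any(object@abundance < 0)) {
    msg <- c(msg, "abundance override must be nonnegative")
  }
  if (length(msg)) msg else TRUE
}

setValidity("OmicsDesign", .validOmicsDesign)

setMethod("show", "OmicsDesign", function(object) {
  cat("OmicsDesign:", object@nGenes, "genes,",
      length(object@pathways), "pathways,",
      object@nReplicates, "replicates/assay, depth",
      format(object@depth, big.mark = ","), "\n")
  planted <- object@teEffects[object@teEffects != 1]
  if (length(planted)) {
    cat("  planted TE effects:",
        paste(sprintf("%s=%.2g", names(planted), planted), collapse = ", "),
        "\n")
  } else {
    cat("  null design (all TE effects = 1)\n")
  }
  cat("  seed:", object@seed, "\n")
})
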