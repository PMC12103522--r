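# Toy ME-model generator ("minicell"): a substrate exchange feeding a
# high-yield but proteome-expensive respiration branch (plus a redundant,
# less efficient isozyme), a low-yield proteome-cheap overflow branch that
# secretes its by-product, a set of small biosynthesis modules, and a
# minimal expression sector: one translation reaction per enzyme and a
# self-replicating ribosome. Every unit of catalytic flux drags a
# growth-rate-dependent expression cost (enzyme dilution mu/keff, ribosome
# occupancy mu*L/c, amino-acid drain on the biomass precursor), and the
# respiratory machinery additionally has a finite expression capacity
# (a bound on its translation flux). Growth is therefore uptake-limited
# when substrate is scarce and proteome-limited when it is abundant: the
# growth curve is strictly concave and saturates, and once the
# respiratory expression capacity binds, extra substrate spills through
# the cheap overflow branch whose product is secreted at a rate rising
# continuously from zero. The M-analog obtained by stripExpression()
# shows neither feature.

#' Parameters of the minicell generator
#'
#' Defaults place the overflow onset near uptake 5 mmol/gDW/h, growth at
#' the reference uptake of 10 around 0.46 1/h, and an asymptotic
#' proteome-limited ceiling below 1/h. Two invariants are enforced at
#' construction: respiration must have the higher biomass yield *and* the
#' higher proteome cost (protein length over catalytic rate) than
#' overflow; otherwise overflow metabolism cannot arise and generation
#' aborts.
#'
#' The decisive quantity is each branch's effective biomass return per
#' substrate at growth rate mu,
#' \deqn{s_i(\mu) = Y_i - m_{aa}\, \mu\, g(\mu)\, L_i/k_{eff,i},}
#' where \eqn{g(\mu) = 1/(1 - \mu L_{rib}/c)} accounts for the ribosome
#' translating itself. Below the onset all substrate is respired; when
#' the respiratory expression capacity `respTranslationCap` saturates,
#' each extra unit of uptake flows through the overflow branch, whose
#' lower return makes the growth curve bend while its product
#' accumulates in the medium.
#'
#' @param yieldRespiration,yieldOverflow biomass yield per substrate
#'   (gDW/mmol) of the two catabolic branches.
#' @param keffRespiration,keffIsozyme,keffOverflow effective catalytic
#'   rates (1/h) of the respiration enzyme, its redundant isozyme, and the
#'   overflow enzyme.
#' @param lengthRespiration,lengthIsozyme,lengthOverflow,lengthRibosome
#'   protein lengths in amino acids (`lengthRibosome` is the full
#'   polymerization cost of one ribosome equivalent).
#' @param ribosomeCapacity ribosome elongation capacity (aa/(h*ribosome));
#'   `ribosomeCapacity / lengthRibosome` is the hard growth ceiling at
#'   which a ribosome can no longer replicate itself.
#' @param aaMass biomass-precursor cost per amino acid polymerized
#'   (gDW-equivalent/mmol aa).
#' @param respTranslationCap upper bound (mmol protein/gDW/h) on the
#'   translation flux of each respiratory enzyme: a finite expression
#'   capacity for membrane-bound respiratory machinery. Once it binds,
#'   additional substrate can only be catabolized through the overflow
#'   branch, which makes overflow secretion rise continuously from zero at
#'   a finite uptake threshold.
#' @param nAux number of auxiliary biosynthesis modules, each with its own
#'   enzyme, gene and subsystem.
#' @param auxFraction fraction of biomass drawn through the auxiliary
#'   modules (split evenly).
#' @param auxKeff,auxLength per-module catalytic rates and protein lengths
#'   (recycled to length `nAux`).
#' @param uptakeBound default substrate uptake bound (mmol/gDW/h).
#' @param secretionCap upper bound on secretion exchanges.
#' @param innerCap generic large bound on internal reactions.
#' @param uptakeExchangeId identifier of the substrate exchange reaction.
#' @param includeOverflow set `FALSE` to delete the overflow branch.
#' @param muMaxHint bisection ceiling stored in the model (1/h).
#' @return A validated parameter list of class `"MinicellParams"`.
#' @seealso [makeMinicell()], [randomMinicellParams()]
#' @export
minicellParams <- function(yieldRespiration = 0.1, yieldOverflow = 0.07,
                           keffRespiration = 2000, keffIsozyme = 1000,
                           keffOverflow = 3000,
                           lengthRespiration = 800, lengthIsozyme = 800,
                           lengthOverflow = 600, lengthRibosome = 30000,
                           ribosomeCapacity = 30000, aaMass = 0.15,
                           respTranslationCap = 7e-4,
                           nAux = 6L, auxFraction = 0.3,
                           auxKeff = c(600, 1000, 1500, 2000, 2600, 3200),
                           auxLength = c(250, 400, 550, 700, 850, 1000),
                           uptakeBound = 10, secretionCap = 1000,
                           innerCap = 1000,
                           uptakeExchangeId = "EX_glc",
                           includeOverflow = TRUE, muMaxHint = 3) {
  p <- list(yieldRespiration = yieldRespiration,
            yieldOverflow = yieldOverflow,
            keffRespiration = keffRespiration, keffIsozyme = keffIsozyme,
            keffOverflow = keffOverflow,
            lengthRespiration = lengthRespiration,
            lengthIsozyme = lengthIsozyme,
            lengthOverflow = lengthOverflow,
            lengthRibosome = lengthRibosome,
            ribosomeCapacity = ribosomeCapacity, aaMass = aaMass,
            respTranslationCap = respTranslationCap,
            nAux = as.integer(nAux), auxFraction = auxFraction,
            auxKeff = rep_len(auxKeff, nAux),
            auxLength = rep_len(auxLength, nAux),
            uptakeBound = uptakeBound, secretionCap = secretionCap,
            innerCap = innerCap, uptakeExchangeId = uptakeExchangeId,
            includeOverflow = isTRUE(includeOverflow),
            muMaxHint = muMaxHint)
  pos <- c("yieldRespiration", "yieldOverflow", "keffRespiration",
           "keffIsozyme", "keffOverflow", "lengthRespiration",
           "lengthIsozyme", "lengthOverflow", "lengthRibosome",
           "ribosomeCapacity", "aaMass", "respTranslationCap", "uptakeBound",
           "secretionCap", "innerCap", "muMaxHint")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop("minicell parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$nAux < 0L) stop("nAux must be nonnegative", call. = FALSE)
  if (p$nAux > 0L && (p$auxFraction <= 0 || p$auxFraction >= 1)) {
    stop("auxFraction must be in (0, 1)", call. = FALSE)
  }
  if (any(p$auxKeff <= 0) || any(p$auxLength <= 0)) {
    stop("auxiliary keff and lengths must be positive", call. = FALSE)
  }
  if (p$yieldRespiration <= p$yieldOverflow) {
    stop("generation error: respiration must have higher yield than overflow",
         call. = FALSE)
  }
  costR <- p$lengthRespiration / p$keffRespiration
  costO <- p$lengthOverflow / p$keffOverflow
  if (costR <= costO) {
    stop("generation error: respiration must have higher proteome cost ",
         "(length/keff) than overflow", call. = FALSE)
  }
  structure(p, class = "MinicellParams")
}

#' Seeded random minicell parameter variants
#'
#' Draws a parameter set from ranges within which the minicell invariants
#' (respiration higher-yield and higher-cost than overflow) hold by
#' construction. Used to exercise the solver across many model shapes.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [minicellParams()].
#' @return A `"MinicellParams"` list.
#' @export
randomMinicellParams <- function(seed, ...) {
  set.seed(as.integer(seed))
  yR <- stats::runif(1, 0.08, 0.12)
  nAux <- 6L
  draws <- list(
    yieldRespiration = yR,
    yieldOverflow = yR * stats::runif(1, 0.55, 0.8),
    keffRespiration = stats::runif(1, 1500, 2500),
    keffIsozyme = stats::runif(1, 700, 1300),
    keffOverflow = stats::runif(1, 2500, 3500),
    lengthRespiration = stats::runif(1, 600, 1000),
    lengthIsozyme = stats::runif(1, 600, 1000),
    respTranslationCap = stats::runif(1, 5e-4, 1.2e-3),
    lengthRibosome = stats::runif(1, 24000, 36000),
    ribosomeCapacity = stats::runif(1, 28000, 34000),
    auxKeff = stats::runif(nAux, 500, 3000),
    auxLength = stats::runif(nAux, 200, 1000),
    nAux = nAux)
  # overflow proteome cost drawn as a fraction of respiration's, so the
  # cost-ordering invariant holds for every seed
  draws$lengthOverflow <- draws$keffOverflow *
    (draws$lengthRespiration / draws$keffRespiration) *
    stats::runif(1, 0.35, 0.65)
  args <- utils::modifyList(draws, list(...))
  do.call(minicellParams, args)
}

#' Generate a paired toy ME model and its M-analog
#'
#' Assembles the minicell [MEModel-class] described in
#' [minicellParams()] and the metabolism-only analog obtained by
#' [stripExpression()]. Construction fails with a diagnostic if the
#' parameter combination admits no growth at the reference uptake bound.
#'
#' @param params a `"MinicellParams"` list.
#' @param check verify feasibility at a small reference growth rate
#'   (default `TRUE`).
#' @return list with elements `me` (coupled model), `m` (stripped analog)
#'   and `params`.
#' @examples
#' mc <- makeMinicell()
#' mc$me
#' muStar(maximizeGrowth(mc$me))
#' @export
makeMinicell <- function(params = minicellParams(), check = TRUE) {
  stopifnot(inherits(params, "MinicellParams"))
  p <- params
  k <- seq_len(p$nAux)
  auxCmp <- sprintf("cmp_aux%d", k)
  auxProt <- sprintf("prot_aux%d", k)
  auxSyn <- sprintf("SYN_aux%d", k)
  auxTl <- sprintf("TL_aux%d", k)
  auxGene <- sprintf("g_aux%d", k)
  auxSub <- sprintf("Biosynthesis_%d", k)

  mets <- c("glc", "bm", if (p$includeOverflow) "ace", auxCmp,
            "rib", "prot_resp", "prot_resp2",
            if (p$includeOverflow) "prot_ovf", auxProt)

  rxn <- list()
  sto <- list()
  addRxn <- function(id, lb, ub, subsystem, entries) {
    rxn[[length(rxn) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, subsystem = subsystem,
      stringsAsFactors = FALSE)
    sto[[length(sto) + 1L]] <<- data.frame(
      reaction = id, metabolite = names(entries),
      a = vapply(entries, `[`, numeric(1), 1L),
      b = vapply(entries, `[`, numeric(1), 2L),
      stringsAsFactors = FALSE)
  }
  ent <- function(...) {
    e <- list(...)
    lapply(e, function(x) if (length(x) == 1L) c(x, 0) else x)
  }

  cRib <- p$ribosomeCapacity
  addRxn(p$uptakeExchangeId, -p$uptakeBound, 0, "Exchange",
         ent(glc = -1))
  if (p$includeOverflow) {
    addRxn("EX_ace", 0, p$secretionCap, "Exchange", ent(ace = -1))
  }
  addRxn("RESP", 0, p$innerCap, "Respiration",
         ent(glc = -1, bm = p$yieldRespiration,
             prot_resp = c(0, -1 / p$keffRespiration)))
  addRxn("RESP2", 0, p$innerCap, "Respiration",
         ent(glc = -1, bm = p$yieldRespiration,
             prot_resp2 = c(0, -1 / p$keffIsozyme)))
  if (p$includeOverflow) {
    addRxn("OVF", 0, p$innerCap, "Overflow",
           ent(glc = -1, bm = p$yieldOverflow, ace = 1,
               prot_ovf = c(0, -1 / p$keffOverflow)))
  }
  w <- if (p$nAux > 0L) rep(p$auxFraction / p$nAux, p$nAux) else numeric(0)
  for (i in k) {
    e <- ent(bm = -1)
    e[[auxCmp[i]]] <- c(1, 0)
    e[[auxProt[i]]] <- c(0, -1 / p$auxKeff[i])
    addRxn(auxSyn[i], 0, p$innerCap, auxSub[i], e)
  }
  bmShare <- if (p$nAux > 0L) 1 - p$auxFraction else 1
  eb <- ent(bm = -bmShare)
  for (i in k) eb[[auxCmp[i]]] <- c(-w[i], 0)
  addRxn("BIOMASS", 0, p$innerCap, "Biomass", eb)

  addTl <- function(id, prot, len, cap = p$innerCap) {
    e <- ent(bm = -p$aaMass * len)
    e[["rib"]] <- if (prot == "rib") c(1, -len / cRib) else c(0, -len / cRib)
    if (prot != "rib") e[[prot]] <- c(1, 0)
    addRxn(id, 0, cap, "Translation", e)
  }
  addTl("TL_resp", "prot_resp", p$lengthRespiration,
        cap = p$respTranslationCap)
  addTl("TL_resp2", "prot_resp2", p$lengthIsozyme,
        cap = p$respTranslationCap)
  if (p$includeOverflow) addTl("TL_ovf", "prot_ovf", p$lengthOverflow)
  for (i in k) addTl(auxTl[i], auxProt[i], p$auxLength[i])
  addTl("TL_rib", "rib", p$lengthRibosome)

  gg <- c("g_resp", "g_resp2", if (p$includeOverflow) "g_ovf", auxGene,
          "g_rib")
  tl <- setNames(c("TL_resp", "TL_resp2", if (p$includeOverflow) "TL_ovf",
                   auxTl, "TL_rib"), gg)

  me <- MEModel(metabolites = mets,
                reactions = do.call(rbind, rxn),
                stoichiometry = do.call(rbind, sto),
                genes = gg, translationOf = tl,
                growthReactionId = "BIOMASS",
                expressionSubsystems = "Translation",
                muMaxHint = p$muMaxHint)
  if (check && !isFeasible(me, 1e-3)) {
    stop("generation error: minicell infeasible at mu = 1e-3 under the ",
         "reference uptake bound; yields or expression costs are too ",
         "restrictive", call. = FALSE)
  }
  list(me = me, m = stripExpression(me), params = params)
}
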