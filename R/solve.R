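# me_core operations: stoichiometry evaluation, feasibility, growth
# bisection, FVA, essentiality, substrate scans, expression stripping.

# dense S(mu) in model reaction order (columns) / metabolite order (rows)
.denseSmu <- function(model, mu) {
  sto <- model@stoichiometry
  S <- matrix(0, length(model@metabolites), nrow(model@reactions),
              dimnames = list(model@metabolites, model@reactions$id))
  if (nrow(sto)) {
    coef <- sto$a + sto$b * mu
    i <- match(sto$metabolite, model@metabolites)
    j <- match(sto$reaction, model@reactions$id)
    for (k in seq_along(coef)) S[i[k], j[k]] <- S[i[k], j[k]] + coef[k]
  }
  S
}

# bounds with the growth flux pinned to mu; NULL if mu violates the growth
# reaction's own bounds (the pinned LP is then trivially infeasible)
.boundsAtMu <- function(model, mu, tol = 1e-9) {
  rxn <- model@reactions
  g <- match(model@growthReactionId, rxn$id)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  if (mu < lb[g] - tol || mu > ub[g] + tol) return(NULL)
  lb[g] <- mu
  ub[g] <- mu
  list(lb = lb, ub = ub, growthIndex = g)
}

#' Evaluate the growth-rate-dependent stoichiometric matrix
#'
#' Builds the sparse metabolite-by-reaction matrix \eqn{S(\mu)} whose entry
#' for metabolite \eqn{m} in reaction \eqn{r} is the sum over that
#' reaction's coefficient entries of \eqn{a + b\mu}.
#'
#' @param model an [MEModel-class].
#' @param mu growth rate (1/h), nonnegative.
#' @param ... unused.
#' @return A [Matrix::sparseMatrix()] (metabolites x reactions) with
#'   dimnames.
#' @examples
#' mc <- makeMinicell()
#' S <- evaluateStoichiometry(mc$me, 0.2)
#' dim(S)
#' @rdname evaluateStoichiometry
#' @export
setMethod("evaluateStoichiometry", "MEModel", function(model, mu, ...) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (mu < 0) stop("mu must be nonnegative", call. = FALSE)
  sto <- model@stoichiometry
  Matrix::sparseMatrix(
    i = match(sto$metabolite, model@metabolites),
    j = match(sto$reaction, model@reactions$id),
    x = sto$a + sto$b * mu,
    dims = c(length(model@metabolites), nrow(model@reactions)),
    dimnames = list(model@metabolites, model@reactions$id))
})

#' Test LP feasibility of an MEModel at a fixed growth rate
#'
#' Decides whether \eqn{\{S(\mu)v = 0,\ lb \le v \le ub,\
#' v_{\mathrm{growth}} = \mu\}} admits a feasible flux vector. This is the
#' primitive under growth maximization, gene essentiality and the grid
#' oracles: a model grows at rate `mu` iff this LP is feasible.
#'
#' @param model an [MEModel-class].
#' @param mu growth rate to test (1/h).
#' @param tol solver feasibility tolerance (default `1e-9`, double
#'   precision).
#' @param ... unused.
#' @return `TRUE`/`FALSE`.
#' @rdname isFeasible
#' @export
setMethod("isFeasible", "MEModel", function(model, mu, tol = 1e-9, ...) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (mu < 0) stop("mu must be nonnegative", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  bd <- .boundsAtMu(model, mu, tol)
  if (is.null(bd)) return(FALSE)
  .lpFeasiblePoint(.denseSmu(model, mu), bd$lb, bd$ub, tol)$feasible
})

# feasibility + the feasible point (internal; avoids re-solving)
.feasiblePointAtMu <- function(model, mu, tol = 1e-9) {
  bd <- .boundsAtMu(model, mu, tol)
  if (is.null(bd)) return(list(feasible = FALSE, v = NULL))
  .lpFeasiblePoint(.denseSmu(model, mu), bd$lb, bd$ub, tol)
}

#' Maximize growth rate by bisection over LP feasibility
#'
#' Growth maximization is a one-dimensional search: feasibility of the
#' fixed-\eqn{\mu} LP is monotone non-increasing in \eqn{\mu} (growing
#' faster only adds dilution and machinery cost), so the largest feasible
#' growth rate is found by bisection between a feasible floor `muLo` and an
#' infeasible ceiling `muHi`.
#'
#' @param model an [MEModel-class].
#' @param muLo lower bracket (1/h); must be feasible, else the returned
#'   status is `"infeasible_at_floor"`.
#' @param muHi upper bracket (1/h); must be infeasible, else an error asks
#'   the caller to raise it. Defaults to the model's `muMaxHint`.
#' @param bisectTol termination width of the bracket (1/h).
#' @param tol LP feasibility tolerance.
#' @param ... unused.
#' @return A [GrowthSolution-class]: `muStar` feasible with
#'   `muStar + bisectTol` infeasible, and the flux vector of the feasible
#'   LP solution at `muStar`.
#' @examples
#' mc <- makeMinicell()
#' sol <- maximizeGrowth(mc$me)
#' muStar(sol)
#' @rdname maximizeGrowth
#' @export
setMethod("maximizeGrowth", "MEModel",
          function(model, muLo = 0, muHi = muMaxHint(model),
                   bisectTol = 1e-6, tol = 1e-9, ...) {
  stopifnot(bisectTol > 0, tol > 0)
  if (!(muLo >= 0 && muLo < muHi)) {
    stop("need 0 <= muLo < muHi", call. = FALSE)
  }
  if (isFeasible(model, muHi, tol)) {
    stop("muHi = ", muHi, " is still feasible; raise muHi (bracket error)",
         call. = FALSE)
  }
  at_lo <- .feasiblePointAtMu(model, muLo, tol)
  if (!at_lo$feasible) {
    return(new("GrowthSolution", muStar = NA_real_,
               fluxes = numeric(0), status = "infeasible_at_floor",
               notes = character(0)))
  }
  lo <- muLo
  hi <- muHi
  best <- at_lo$v
  while (hi - lo > bisectTol) {
    mid <- (lo + hi) / 2
    at_mid <- .feasiblePointAtMu(model, mid, tol)
    if (at_mid$feasible) {
      lo <- mid
      best <- at_mid$v
    } else {
      hi <- mid
    }
  }
  # report a parsimonious (minimum total flux) vertex at mu*: alternate
  # optima otherwise leave branch fluxes arbitrary
  bd <- .boundsAtMu(model, lo, tol)
  best <- .lpParsimonious(.denseSmu(model, lo), bd$lb, bd$ub, best)
  new("GrowthSolution", muStar = lo,
      fluxes = setNames(best, model@reactions$id),
      status = "optimal", notes = character(0))
})

#' Flux variability analysis at a fixed growth rate
#'
#' For every reaction, minimizes and maximizes its flux subject to
#' \eqn{S(\mu)v = 0}, the bounds, and the growth flux pinned to
#' `fraction * muStar`. Expression coupling narrows these ranges: each unit
#' of metabolic flux drags an expression cost, so alternate routes that are
#' free in a metabolism-only model become suboptimal.
#'
#' @param model an [MEModel-class].
#' @param muStar growth rate at which to evaluate variability (typically
#'   the optimum from [maximizeGrowth()]).
#' @param fraction fraction of `muStar` to pin growth at (default 1).
#' @param tol LP feasibility tolerance.
#' @param ... unused.
#' @return data.frame with columns `id`, `v_min`, `v_max`, `range`.
#' @rdname fluxVariability
#' @export
setMethod("fluxVariability", "MEModel",
          function(model, muStar, fraction = 1, tol = 1e-9, ...) {
  stopifnot(fraction > 0, fraction <= 1)
  mu <- fraction * muStar
  bd <- .boundsAtMu(model, mu, tol)
  if (is.null(bd) || !isFeasible(model, mu, tol)) {
    stop("model is infeasible at mu = ", mu,
         "; run maximizeGrowth first", call. = FALSE)
  }
  S <- .denseSmu(model, mu)
  n <- nrow(model@reactions)
  v_min <- v_max <- numeric(n)
  for (j in seq_len(n)) {
    if (bd$ub[j] - bd$lb[j] <= tol) {
      v_min[j] <- v_max[j] <- (bd$lb[j] + bd$ub[j]) / 2
      next
    }
    obj <- numeric(n)
    obj[j] <- 1
    lo <- .lpOptimize(obj, S, bd$lb, bd$ub, maximize = FALSE)
    hi <- .lpOptimize(obj, S, bd$lb, bd$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem failed for reaction ", model@reactions$id[j],
           call. = FALSE)
    }
    v_min[j] <- lo$value
    v_max[j] <- hi$value
  }
  data.frame(id = model@reactions$id, v_min = v_min, v_max = v_max,
             range = v_max - v_min, stringsAsFactors = FALSE)
})

#' Translation-knockout gene essentiality
#'
#' Closes (sets both bounds to zero) the translation reaction of `gene` and
#' tests feasibility at growth rate `muTest`. The gene is essential iff the
#' knocked-out model cannot grow at `muTest`. Knocking out only the
#' translation reaction is sufficient: without synthesis the enzyme cannot
#' be maintained against growth dilution, so every reaction it catalyzes is
#' transitively disabled.
#'
#' @param model an [MEModel-class]; not modified.
#' @param gene gene identifier (must be present in the model's translation
#'   map).
#' @param muTest growth rate at which feasibility is tested (default
#'   `1e-3` 1/h).
#' @param tol LP feasibility tolerance.
#' @param ... unused.
#' @return `TRUE` if the gene is essential.
#' @rdname geneEssentiality
#' @export
setMethod("geneEssentiality", "MEModel",
          function(model, gene, muTest = 1e-3, tol = 1e-9, ...) {
  tl <- translationReaction(model, gene)
  ko <- model
  j <- match(tl, ko@reactions$id)
  ko@reactions$lower_bound[j] <- 0
  ko@reactions$upper_bound[j] <- 0
  !isFeasible(ko, muTest, tol)
})

# exchange reactions: single-metabolite, mu-independent boundary reactions
.exchangeReactions <- function(model) {
  sto <- model@stoichiometry
  tab <- split(sto, sto$reaction)
  ids <- names(tab)[vapply(tab, function(d) {
    length(unique(d$metabolite)) == 1L && all(d$b == 0)
  }, logical(1))]
  intersect(model@reactions$id, ids)
}

#' Substrate uptake scan
#'
#' Steps the uptake bound of one exchange reaction through increasing
#' values, maximizing growth at each, and records the optimum and all
#' secretion (positive exchange) fluxes. On a model with expression
#' coupling this traces the proteome-limitation curve: growth saturates in
#' substrate excess and a low-yield, proteome-cheap branch switches on,
#' secreting its overflow product.
#'
#' @param model an [MEModel-class].
#' @param exchangeId id of the uptake exchange reaction; its lower bound is
#'   set to `-u` for each scanned uptake value `u`.
#' @param uptakeValues nonnegative, strictly increasing uptake bounds
#'   (mmol/gDW/h).
#' @param bisectTol,tol passed to [maximizeGrowth()].
#' @param ... unused.
#' @return data.frame with one row per uptake value: `uptake_bound`,
#'   `mu_star`, `status`, and one `secretion_<id>` column per other
#'   exchange reaction.
#' @rdname substrateScan
#' @export
setMethod("substrateScan", "MEModel",
          function(model, exchangeId, uptakeValues, bisectTol = 1e-6,
                   tol = 1e-9, ...) {
  if (!length(uptakeValues)) stop("uptakeValues is empty", call. = FALSE)
  if (any(uptakeValues < 0) || any(diff(uptakeValues) <= 0) &&
      length(uptakeValues) > 1L) {
    if (any(uptakeValues < 0)) {
      stop("uptakeValues must be nonnegative", call. = FALSE)
    }
    stop("uptakeValues must be strictly increasing", call. = FALSE)
  }
  j <- match(exchangeId, model@reactions$id)
  if (is.na(j)) stop("unknown exchange reaction: ", exchangeId, call. = FALSE)
  secIds <- setdiff(.exchangeReactions(model), exchangeId)
  res <- data.frame(uptake_bound = uptakeValues,
                    mu_star = NA_real_, status = NA_character_,
                    stringsAsFactors = FALSE)
  sec <- matrix(0, length(uptakeValues), length(secIds),
                dimnames = list(NULL, secIds))
  for (k in seq_along(uptakeValues)) {
    m <- model
    m@reactions$lower_bound[j] <- -uptakeValues[k]
    m@reactions$upper_bound[j] <- max(m@reactions$upper_bound[j],
                                      -uptakeValues[k])
    sol <- maximizeGrowth(m, bisectTol = bisectTol, tol = tol)
    res$status[k] <- sol@status
    if (sol@status == "optimal") {
      res$mu_star[k] <- sol@muStar
      if (length(secIds)) {
        sec[k, ] <- pmax(sol@fluxes[secIds], 0)
      }
    }
  }
  if (length(secIds)) {
    colnames(sec) <- paste0("secretion_", secIds)
    res <- cbind(res, as.data.frame(sec))
  }
  rownames(res) <- NULL
  res
})

#' Strip expression coupling to obtain a metabolism-only model
#'
#' Removes every reaction whose subsystem is expression machinery, deletes
#' all growth-rate-dependent (`b`) coefficient terms from the remaining
#' reactions, and drops metabolite species that thereby lose all their
#' references. The result is the M-model analog of the input: same
#' metabolic network, no biosynthetic cost, so its optimal growth rate
#' dominates the coupled model's at equal exchange bounds.
#'
#' @param model an [MEModel-class]; its growth reaction must not be in an
#'   expression subsystem.
#' @param ... unused.
#' @return An [MEModel-class] with no expression reactions and no
#'   mu-dependent coefficients.
#' @rdname stripExpression
#' @export
setMethod("stripExpression", "MEModel", function(model, ...) {
  rxn <- model@reactions
  sto <- model@stoichiometry
  gsub_ <- rxn$subsystem[match(model@growthReactionId, rxn$id)]
  if (gsub_ %in% model@expressionSubsystems) {
    stop("growth reaction is labeled as expression machinery", call. = FALSE)
  }
  keep <- !(rxn$subsystem %in% model@expressionSubsystems)
  rxn2 <- rxn[keep, , drop = FALSE]
  sto2 <- sto[sto$reaction %in% rxn2$id, , drop = FALSE]
  # remove mu-dependent terms; entries that were purely mu-coupled vanish
  drop_entry <- sto2$a == 0 & sto2$b != 0
  sto2 <- sto2[!drop_entry, , drop = FALSE]
  sto2$b <- 0
  referenced_before <- model@metabolites %in% sto$metabolite
  referenced_after <- model@metabolites %in% sto2$metabolite
  mets2 <- model@metabolites[referenced_after | !referenced_before]
  tl2 <- model@translationOf[model@translationOf %in% rxn2$id]
  MEModel(metabolites = mets2, reactions = rxn2, stoichiometry = sto2,
          genes = intersect(model@genes, names(tl2)),
          translationOf = tl2,
          growthReactionId = model@growthReactionId,
          expressionSubsystems = character(0),
          muMaxHint = model@muMaxHint)
})

#' Subsystem membership of genes
#'
#' Maps each gene to the subsystems of the reactions its protein product
#' catalyzes: the product is the species produced (positive `a`) by the
#' gene's translation reaction, and catalyzed reactions are those consuming
#' that species through a growth-rate-coupled usage term (negative `b`).
#' Used to aggregate translation fluxes and omics signal on a common
#' subsystem vocabulary.
#'
#' @param model an [MEModel-class].
#' @return data.frame with columns `id` (gene) and `subsystem`; a gene
#'   serving several subsystems gets one row per subsystem.
#' @export
geneSubsystems <- function(model) {
  stopifnot(is(model, "MEModel"))
  sto <- model@stoichiometry
  subs <- reactionSubsystems(model)
  out <- list()
  for (g in model@genes) {
    tl <- model@translationOf[[g]]
    prod <- sto$metabolite[sto$reaction == tl & sto$a > 0]
    users <- unique(sto$reaction[sto$metabolite %in% prod & sto$b < 0 &
                                   sto$reaction != tl])
    ss <- unique(unname(subs[users]))
    if (length(ss)) out[[g]] <- data.frame(id = g, subsystem = ss,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(id = character(0), subsystem = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Translation fluxes per gene
#'
#' Extracts the flux through each gene's translation reaction from a growth
#' solution, named by gene.
#'
#' @param model an [MEModel-class].
#' @param solution a [GrowthSolution-class] for `model`.
#' @return named numeric vector (genes).
#' @export
translationFluxes <- function(model, solution) {
  stopifnot(is(model, "MEModel"), is(solution, "GrowthSolution"))
  if (solution@status != "optimal") {
    stop("solution status is not optimal", call. = FALSE)
  }
  setNames(as.numeric(solution@fluxes[model@translationOf[model@genes]]),
           model@genes)
}
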