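suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Exhaustive feasibility scan over a mu grid: the independent oracle for
# growth bisection. Walks upward in steps of `step` until the first
# infeasible point (feasibility is monotone non-increasing in mu for
# generator-produced models; that property is tested separately).
gridMuStar <- function(model, step = 1e-4, tol = 1e-9) {
  mu <- 0
  if (!isFeasible(model, mu, tol)) return(NA_real_)
  while (isFeasible(model, mu + step, tol)) mu <- mu + step
  mu
}

# Naive per-entry evaluation of S(mu): a plain accumulation loop over the
# coefficient table, independent of the sparse-matrix construction path.
handStoichiometry <- function(model, mu) {
  sto <- stoichiometry(model)
  mets <- metabolites(model)
  rxns <- reactions(model)$id
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  for (k in seq_len(nrow(sto))) {
    S[sto$metabolite[k], sto$reaction[k]] <-
      S[sto$metabolite[k], sto$reaction[k]] + sto$a[k] + sto$b[k] * mu
  }
  S
}

# Exact one-tailed Mann-Whitney p-value by full enumeration of all
# C(n + m, n) assignments of the pooled values to the first sample.
mwuEnumerate <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  uObs <- uOf(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  uAll <- apply(combos, 2, uOf)
  if (alternative == "greater") mean(uAll >= uObs) else mean(uAll <= uObs)
}

# Unbranched three-step pathway: uptake -> convert -> growth. Every active
# flux is forced, so FVA ranges collapse to solver noise.
linearChainModel <- function(uptake = 5, yield = 0.1) {
  MEModel(
    metabolites = c("s", "p"),
    reactions = data.frame(
      id = c("EX_s", "CONV", "GROW"),
      lower_bound = c(-uptake, 0, 0),
      upper_bound = c(0, 1000, 1000),
      subsystem = c("Exchange", "Metabolism", "Biomass")),
    stoichiometry = data.frame(
      reaction = c("EX_s", "CONV", "CONV", "GROW"),
      metabolite = c("s", "s", "p", "p"),
      a = c(-1, -1, yield, -1),
      b = c(0, 0, 0, 0)),
    growthReactionId = "GROW",
    muMaxHint = 2)
}

# Deterministic six-gene two-assay CPM fixture: pathway genes hold the
# bottom three RNA ranks and the top three Ribo ranks.
sixGeneFixture <- function() {
  genes <- paste0("g", 1:6)
  rna <- matrix(c(1, 2, 3, 10, 20, 30), 6, 1,
                dimnames = list(genes, NULL))
  ribo <- matrix(c(40, 50, 60, 1, 2, 3), 6, 1,
                 dimnames = list(genes, NULL))
  list(
    rna = cpmNormalize(countMatrix(rna, assay = "rna", replicate = 1)),
    ribo = cpmNormalize(countMatrix(ribo, assay = "ribo", replicate = 1)),
    pathway = list(P = genes[1:3]))
}
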