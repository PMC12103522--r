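# synthetic_data module, omics half: negative-binomial paired
# RNA-Seq/Ribo-Seq count simulation with planted pathway-level TE effects.

#' Construct an OmicsDesign
#'
#' See [OmicsDesign-class] for the generative model. Most analyses use the
#' pre-parameterized [defaultOmicsDesign()] (heterogeneous abundances,
#' optional planted TE effects) or [nullOmicsDesign()] (exchangeable null
#' for calibration).
#'
#' @param nGenes number of genes.
#' @param pathways named list of disjoint gene-id vectors.
#' @param geneIds gene identifiers (default `g0001`...).
#' @param nReplicates replicates per assay.
#' @param depth expected reads per sample.
#' @param meanlog,sdlogBetween,sdlogWithin abundance log-normal parameters
#'   (natural log): pathway baselines spread with `sdlogBetween`, genes
#'   scatter around their pathway baseline with `sdlogWithin`.
#' @param dispersion NB dispersion (1/size), scalar or per gene.
#' @param teEffects named multiplicative TE effect per pathway; pathways
#'   omitted from the vector get effect 1.
#' @param sdlogTE gene-level TE noise (natural-log sd).
#' @param depthFactorSdlog library-size variation across replicates.
#' @param abundance optional explicit per-gene relative abundances
#'   (overrides the log-normal draw).
#' @param seed RNG seed.
#' @return A validated [OmicsDesign-class].
#' @export
omicsDesign <- function(nGenes, pathways = list(),
                        geneIds = sprintf("g%04d", seq_len(nGenes)),
                        nReplicates = 3L, depth = 5e6,
                        meanlog = 0, sdlogBetween = 2.0, sdlogWithin = 0.3,
                        dispersion = 0.1, teEffects = numeric(0),
                        sdlogTE = 0.2, depthFactorSdlog = 0.1,
                        abundance = numeric(0), seed = 1L) {
  pathways <- lapply(pathways, as.character)
  eff <- setNames(rep(1, length(pathways)), names(pathways))
  if (length(teEffects)) eff[names(teEffects)] <- teEffects
  new("OmicsDesign", nGenes = as.integer(nGenes), geneIds = geneIds,
      pathways = pathways, nReplicates = as.integer(nReplicates),
      depth = depth, meanlog = meanlog, sdlogBetween = sdlogBetween,
      sdlogWithin = sdlogWithin, dispersion = dispersion,
      teEffects = eff, sdlogTE = sdlogTE,
      depthFactorSdlog = depthFactorSdlog,
      abundance = as.numeric(abundance), seed = as.integer(seed))
}

#' Default paired-omics simulation design
#'
#' Fifty 10-gene pathways plus 100 unassigned background genes, three
#' replicates per assay at 5e6 reads. Pathway baseline abundances span
#' several orders of magnitude (`sdlogBetween = 2`) while genes within a
#' pathway stay within a narrow band (`sdlogWithin = 0.3`), mimicking
#' co-regulated bacterial operons; the resulting mean counts cover more
#' than four decades.
#'
#' @param seed RNG seed.
#' @param nPathways,genesPerPathway,nBackground universe layout.
#' @param teEffects named per-pathway TE effects to plant (default none).
#' @param ... further overrides passed to [omicsDesign()].
#' @return An [OmicsDesign-class].
#' @examples
#' d <- defaultOmicsDesign(seed = 1, teEffects = c(pw01 = 2))
#' d
#' @export
defaultOmicsDesign <- function(seed = 1L, nPathways = 50L,
                               genesPerPathway = 10L, nBackground = 100L,
                               teEffects = numeric(0), ...) {
  nGenes <- nPathways * genesPerPathway + nBackground
  ids <- sprintf("g%04d", seq_len(nGenes))
  pw <- split(ids[seq_len(nPathways * genesPerPathway)],
              rep(sprintf("pw%02d", seq_len(nPathways)),
                  each = genesPerPathway))
  omicsDesign(nGenes = nGenes, pathways = pw, geneIds = ids,
              teEffects = teEffects, seed = seed, ...)
}

#' Exchangeable null design for test calibration
#'
#' All genes share one abundance and all TE effects are 1, so a gene's
#' rank in the RNA and in the Ribo ranking are driven by independent
#' counting noise. This exchangeability is what the Mann-Whitney U null
#' distribution assumes; under the heterogeneous default design the two
#' rank vectors of the same genes are strongly paired and the unpaired
#' test is conservative rather than miscalibrated. Depth is reduced to
#' 6e5 reads so that large batches of null simulations stay cheap.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [defaultOmicsDesign()].
#' @return An [OmicsDesign-class].
#' @export
nullOmicsDesign <- function(seed = 1L, ...) {
  defaultOmicsDesign(seed = seed, sdlogBetween = 0, sdlogWithin = 0,
                     depth = 6e5, ...)
}

#' Simulate paired RNA-Seq/Ribo-Seq counts with ground truth
#'
#' Draws latent gene abundances and translational efficiencies from the
#' design, then samples RNA counts with NB mean proportional to abundance
#' and Ribo counts with NB mean proportional to abundance x TE, each assay
#' renormalized to its expected library size (sequencing is
#' compositional) and scaled by a per-replicate depth factor. RNA and Ribo
#' counts are conditionally independent given the latent abundances.
#' Everything is driven by `design@seed`: the same design reproduces the
#' same counts bit for bit.
#'
#' @param design an [OmicsDesign-class].
#' @return list with `rna` and `ribo` (count `SummarizedExperiment`s) and
#'   `truth`: per-gene relative abundance, TE and pathway; per-pathway
#'   planted effect and expected classification; per-sample depth factors.
#' @examples
#' sim <- simulateCounts(defaultOmicsDesign(seed = 7))
#' sim$rna
#' head(sim$truth$gene)
#' @export
simulateCounts <- function(design) {
  stopifnot(is(design, "OmicsDesign"))
  validObject(design)
  set.seed(design@seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n <- design@nGenes
  ids <- design@geneIds
  pwOf <- rep(NA_character_, n)
  names(pwOf) <- ids
  for (pn in names(design@pathways)) pwOf[design@pathways[[pn]]] <- pn

  # latent abundances: pathway baseline + within-pathway scatter
  if (length(design@abundance)) {
    a <- design@abundance
  } else {
    base <- setNames(rnorm(length(design@pathways), design@meanlog,
                           design@sdlogBetween), names(design@pathways))
    la <- numeric(n)
    inPw <- !is.na(pwOf)
    la[inPw] <- rnorm(sum(inPw), base[pwOf[inPw]], design@sdlogWithin)
    la[!inPw] <- rnorm(sum(!inPw), design@meanlog,
                       sqrt(design@sdlogBetween^2 + design@sdlogWithin^2))
    a <- exp(la)
  }

  effOf <- ifelse(is.na(pwOf), 1, design@teEffects[pwOf])
  te <- effOf * exp(rnorm(n, 0, design@sdlogTE))

  nr <- design@nReplicates
  dfRna <- exp(rnorm(nr, 0, design@depthFactorSdlog))
  dfRibo <- exp(rnorm(nr, 0, design@depthFactorSdlog))

  size <- 1 / rep_len(design@dispersion, n)
  relR <- if (sum(a) > 0) a / sum(a) else a
  ab <- a * te
  relB <- if (sum(ab) > 0) ab / sum(ab) else ab

  drawAssay <- function(rel, df, prefix) {
    m <- matrix(0L, n, nr, dimnames = list(ids, paste0(prefix, "_",
                                                       seq_len(nr))))
    for (r in seq_len(nr)) {
      m[, r] <- as.integer(rnbinom(n, mu = rel * design@depth * df[r],
                                   size = size))
    }
    m
  }
  rnaC <- drawAssay(relR, dfRna, "rna")
  riboC <- drawAssay(relB, dfRibo, "ribo")

  truthPw <- data.frame(
    pathway = names(design@pathways),
    te_effect = unname(design@teEffects[names(design@pathways)]),
    stringsAsFactors = FALSE)
  truthPw$expected_class <- ifelse(truthPw$te_effect > 1, "up",
                                   ifelse(truthPw$te_effect < 1, "down",
                                          "ns"))
  list(
    rna = countMatrix(rnaC, assay = rep("rna", nr),
                      replicate = seq_len(nr)),
    ribo = countMatrix(riboC, assay = rep("ribo", nr),
                       replicate = seq_len(nr)),
    truth = list(
      gene = data.frame(gene = ids, abundance = relR, te = te,
                        pathway = pwOf, row.names = NULL,
                        stringsAsFactors = FALSE),
      pathway = truthPw,
      depthFactors = list(rna = dfRna, ribo = dfRibo)))
}

#' Simulate omics counts coupled to a model's translation fluxes
#'
#' Builds an [OmicsDesign-class] over a model's genes whose latent
#' abundances are proportional to the translation fluxes of a growth
#' solution, perturbed by log-normal noise, with pathways given by each
#' gene's annotated subsystem. Used to benchmark how well model flux
#' profiles recover a (here, synthetic) expression profile they generated.
#'
#' @param model an [MEModel-class].
#' @param solution a [GrowthSolution-class] for `model`.
#' @param seed RNG seed (drives both the abundance noise and the counts).
#' @param noiseSdlog log-normal abundance noise around the flux signal.
#' @param depth,nReplicates,dispersion passed to the design.
#' @return As [simulateCounts()], plus element `design`.
#' @export
simulateCoupledOmics <- function(model, solution, seed = 1L,
                                 noiseSdlog = 0.3, depth = 5e6,
                                 nReplicates = 3L, dispersion = 0.1) {
  tf <- translationFluxes(model, solution)
  gs <- geneSubsystems(model)
  # one pathway per subsystem; the generator needs disjoint sets, so a
  # multi-subsystem gene is assigned to its first subsystem here
  first <- gs[!duplicated(gs$id), , drop = FALSE]
  pw <- split(first$id, first$subsystem)
  set.seed(as.integer(seed) + 1L)
  ab <- tf * exp(rnorm(length(tf), 0, noiseSdlog))
  design <- omicsDesign(nGenes = length(tf), pathways = pw,
                        geneIds = names(tf), nReplicates = nReplicates,
                        depth = depth, dispersion = dispersion,
                        sdlogTE = 0, abundance = unname(ab),
                        seed = seed)
  out <- simulateCounts(design)
  out$design <- design
  out
}
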