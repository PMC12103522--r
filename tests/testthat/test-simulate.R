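test_that("the generator is deterministic and design-validated", {
  d <- defaultOmicsDesign(seed = 9)
  s1 <- simulateCounts(d)
  s2 <- simulateCounts(defaultOmicsDesign(seed = 9))
  expect_identical(assay(s1$rna, "counts"), assay(s2$rna, "counts"))
  expect_identical(assay(s1$ribo, "counts"), assay(s2$ribo, "counts"))
  expect_identical(s1$truth$gene, s2$truth$gene)
  s3 <- simulateCounts(defaultOmicsDesign(seed = 10))
  expect_false(identical(assay(s1$rna, "counts"),
                         assay(s3$rna, "counts")))

  expect_error(omicsDesign(nGenes = 10, nReplicates = 1), "nReplicates")
  expect_error(omicsDesign(nGenes = 10, depth = 0), "depth")
  expect_error(omicsDesign(nGenes = 5, pathways = list(P = "g9999")),
               "unknown genes")
  expect_error(
    omicsDesign(nGenes = 5, pathways = list(P = "g0001", Q = "g0001")),
    "disjoint")
})

test_that("mean counts span at least four orders of magnitude", {
  sim <- simulateCounts(defaultOmicsDesign(seed = 1))
  for (a in c("rna", "ribo")) {
    m <- rowMeans(assay(sim[[a]], "counts"))
    m <- m[m > 0]
    expect_gte(log10(max(m) / min(m)), 4)
  }
})

test_that("planted truth is annotated and null designs are flat", {
  d <- defaultOmicsDesign(seed = 5, teEffects = c(pw03 = 2, pw04 = 0.5))
  sim <- simulateCounts(d)
  pw <- sim$truth$pathway
  expect_identical(pw$expected_class[pw$pathway == "pw03"], "up")
  expect_identical(pw$expected_class[pw$pathway == "pw04"], "down")
  expect_true(all(pw$expected_class[!pw$pathway %in%
                                      c("pw03", "pw04")] == "ns"))
  # exchangeable null: every gene shares the same latent abundance
  nullSim <- simulateCounts(nullOmicsDesign(seed = 5))
  expect_equal(length(unique(nullSim$truth$gene$abundance)), 1L)
})

test_that("TE estimates converge to the truth as depth grows", {
  err <- vapply(c(2e5, 5e6), function(depth) {
    d <- defaultOmicsDesign(seed = 11, depth = depth,
                            teEffects = c(pw01 = 2))
    sim <- simulateCounts(d)
    te <- geneTE(cpmNormalize(sim$rna), cpmNormalize(sim$ribo))
    keep <- te$included
    truthTe <- sim$truth$gene$te[match(te$gene, sim$truth$gene$gene)]
    # compositional rescaling affects all genes equally; compare shapes
    est <- te$te[keep] / mean(te$te[keep])
    tru <- truthTe[keep] / mean(truthTe[keep])
    median(abs(log(est / tru)))
  }, numeric(1))
  # deeper sequencing strips the Poisson component; the NB overdispersion
  # floor (dispersion 0.1 over 3 replicates) remains
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.25)
})

test_that("coupled omics reflect a model's translation fluxes", {
  mc <- makeMinicell()
  sol <- maximizeGrowth(mc$me)
  cp <- simulateCoupledOmics(mc$me, sol, seed = 2)
  expect_setequal(rownames(assay(cp$rna, "counts")), genes(mc$me))
  tf <- translationFluxes(mc$me, sol)
  m <- rowMeans(assay(cp$ribo, "counts"))[names(tf)]
  # silent genes yield no reads; expressed genes correlate with flux
  expect_true(all(m[tf == 0] == 0))
  on <- tf > 0
  expect_gt(cor(log10(m[on] + 1), log10(tf[on] * 1e6 + 1)), 0.8)
})
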