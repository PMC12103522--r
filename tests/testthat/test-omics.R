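test_that("CPM matches the defining ratio on hand-computable vectors", {
  cm <- countMatrix(matrix(c(1, 1, 2), 3, 1,
                           dimnames = list(paste0("g", 1:3))),
                    assay = "rna", replicate = 1)
  cpm <- assay(cpmNormalize(cm), "cpm")
  expect_equal(as.numeric(cpm), c(250000, 250000, 500000))

  n <- 8
  eq <- countMatrix(matrix(5L, n, 2, dimnames = list(paste0("g", 1:n))),
                    assay = c("rna", "rna"), replicate = 1:2)
  expect_true(all(assay(cpmNormalize(eq), "cpm") == 1e6 / n))
})

test_that("CPM columns sum to 1e6 and are scale invariant", {
  sim <- simulateCounts(defaultOmicsDesign(seed = 2))
  cpm <- assay(cpmNormalize(sim$rna), "cpm")
  expect_equal(unname(colSums(cpm)), rep(1e6, ncol(cpm)),
               tolerance = 1e-6)
  # multiplying a sample's counts by a constant leaves its CPM unchanged
  m <- assay(sim$rna, "counts")
  m2 <- m
  m2[, 1] <- m2[, 1] * 7L
  cm2 <- countMatrix(m2, assay = colData(sim$rna)$assay,
                     replicate = colData(sim$rna)$replicate)
  expect_equal(assay(cpmNormalize(cm2), "cpm")[, 1], cpm[, 1])
})

test_that("zero-total samples are refused by name", {
  cm <- countMatrix(matrix(c(1L, 0L), 1, 2,
                           dimnames = list("g1")),
                    assay = c("rna", "rna"), replicate = 1:2)
  expect_error(cpmNormalize(cm), "rna_2")
})

test_that("replicate QC flags duplicates as perfect and scrambles as broken", {
  sim <- simulateCounts(defaultOmicsDesign(seed = 3))
  m <- assay(sim$rna, "counts")
  # exact duplicate replicate: PCC 1, no mean difference
  dup <- countMatrix(cbind(m[, 1], m[, 1], m[, 2]),
                     assay = rep("rna", 3), replicate = 1:3)
  qc <- replicateQC(cpmNormalize(dup))
  expect_equal(qc$pcc$rna[1, 2], 1)
  expect_equal(qc$ttestP$rna[1, 2], 1)
  # well-behaved replicates pass
  expect_true(replicateQC(cpmNormalize(sim$rna))$pass)
  # scrambling one replicate destroys its correlation
  bad <- m
  set.seed(1)
  bad[, 3] <- bad[sample(nrow(bad)), 3]
  qcBad <- replicateQC(cpmNormalize(
    countMatrix(bad, assay = rep("rna", 3), replicate = 1:3)))
  expect_lt(qcBad$pcc$rna[1, 3], 0.9)
  expect_false(qcBad$pass)
  # single replicate: untested pass with a warning
  expect_warning(
    qc1 <- replicateQC(cpmNormalize(
      countMatrix(m[, 1, drop = FALSE], assay = "rna", replicate = 1))),
    "single replicate")
  expect_true(qc1$pass)
  expect_true(qc1$untested)
})

test_that("TE is the Ribo/RNA CPM ratio with strict zero handling", {
  genes <- paste0("g", 1:5)
  # the large anchor gene keeps library totals comparable, so the
  # compositional distortion of a single shifted gene stays small
  base <- matrix(c(10L, 100L, 50L, 0L, 10000L), 5, 2,
                 dimnames = list(genes))
  rna <- cpmNormalize(countMatrix(base, assay = c("rna", "rna"),
                                  replicate = 1:2))
  riboSame <- cpmNormalize(countMatrix(base, assay = c("ribo", "ribo"),
                                       replicate = 1:2))
  te <- geneTE(rna, riboSame)
  expect_equal(te$te[te$included], rep(1, 4))
  expect_false(te$included[4])
  expect_true(is.na(te$te[4]))

  ribo3 <- cpmNormalize(countMatrix(base * 3L, assay = c("ribo", "ribo"),
                                    replicate = 1:2))
  te3 <- geneTE(rna, ribo3)
  # library-size normalization cancels the common factor; ratios of CPM
  # equal ratios of relative abundance, which are identical here
  expect_equal(te3$te[te3$included], rep(1, 4))
  # a genuine per-gene shift survives CPM
  shifted <- base
  shifted[2, ] <- shifted[2, ] * 3L
  teS <- geneTE(rna, cpmNormalize(countMatrix(
    shifted, assay = c("ribo", "ribo"), replicate = 1:2)))
  expect_gt(teS$te[2], 2.5)

  other <- cpmNormalize(countMatrix(
    matrix(1L, 2, 1, dimnames = list(c("g1", "zz"))),
    assay = "ribo", replicate = 1))
  expect_error(geneTE(rna, other), "universes differ.*zz")
})

test_that("identical assays yield TE 1 and an all-ns prioritization", {
  sim <- simulateCounts(defaultOmicsDesign(seed = 4))
  cr <- cpmNormalize(sim$rna)
  same <- SummarizedExperiment(
    assays = list(cpm = assay(cr, "cpm")),
    colData = colData(cr))
  te <- geneTE(cr, same)
  expect_equal(te$te[te$included], rep(1, sum(te$included)))
  pr <- pathwayPrioritization(te, cr, same,
                              defaultOmicsDesign(seed = 4)@pathways)
  expect_true(all(pr$class == "ns"))
})

test_that("one-tailed MWU p-values match full enumeration for n <= 8", {
  cases <- list(
    list(x = c(6, 7, 8), y = c(1, 2, 3)),
    list(x = c(1, 4, 6), y = c(2, 3, 5)),
    list(x = c(2, 3), y = c(1, 4, 5, 6)),
    list(x = c(5, 2, 7, 1), y = c(3, 4, 6, 8)),
    list(x = c(1, 2), y = c(3, 4)))
  for (cs in cases) {
    for (alt in c("greater", "less")) {
      got <- meomics:::.mwu(cs$x, cs$y, alt)
      expect_equal(got$p, mwuEnumerate(cs$x, cs$y, alt),
                   tolerance = 1e-12,
                   label = sprintf("x=%s alt=%s",
                                   paste(cs$x, collapse = ","), alt))
    }
  }
})

test_that("a fully rank-separated pathway attains the enumeration p-value", {
  fx <- sixGeneFixture()
  te <- geneTE(fx$rna, fx$ribo)
  pr <- pathwayPrioritization(te, fx$rna, fx$ribo, fx$pathway,
                              minGenes = 3)
  # ribo ranks {4,5,6} vs rna ranks {1,2,3}: U = 9, one tail of the 20
  # equally likely rank assignments
  expect_equal(pr$U, 9)
  expect_equal(pr$p_right, 1 / choose(6, 3), tolerance = 1e-12)
  expect_equal(pr$p_right, mwuEnumerate(c(4, 5, 6), c(1, 2, 3), "greater"))
})

test_that("small pathways are flagged, multi-membership genes count twice", {
  fx <- sixGeneFixture()
  te <- geneTE(fx$rna, fx$ribo)
  pws <- list(tiny = c("g1", "g2"), P = paste0("g", 1:3),
              Q = c("g1", "g2", "g3", "g4"))
  pr <- pathwayPrioritization(te, fx$rna, fx$ribo, pws, minGenes = 3)
  tiny <- pr[pr$pathway == "tiny", ]
  expect_identical(tiny$class, "ns")
  expect_true(tiny$insufficient)
  expect_true(is.na(tiny$p_right))
  expect_identical(nrow(pr), 3L)
  expect_equal(pr$n_genes[pr$pathway == "Q"], 4)
  expect_error(
    pathwayPrioritization(te, fx$rna, fx$ribo, list(P = c("g1", "zz"))),
    "absent.*zz")
})
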