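test_that("subsystem aggregation sums absolute values and reports strays", {
  map <- data.frame(id = c("gA", "gB", "gC"),
                    subsystem = c("S1", "S1", "S2"))
  agg <- aggregateSubsystem(c(gA = 100, gB = 200, gC = -5), map)
  prof <- agg$profile
  expect_equal(prof$f[prof$subsystem == "S1"], 300)
  # reversible flux enters by magnitude, not sign
  expect_equal(prof$f[prof$subsystem == "S2"], 5)
  expect_equal(prof$log_f, log10(prof$f + 1))
  # unmapped ids are reported, not dropped silently
  agg2 <- aggregateSubsystem(c(gA = 1, zz = 9), map)
  expect_identical(agg2$unmapped, "zz")
  expect_false("zz" %in% agg2$profile$subsystem)
  expect_error(aggregateSubsystem(c(a = 1), data.frame()), "mapping")
})

test_that("minicell translation fluxes aggregate to hand totals", {
  mc <- makeMinicell()
  sol <- maximizeGrowth(mc$me)
  tf <- translationFluxes(mc$me, sol)
  gmap <- geneSubsystems(mc$me)
  agg <- aggregateSubsystem(tf, gmap, mode = "translation_flux")
  byHand <- tapply(abs(tf[gmap$id]), gmap$subsystem, sum)
  prof <- agg$profile
  expect_equal(setNames(prof$f, prof$subsystem),
               setNames(as.numeric(byHand), names(byHand))[prof$subsystem])
})

test_that("aggregation is linear across sample splits", {
  map <- data.frame(id = c("gA", "gB"), subsystem = c("S", "S"))
  whole <- aggregateSubsystem(c(gA = 9, gB = 1), map)$profile$f
  m <- matrix(c(4, 1, 5, 0), 2, 2, dimnames = list(c("gA", "gB")))
  colnames(m) <- c("s1", "s2")
  parts <- aggregateSubsystem(m, map)$profile
  expect_equal(sum(parts$f), whole)
})

test_that("self-correlation is exact and anticorrelation is -1", {
  p <- aggregateSubsystem(c(a = 2, b = 30, c = 400, d = 5000),
                          data.frame(id = letters[1:4],
                                     subsystem = LETTERS[1:4]))
  selfie <- correlateProfiles(p, p)
  expect_equal(selfie$slope, 1, tolerance = 1e-12)
  expect_equal(selfie$intercept, 0, tolerance = 1e-12)
  expect_equal(selfie$pcc, 1, tolerance = 1e-12)

  x <- data.frame(subsystem = c("A", "B", "C"), log_f = c(1, 2, 3))
  y <- data.frame(subsystem = c("A", "B", "C"), log_f = c(3, 2, 1))
  anti <- correlateProfiles(x, y)
  expect_equal(anti$pcc, -1, tolerance = 1e-12)
  # symmetry of correlation under argument swap
  expect_equal(correlateProfiles(y, x)$pcc, anti$pcc)
  expect_error(
    correlateProfiles(x[1:2, ], y),
    "at least 3 shared")
})

test_that("shared-subsystem filtering is reported", {
  x <- data.frame(subsystem = c("A", "B", "C", "onlyX"),
                  log_f = c(1, 2, 3, 9))
  y <- data.frame(subsystem = c("A", "B", "C", "onlyY"),
                  log_f = c(1.1, 2.2, 2.9, 7))
  r <- correlateProfiles(x, y)
  expect_identical(sort(r$excluded), c("onlyX", "onlyY"))
  expect_identical(r$n, 3L)
})

test_that("log10(f + 1) preserves order and anchors zero", {
  f <- c(0, 0.5, 2, 1000)
  lf <- log10(f + 1)
  expect_equal(lf[1], 0)
  expect_true(all(diff(lf) > 0))
  agg <- aggregateSubsystem(setNames(f, letters[1:4]),
                            data.frame(id = letters[1:4],
                                       subsystem = letters[1:4]))
  expect_equal(sort(agg$profile$log_f), sort(lf))
})

test_that("expression-aware fluxes track coupled omics better than the relaxation", {
  mc <- makeMinicell()
  sol <- maximizeGrowth(mc$me)
  solM <- maximizeGrowth(mc$m)
  cp <- simulateCoupledOmics(mc$me, sol, seed = 5)
  omics <- aggregateSubsystem(assay(cpmNormalize(cp$ribo), "cpm"),
                              geneSubsystems(mc$me), mode = "cpm")
  profMe <- aggregateSubsystem(translationFluxes(mc$me, sol),
                               geneSubsystems(mc$me),
                               mode = "translation_flux")
  profM <- aggregateSubsystem(fluxes(solM), reactionSubsystems(mc$m),
                              mode = "reaction_flux")
  bMe <- correlateProfiles(profMe, omics)
  bM <- correlateProfiles(profM, omics)
  expect_gt(bMe$pcc, bM$pcc)
  expect_gt(bMe$pcc, 0.8)
  expect_lt(bM$p, 0.05)  # still positively related, only weaker
})
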