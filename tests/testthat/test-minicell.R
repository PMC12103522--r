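test_that("the default minicell is a working ME/M pair", {
  mc <- makeMinicell()
  expect_s4_class(mc$me, "MEModel")
  expect_true(validObject(mc$me))
  sol <- maximizeGrowth(mc$me)
  expect_identical(solutionStatus(sol), "optimal")
  expect_gt(muStar(sol), 0.1)
  expect_lt(muStar(sol), 1)
  expect_length(genes(mc$me), 10)
  expect_length(genes(mc$m), 0)
})

test_that("parameter invariants are enforced at construction", {
  expect_error(minicellParams(yieldOverflow = 0.2),
               "higher yield")
  expect_error(minicellParams(lengthOverflow = 900, keffOverflow = 2000),
               "higher proteome cost")
  expect_error(minicellParams(uptakeBound = -1), "positive")
  expect_error(minicellParams(auxFraction = 1.2), "auxFraction")
})

test_that("generation is deterministic down to the serialized bytes", {
  p1 <- randomMinicellParams(42)
  p2 <- randomMinicellParams(42)
  f1 <- tempfile(); f2 <- tempfile()
  writeMEModel(makeMinicell(p1)$me, f1)
  writeMEModel(makeMinicell(p2)$me, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different model
  f3 <- tempfile()
  writeMEModel(makeMinicell(randomMinicellParams(43))$me, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("the sole ribosome producer is essential in every variant", {
  for (s in c(5, 21, 33)) {
    me <- makeMinicell(randomMinicellParams(s))$me
    expect_true(geneEssentiality(me, "g_rib"))
  }
})

test_that("gene-to-subsystem mapping follows catalysis", {
  me <- makeMinicell()$me
  gs <- geneSubsystems(me)
  expect_identical(gs$subsystem[gs$id == "g_resp"], "Respiration")
  expect_identical(gs$subsystem[gs$id == "g_ovf"], "Overflow")
  # the ribosome serves the translation sector itself
  expect_identical(gs$subsystem[gs$id == "g_rib"], "Translation")
})
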