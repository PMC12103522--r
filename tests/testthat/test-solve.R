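test_that("feasibility behaves at the growth extremes", {
  mc <- makeMinicell()
  # zero growth with all-zero fluxes is always admissible
  expect_true(isFeasible(mc$me, 0))
  # no carbon, no growth
  starved <- makeMinicell(minicellParams(uptakeBound = 1e-9), check = FALSE)
  expect_false(isFeasible(starved$me, 0.1))
  expect_error(isFeasible(mc$me, -1), "nonnegative")
  expect_error(isFeasible(mc$me, 0.1, tol = 0), "tol")
})

test_that("feasibility flips exactly at the grid-scan optimum", {
  mc <- makeMinicell(randomMinicellParams(7))
  muGrid <- gridMuStar(mc$me, step = 1e-3)
  expect_true(isFeasible(mc$me, muGrid))
  expect_false(isFeasible(mc$me, muGrid + 1e-3))
})

test_that("growth maximization matches closed forms and the grid oracle", {
  # metabolism-only: mu* = yield * uptake when only the uptake bound binds
  m <- makeMinicell(minicellParams(uptakeBound = 5))$m
  sol <- maximizeGrowth(m)
  expect_equal(muStar(sol), 0.1 * 5, tolerance = 2e-6)

  # seeded ME fixture against the exhaustive feasibility scan
  me <- makeMinicell(randomMinicellParams(7))$me
  sol7 <- maximizeGrowth(me, bisectTol = 1e-6)
  expect_lt(abs(muStar(sol7) - gridMuStar(me, step = 1e-4)), 1e-4 + 2e-6)

  # conservation at the reported flux vector
  S <- evaluateStoichiometry(me, muStar(sol7))
  expect_lt(max(abs(as.numeric(S %*% fluxes(sol7)))), 1e-8)
})

test_that("starvation and bracket misuse are reported", {
  starved <- makeMinicell(minicellParams(uptakeBound = 1e-9),
                          check = FALSE)$me
  # infeasible floor
  sol <- maximizeGrowth(starved, muLo = 0.1)
  expect_identical(solutionStatus(sol), "infeasible_at_floor")
  expect_true(is.na(muStar(sol)))
  # mu_lo = 0 is always feasible here; optimum collapses to zero growth
  sol0 <- maximizeGrowth(starved, muLo = 0)
  expect_identical(solutionStatus(sol0), "optimal")
  expect_lt(muStar(sol0), 1e-5)
  # feasible ceiling is a bracket error
  mc <- makeMinicell()
  expect_error(maximizeGrowth(mc$me, muHi = 0.01), "raise muHi")
  expect_error(maximizeGrowth(mc$me, muLo = 2, muHi = 1), "muLo < muHi")
})

test_that("FVA ranges collapse where fluxes are forced", {
  # blocked reaction pinned at zero
  lin <- linearChainModel()
  sol <- maximizeGrowth(lin)
  blocked <- lin
  blocked@reactions$lower_bound[2] <- 0
  blocked@reactions$upper_bound[2] <- 0
  fvaB <- fluxVariability(blocked, 0)
  expect_equal(fvaB$v_min[2], 0)
  expect_equal(fvaB$v_max[2], 0)

  # unbranched pathway: every active reaction is forced at mu*
  fva <- fluxVariability(lin, muStar(sol))
  expect_lt(max(fva$range), 1e-6)

  # the observed flux vector sits inside its own ranges
  me <- makeMinicell()$me
  solMe <- maximizeGrowth(me)
  fvaMe <- fluxVariability(me, muStar(solMe))
  v <- fluxes(solMe)[fvaMe$id]
  expect_true(all(v >= fvaMe$v_min - 1e-6))
  expect_true(all(v <= fvaMe$v_max + 1e-6))

  expect_error(fluxVariability(me, muMaxHint(me)), "infeasible")
})

test_that("expression coupling narrows every shared flux range", {
  mc <- makeMinicell()
  solMe <- maximizeGrowth(mc$me, bisectTol = 1e-8)
  solM <- maximizeGrowth(mc$m, bisectTol = 1e-8)
  fvaMe <- fluxVariability(mc$me, muStar(solMe))
  fvaM <- fluxVariability(mc$m, muStar(solM))
  shared <- intersect(fvaMe$id, fvaM$id)
  rMe <- fvaMe$range[match(shared, fvaMe$id)]
  rM <- fvaM$range[match(shared, fvaM$id)]
  # ranges below ~1e-5 are numerically zero: bisection slack (bisectTol
  # 1e-8) divided by effective yields ~0.03 leaves sub-1e-6 wiggle room
  expect_true(all(rMe <= rM + 1e-5))
  # the degenerate respiratory isozymes are where the reduction is real
  expect_gt(fvaM$range[fvaM$id == "RESP"], 5)
  expect_lt(fvaMe$range[fvaMe$id == "RESP"], 1e-4)
})

test_that("translation knockouts decide essentiality and leave the model intact", {
  mc <- makeMinicell()
  before <- mc$me@reactions
  # sole ribosome producer: no translation at all without it
  expect_true(geneEssentiality(mc$me, "g_rib"))
  # overflow branch is dispensable while respiration stands
  expect_false(geneEssentiality(mc$me, "g_ovf"))
  # respiration enzyme is backed by its isozyme, and vice versa
  expect_false(geneEssentiality(mc$me, "g_resp"))
  expect_false(geneEssentiality(mc$me, "g_resp2"))
  # every auxiliary biosynthesis module is a sole biomass supplier
  expect_true(all(vapply(sprintf("g_aux%d", 1:6), geneEssentiality,
                         logical(1), model = mc$me)))
  expect_identical(mc$me@reactions, before)
  expect_error(geneEssentiality(mc$me, "nope"), "unknown gene")
})

test_that("stripping expression yields the metabolic relaxation", {
  # a model with no expression structure passes through unchanged
  lin <- linearChainModel()
  expect_equal(stripExpression(lin), lin)

  mc <- makeMinicell()
  nMetabolic <- sum(!reactions(mc$me)$subsystem %in%
                      expressionSubsystems(mc$me))
  expect_identical(nrow(reactions(mc$m)), nMetabolic)
  expect_true(all(stoichiometry(mc$m)$b == 0))
  # relaxation can only increase the optimum
  for (s in c(1, 2, 3)) {
    pair <- makeMinicell(randomMinicellParams(s))
    expect_gte(muStar(maximizeGrowth(pair$m)),
               muStar(maximizeGrowth(pair$me)) - 1e-6)
  }
  # growth reaction inside the expression sector is a hard error
  bad <- mc$me
  bad@reactions$subsystem[bad@reactions$id == "BIOMASS"] <- "Translation"
  expect_error(stripExpression(bad), "expression")
})

test_that("feasibility is monotone in mu for generated models", {
  for (s in c(11, 12)) {
    me <- makeMinicell(randomMinicellParams(s))$me
    feas <- vapply(seq(0, muMaxHint(me), length.out = 40), isFeasible,
                   logical(1), model = me)
    # TRUEs form a prefix: no infeasible window below a feasible point
    expect_true(all(diff(as.integer(feas)) <= 0))
  }
})
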