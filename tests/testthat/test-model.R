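test_that("model validity rejects structural defects", {
  rxn <- data.frame(id = c("r1", "grow"), lower_bound = c(0, 0),
                    upper_bound = c(10, 10),
                    subsystem = c("Metabolism", "Biomass"))
  sto <- data.frame(reaction = c("r1", "grow"), metabolite = c("m", "m"),
                    a = c(1, -1), b = c(0, 0))
  ok <- MEModel(metabolites = "m", reactions = rxn, stoichiometry = sto,
                growthReactionId = "grow", muMaxHint = 2)
  expect_s4_class(ok, "MEModel")

  expect_error(
    MEModel(metabolites = "m", reactions = rxn,
            stoichiometry = transform(sto, metabolite = c("m", "zz")),
            growthReactionId = "grow", muMaxHint = 2),
    "unknown metabolites.*zz")
  expect_error(
    MEModel(metabolites = "m", reactions = rxn, stoichiometry = sto,
            growthReactionId = "absent", muMaxHint = 2),
    "growth_reaction_id")
  expect_error(
    MEModel(metabolites = "m",
            reactions = transform(rxn, lower_bound = c(20, 0)),
            stoichiometry = sto, growthReactionId = "grow", muMaxHint = 2),
    "lower_bound > upper_bound")
  expect_error(
    MEModel(metabolites = "m", reactions = rxn, stoichiometry = sto,
            growthReactionId = "grow", muMaxHint = -1),
    "mu_max_hint")
  expect_error(
    MEModel(metabolites = "m", reactions = rxn, stoichiometry = sto,
            genes = "g1", translationOf = c(g1 = "nope"),
            growthReactionId = "grow", muMaxHint = 2),
    "translation_of")
})

test_that("accessors expose the model pieces", {
  mc <- makeMinicell()
  me <- mc$me
  expect_true("glc" %in% metabolites(me))
  expect_identical(growthReaction(me), "BIOMASS")
  expect_gt(muMaxHint(me), 0)
  expect_identical(translationReaction(me, "g_rib"), "TL_rib")
  expect_error(translationReaction(me, "nope"), "unknown gene")
  subs <- reactionSubsystems(me)
  expect_identical(unname(subs["RESP"]), "Respiration")
  expect_true(all(genes(me) %in% names(me@translationOf)))
  expect_output(show(me), "MEModel with")
})
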