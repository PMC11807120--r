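test_that("templates apply deterministic, chemically valid transforms", {
  tpl <- toy_templates()
  cases <- list(
    list("Nc1ccccc1", "amidation_propionyl", "CCC(=O)Nc1ccccc1"),
    list("Nc1ccccc1", "sulfonamidation_mesyl", "CS(=O)(=O)Nc1ccccc1"),
    list("Brc1ccccc1", "snar_ethylamine", "CCNc1ccccc1"),
    list("Oc1ccccc1", "ether_ethylation", "CCOc1ccccc1"),
    list("O=Cc1ccccc1", "reductive_amination_ethylamine", "CCNCc1ccccc1"),
    list("O=[N+]([O-])c1ccccc1", "nitro_reduction", "Nc1ccccc1"),
    list("COC(=O)c1ccccc1", "ester_hydrolysis_methyl", "OC(=O)c1ccccc1"),
    list("CC(C)(C)OC(=O)Nc1ccccc1", "boc_deprotection", "Nc1ccccc1"))
  for (cs in cases) {
    expect_identical(apply_template(cs[[1]], tpl[[cs[[2]]]]),
                     canonical_smiles(cs[[3]]), label = cs[[2]])
  }
})

test_that("non-matching and consumed patterns give no-match", {
  tpl <- toy_templates()
  expect_true(is.na(apply_template("CCO", tpl$amidation_propionyl)))
  once <- apply_template("Oc1ccccc1", tpl$ether_ethylation)
  expect_true(is.na(apply_template(once, tpl$ether_ethylation)))
})

test_that("multi-site molecules resolve to the lowest-rank match site", {
  tpl <- toy_templates()
  m <- canonical_smiles("Nc1ccc(N)c(Br)c1")
  p1 <- apply_template(m, tpl$amidation_propionyl)
  expect_false(is.na(p1))
  expect_identical(apply_template(m, tpl$amidation_propionyl), p1)
  # still exactly one amine consumed
  expect_equal(smarts_count(p1, "[NX3;H2]"), 1L)
})

test_that("the generated dataset is deterministic and self-consistent", {
  cfg <- fx_grammar_cfg()
  ds <- fx_dataset()
  expect_identical(ds, generate_reaction_dataset(cfg))
  expect_true(all(is_valid_smiles(ds$product)))
  expect_true(all(ds$reactant == canonical_smiles(ds$reactant)))
  tpl <- cfg$templates
  set.seed(3)
  idx <- sample(nrow(ds), 25)
  for (i in idx) {
    expect_identical(apply_template(ds$reactant[i], tpl[[ds$template[i] + 1]]),
                     ds$product[i])
  }
})

test_that("ambiguity sits near its target and one reactant has >= 2 templates", {
  ds <- fx_dataset()
  amb <- attr(ds, "ambiguity")
  cfg <- fx_grammar_cfg()
  expect_lte(abs(amb - cfg$ambiguity_target), 0.25 * cfg$ambiguity_target)
  counts <- table(ds$reactant)
  expect_gte(max(counts), 2)
  # the ambiguity makes the unconditional optimum land near 1/target
  bayes <- bayes_accuracy_unconditional(ds)
  expect_gt(bayes, 0.2)
  expect_lt(bayes, 0.55)
})

test_that("grammar closure supports routes at least four steps deep", {
  tpl <- toy_templates()
  start <- generate_start_molecules(grammar_config(n_start = 10))
  deepest <- 0
  for (m in start) {
    cur <- m
    for (d in 1:4) {
      idx <- applicable_templates(cur, tpl)
      if (length(idx) == 0) break
      cur <- apply_template(cur, tpl[[idx[1] + 1]])
      deepest <- max(deepest, d)
    }
    if (deepest >= 4) break
  }
  expect_gte(deepest, 4)
})

test_that("activity labels follow the pharmacophore rule exactly at zero noise", {
  mols <- fx_molecules()
  rule <- activity_rule(label_noise = 0)
  act <- generate_activity_dataset(mols, rule)
  expect_identical(act$label,
                   as.integer(smarts_count(act$smiles, rule$pharmacophore) > 0))
  expect_gt(sum(act$label), 0)
  expect_gt(sum(act$label == 0), 0)
  expect_error(generate_activity_dataset("CCO", rule), "matches no molecule")
})

test_that("label noise flips a binomially plausible number of labels", {
  mols <- fx_molecules()
  n <- length(mols)
  rule <- activity_rule(label_noise = 0.1, seed = 5)
  act <- generate_activity_dataset(mols, rule)
  flipped <- attr(act, "n_flipped")
  # central 99% binomial band
  expect_gte(flipped, qbinom(0.005, n, 0.1))
  expect_lte(flipped, qbinom(0.995, n, 0.1))
  act2 <- generate_activity_dataset(mols, rule)
  expect_identical(act, act2)
})
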