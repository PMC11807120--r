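test_that("tokenizer follows the reaction-predictor segmentation", {
  expect_identical(tokenize_smiles("C"), "C")
  expect_identical(tokenize_smiles("c1ccccc1Br"),
                   c("c", "1", "c", "c", "c", "c", "c", "1", "Br"))
  expect_identical(tokenize_smiles("CC(=O)O"),
                   c("C", "C", "(", "=", "O", ")", "O"))
  expect_identical(tokenize_smiles("[O-][N+](=O)c1ccccc1%12")[1:2],
                   c("[O-]", "[N+]"))
  expect_identical(tokenize_smiles("C%12CC%12")[2], "%12")
  expect_error(tokenize_smiles("C!C"), "position 2")
})

test_that("tokenize/detokenize is the identity across the grammar corpus", {
  mols <- fx_molecules()
  expect_true(all(vapply(mols, function(s) {
    detokenize(tokenize_smiles(s)) == s
  }, logical(1))))
})

test_that("vocabulary is bijective, reserved ids distinct, stable on disk", {
  v <- build_vocab(c("CCO", "c1ccccc1Br"), n_templates = 5)
  expect_false(anyDuplicated(v$symbols) > 0)
  expect_identical(v$symbols[v$ids[v$symbols]], v$symbols)
  expect_identical(sort(c(v$pad, v$bos, v$eos, v$unk)), 1:4)
  expect_true(all(condition_token(0:4) %in% v$symbols))
  path <- withr::local_tempfile(fileext = ".json")
  vocab_to_json(v, path)
  v2 <- vocab_from_json(path)
  expect_identical(v2$symbols, v$symbols)
  expect_identical(v2$ids, v$ids)
  expect_error(encode_tokens(v, "Si", strict = TRUE), "outside vocabulary")
  expect_identical(encode_tokens(v, "Si"), v$unk)
})

test_that("reagent removal preserves order and flags emptied reactions", {
  rx <- tibble::tibble(
    reactants = list(c("CCO", "ClCCl"), "ClCCl"),
    products = list("CCOC(C)=O", "CCO"),
    template = c(0L, 1L), source_id = c("a", "b"))
  expect_message(out <- remove_reagents(rx, c("ClCCl")), "1 reaction")
  expect_identical(out$reactants[[1]], "CCO")
  expect_true(out$flagged[2])
  # empty reagent list leaves input unchanged
  out2 <- remove_reagents(rx, character(0))
  expect_identical(out2$reactants, rx$reactants)
  expect_false(any(out2$flagged))
})

test_that("pairing maximizes ECFP4 Tanimoto with deterministic ties", {
  p <- pair_reaction("CCO", "CCOC(C)=O")
  expect_identical(p$reactant, "CCO")
  p2 <- pair_reaction(c("CCO", "CCN"), "CCO")
  expect_identical(p2$reactant, "CCO")
  expect_equal(p2$similarity, 1)
  expect_error(pair_reaction(character(0), "CCO"), "empty side")
})

test_that("pairing beats every other combination (brute-force property)", {
  mols <- fx_molecules()
  set.seed(7)
  for (i in 1:20) {
    reactants <- sample(mols, 3)
    products <- sample(mols, 2)
    p <- pair_reaction(reactants, products)
    best <- max(vapply(reactants, function(r) {
      max(vapply(products, function(q) {
        tanimoto(morgan_fp(r, 4), morgan_fp(q, 4))
      }, 0))
    }, 0))
    expect_equal(p$similarity, best)
  }
})

test_that("conditioned sources gain exactly the one condition token", {
  v <- build_vocab(c("CCO", "CCBr"), n_templates = 10)
  tp <- make_training_pair("CCO", "CCBr", 7L, v, conditioned = TRUE)
  expect_identical(tp$source, c("<t_7>", "C", "C", "O"))
  expect_identical(tp$target, c("C", "C", "Br"))
  tu <- make_training_pair("CCO", "CCBr", 7L, v, conditioned = FALSE)
  expect_identical(tu$source, c("C", "C", "O"))
  expect_identical(length(tp$source), length(tu$source) + 1L)
  expect_identical(detokenize(tp$source[-1]), "CCO")
  v2 <- build_vocab("CCO", n_templates = 3)
  expect_error(make_training_pair("CCO", "CCO", 7L, v2), "condition symbol")
})

test_that("splits are exact, seeded partitions", {
  d <- tibble::tibble(x = 1:10)
  sp <- split_dataset(d, c(train = .8, val = .1, test = .1), seed = 0)
  expect_identical(vapply(sp, nrow, 0L), c(train = 8L, val = 1L, test = 1L))
  sp2 <- split_dataset(d, c(train = .8, val = .1, test = .1), seed = 0)
  expect_identical(sp, sp2)
  expect_identical(sort(unname(unlist(lapply(sp, `[[`, "x")))), 1:10)
  expect_error(split_dataset(d[1:2, , drop = FALSE], rep(1 / 3, 3)),
               "fewer records")
})

test_that("the preparation pipeline reads/writes the external dialects", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(dir, grammar_config(n_start = 20, gen_depth = 1,
                                             ambiguity_target = 3.5))
  raw <- read_reactions(paths[["reactions"]])
  expect_true(all(lengths(raw$reactants) == 1))
  prep <- prepare_reactions(raw, reagents = character(0), n_templates = nrow(templates_table()))
  expect_true(all(c("source", "target", "template") %in% names(prep$pairs)))
  expect_true(all(grepl("^<t_", vapply(prep$pairs$source, `[`, "", 1))))
  tsv <- file.path(dir, "pairs.tsv")
  write_pairs_tsv(prep$pairs, tsv)
  line1 <- readLines(tsv, n = 1)
  expect_match(line1, "\t")
  expect_match(line1, "^<t_[0-9]+> ")
})
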