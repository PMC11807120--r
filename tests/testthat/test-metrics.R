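test_that("internal diversity matches hand-computed small cases", {
  # identical molecules: similarity 1 everywhere -> diversity 0
  expect_equal(internal_diversity(c("CCO", "OCC")), 0)
  expect_equal(internal_diversity("CCO"), 0)
  # two molecules with Tanimoto 0 at p = 1: 1 - 2/4
  a <- c(1L, 0L, 0L, 0L)
  b <- c(0L, 1L, 0L, 0L)
  expect_equal(internal_diversity_fp(rbind(a, b), p = 1), 0.5)
  expect_error(internal_diversity(character(0)), "empty")
})

test_that("internal diversity agrees with the brute-force double sum", {
  intdiv_oracle <- function(fps, p) {
    n <- nrow(fps)
    s <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        s <- s + tanimoto(fps[i, ], fps[j, ])^p
      }
    }
    1 - (s / n^2)^(1 / p)
  }
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    fps <- matrix(rbinom(n * 32, 1, 0.3), n)
    p <- sample(1:3, 1)
    expect_equal(internal_diversity_fp(fps, p), intdiv_oracle(fps, p),
                 tolerance = 1e-6)
  }
})

test_that("diversity is permutation-invariant and duplicates never raise it", {
  set.seed(9)
  fps <- matrix(rbinom(5 * 64, 1, 0.2), 5)
  d0 <- internal_diversity_fp(fps)
  expect_equal(internal_diversity_fp(fps[sample(5), ]), d0)
  expect_lte(internal_diversity_fp(rbind(fps, fps[1, ])), d0 + 1e-12)
})

test_that("uniqueness counts follow the constructed fixture", {
  mols <- c("CCO", "CCN", "CCC", "CCCC", "CCCCC", "c1ccccc1", "CCS",
            "CCCl", "OCC", "C(C)N")  # 2 duplicates by canonicalization
  expect_equal(uniqueness(mols), 0.8)
  ref <- c("CCO", "CCN", "CCC")
  expect_equal(uniqueness_to_reference(mols, ref), 0.625)
  expect_equal(uniqueness_to_reference(c("CCO", "CCN"), c("CCO", "CCN")), 0)
  expect_equal(uniqueness_to_reference("CCO", character(0)), 1)
  expect_equal(uniqueness(rep("CCO", 3)), 1 / 3)
})

test_that("threshold counting is strict and uses the total as denominator", {
  g <- tibble::tibble(smiles = c("a", "b"), reward = c(0.6, 0.4))
  ft <- fraction_above_threshold(g)
  expect_equal(ft$count, 1)
  expect_equal(ft$fraction, 0.5)
  g2 <- tibble::tibble(smiles = "a", reward = 0.5)
  expect_equal(fraction_above_threshold(g2)$count, 0)
  g3 <- tibble::tibble(smiles = c("a", "b"), reward = c(0, 0))
  expect_equal(fraction_above_threshold(g3)$fraction, 0)
})

test_that("scaffold retention scores substituent additions as 1", {
  rt <- tibble::tibble(
    smiles = c("Nc1ccccc1", "CCC(=O)Nc1ccccc1"),
    template = c(NA, 0L))
  expect_equal(scaffold_retention_rate(list(rt)), 1)
  # a scaffold-breaking step lowers the rate proportionally
  broken <- tibble::tibble(
    smiles = c("c1ccccc1CCO", "CCO"),  # ring lost
    template = c(NA, 1L))
  expect_equal(scaffold_retention_rate(list(rt, broken)), 0.5)
  expect_error(scaffold_retention_rate(list()), "no routes")
})

test_that("starting-material filters implement the three removal rules", {
  mols <- c("C1CCCCCCCC1",            # 9-ring
            "CCCCCCCCCCCCCCCCCC(=O)NCC",  # amide, MW >= 300
            "Brc1ccccc1",             # survives via halogen
            "CCCCCC")                 # no reactive group
  out <- filter_starting_materials(mols)
  expect_identical(out$keep, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(out$rule[c(1, 2, 4)],
                   c("ring_size", "molecular_weight", "no_reactive_group"))
  # benzene: aromatic ring is not an unsaturated bond under the convention
  expect_false(filter_starting_materials("c1ccccc1")$keep)
  # boundary: MW exactly >= 300 removed
  expect_false(filter_starting_materials("CCCCCCCCCCCCCCCCCCCC=C")$keep &&
                 mol_weight("CCCCCCCCCCCCCCCCCCCC=C") >= 300)
  counts <- attr(out, "removals")
  expect_equal(sum(counts), 3)
})

test_that("ligand efficiency reproduces the worked examples", {
  expect_equal(round(ligand_efficiency(-5.1, 7), 3), 0.729)
  expect_equal(round(ligand_efficiency(-4.5, 7), 3), 0.643)
  expect_equal(ligand_efficiency(0, 10), 0)
  # SMILES input counts heavy atoms without hydrogens
  expect_equal(ligand_efficiency(-7, "c1ccccc1Br"), 1)
  expect_error(ligand_efficiency(-5, 0))
})

fake_result <- function(smiles, reward, depth, total = length(smiles)) {
  structure(list(
    start = "CCO",
    generated = tibble::tibble(smiles = smiles, reward = reward,
                               depth = depth,
                               route_id = seq_along(smiles)),
    routes = list(), counters = tibble::tibble(
      total_generated = total, unique_generated = length(smiles),
      duplicate_children = 0L, reward_evaluations = length(smiles)),
    root_n = 0L, iterations = 0L), class = "search_result")
}

test_that("reaction-step distribution counts depths and conserves mass", {
  res <- fake_result(c("a", "b", "c", "d"), c(.1, .2, .3, .9),
                     c(1L, 1L, 2L, 3L))
  h <- reaction_step_distribution(res)
  expect_identical(h$depth, c(1L, 2L, 3L))
  expect_identical(h$n, c(2L, 1L, 1L))
  expect_equal(sum(h$n), nrow(res$generated))
  empty <- fake_result(character(0), numeric(0), integer(0), total = 0)
  expect_equal(nrow(reaction_step_distribution(empty)), 0)
})

test_that("one reporting call emits the optimization-table columns", {
  res <- fake_result(c("CCO", "CCN", "CCOC"), c(.9, .6, .2), c(1L, 1L, 2L),
                     total = 6)
  rep <- summarize_search(res, reference = "CCO", tau = 0.5)
  expect_named(rep, c("total", "unique", "uniqueness",
                      "uniqueness_to_reference", "above_tau",
                      "pct_above_tau", "diversity", "mean_depth"))
  expect_equal(rep$total, 6)
  expect_equal(rep$unique, 3)
  expect_equal(rep$uniqueness, 0.5)
  expect_equal(rep$uniqueness_to_reference, 2 / 3)
  expect_equal(rep$above_tau, 2)
  expect_equal(rep$pct_above_tau, 100 * 2 / 3)
  expect_equal(rep$mean_depth, 4 / 3)
})
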