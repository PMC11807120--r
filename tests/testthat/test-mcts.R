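test_that("UCB scores match hand evaluation and the unvisited convention", {
  expect_identical(ucb_score(0.3, 0, 5), Inf)
  hand <- 0.5 + 2 * (1 / sqrt(2)) * sqrt(log(10) / 2)
  expect_equal(ucb_score(0.5, 2, 10, cp = 1 / sqrt(2)), hand,
               tolerance = 1e-12)
  # equal Q and N give equal scores (symmetry)
  expect_equal(ucb_score(0.4, 3, 9, 1), ucb_score(0.4, 3, 9, 1))
  expect_error(ucb_score(0.5, -1, 5))
  # scalar-arithmetic oracle over random instances
  set.seed(8)
  for (rep in 1:100) {
    q <- runif(1); ni <- sample(1:50, 1); np <- ni + sample(1:50, 1)
    cp <- runif(1, 0, 2)
    expect_equal(ucb_score(q, ni, np, cp),
                 q + 2 * cp * sqrt(log(np) / ni), tolerance = 1e-6)
  }
})

make_bandit <- function(rewards) {
  root <- synthmcts:::new_search_node("root")
  root$expanded <- TRUE
  for (i in seq_along(rewards)) {
    ch <- synthmcts:::new_search_node(paste0("arm", i), parent = root,
                                      rank = i, depth = 1L)
    root$children <- c(root$children, list(ch))
  }
  root
}

test_that("selection returns the root of a fresh tree and prefers unvisited", {
  cfg <- mcts_config(iterations = 1)
  fresh <- synthmcts:::new_search_node("m")
  expect_identical(select_node(fresh, cfg), fresh)
  root <- make_bandit(c(0.2, 0.8))
  root$N <- 1L
  root$children[[1]]$N <- 1L
  root$children[[1]]$W <- 0.9
  picked <- select_node(root, cfg)
  expect_identical(picked$smiles, "arm2")  # unvisited wins over any Q
})

test_that("selection follows the brute-force argmax path on a fixed tree", {
  cfg <- mcts_config(cp = 0.7)
  root <- make_bandit(c(1, 2, 3))
  root$N <- 30L
  qs <- c(0.2, 0.6, 0.4)
  ns <- c(10L, 12L, 8L)
  for (i in 1:3) {
    root$children[[i]]$N <- ns[i]
    root$children[[i]]$W <- qs[i] * ns[i]
    root$children[[i]]$expanded <- FALSE
  }
  scores <- qs + 2 * 0.7 * sqrt(log(30) / ns)
  expect_identical(select_node(root, cfg)$smiles,
                   paste0("arm", which.max(scores)))
})

test_that("backpropagation updates the full path and Q averages values", {
  root <- synthmcts:::new_search_node("r")
  mid <- synthmcts:::new_search_node("m", parent = root, depth = 1L)
  leaf <- synthmcts:::new_search_node("l", parent = mid, depth = 2L)
  backpropagate(leaf, 0.4)
  expect_equal(c(root$N, mid$N, leaf$N), c(1L, 1L, 1L))
  backpropagate(leaf, 0.8)
  expect_equal(root$W / root$N, 0.6)
  # brute-force oracle: Q equals the mean of all propagated values
  set.seed(13)
  vals <- runif(50)
  root2 <- synthmcts:::new_search_node("r")
  l2 <- synthmcts:::new_search_node("l", parent = root2, depth = 1L)
  for (v in vals) backpropagate(l2, v)
  expect_equal(root2$W / root2$N, mean(vals), tolerance = 1e-9)
  expect_equal(l2$N, 50L)
})

test_that("exploration extremes behave as bandit theory predicts", {
  rewards <- c(0.1, 0.9, 0.5)
  run_bandit <- function(cp, n) {
    root <- make_bandit(rewards)
    cfg <- mcts_config(cp = cp, iterations = n)
    for (i in seq_len(n)) {
      leaf <- select_node(root, cfg)
      arm <- as.integer(sub("arm", "", leaf$smiles))
      backpropagate(leaf, rewards[arm])
    }
    vapply(root$children, function(ch) ch$N, 0L)
  }
  visits_inf <- run_bandit(1e6, 30)
  expect_lte(max(visits_inf) - min(visits_inf), 1)  # uniform +/- 1
  visits_greedy <- run_bandit(0, 30)
  expect_identical(which.max(visits_greedy), 2L)
  expect_gte(visits_greedy[2], 30 - length(rewards))
})

test_that("config invariants reject bad values and carry the defaults", {
  cfg <- mcts_config()
  expect_equal(cfg$iterations, 200)
  expect_equal(cfg$expansion_k, 10)
  expect_equal(cfg$sim_templates, 5)
  expect_equal(cfg$sim_depth, 2)
  expect_equal(cfg$sim_per_template, 1)
  expect_equal(cfg$cp, 1 / sqrt(2))
  expect_error(mcts_config(beam_width = 0))
  expect_error(mcts_config(iterations = -1))
})

test_that("invalid starting materials are rejected before searching", {
  expect_error(run_search("zz", function(s) 0.5, fx_gcn(), fx_cond(),
                          fx_templates()), "invalid starting material")
})
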