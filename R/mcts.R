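# Monte Carlo tree search over virtual reactions.
#
# Nodes are molecules; edges are single-step virtual reactions proposed by
# the template classifier (filtered by substructure match) and realized by
# the conditional sequence model. The four phases: UCB selection, expansion
# through enumerate_products(), fixed-schedule simulation (5 sampled
# templates x 1 molecule x 2 steps, value = max reward over the <= 25
# rollout products), and backpropagation of the value to the root.

#' Search configuration
#'
#' @param cp Exploration constant \eqn{C_p} of the UCB score (default
#'   \eqn{1/\sqrt 2}).
#' @param iterations Number of selection-to-backpropagation cycles
#'   (default 200).
#' @param expansion_k Templates proposed per expansion (default 10).
#' @param beam_width Beam width of the product decoder (default 10).
#' @param sim_templates Templates sampled per simulation step (default 5).
#' @param sim_depth Reaction steps explored per simulation (default 2).
#' @param sim_per_template Molecules generated per sampled template
#'   (default 1).
#' @param max_depth Route-length cap of the tree (default 10).
#' @param seed Integer seed.
#' @return List of class `mcts_config`.
#' @export
mcts_config <- function(cp = 1 / sqrt(2), iterations = 200, expansion_k = 10,
                        beam_width = 10, sim_templates = 5, sim_depth = 2,
                        sim_per_template = 1, max_depth = 10, seed = 1L) {
  stopifnot(cp >= 0, iterations >= 0, expansion_k >= 1, beam_width >= 1,
            sim_templates >= 1, sim_depth >= 1, sim_per_template >= 1,
            max_depth >= 1)
  structure(list(cp = cp, iterations = iterations,
                 expansion_k = expansion_k, beam_width = beam_width,
                 sim_templates = sim_templates, sim_depth = sim_depth,
                 sim_per_template = sim_per_template, max_depth = max_depth,
                 seed = as.integer(seed)),
            class = "mcts_config")
}

#' Upper-confidence-bound score of a child node
#'
#' \eqn{Q(s_i) + 2 C_p \sqrt{\ln N(s_p) / N(s_i)}}; an unvisited child
#' (\eqn{N(s_i) = 0}) scores \eqn{+\infty} so it is selected first.
#'
#' @param q Mean value \eqn{Q(s_i) = W(s_i)/N(s_i)} of the child.
#' @param n_child Visit count \eqn{N(s_i)} (>= 0).
#' @param n_parent Visit count \eqn{N(s_p)} (>= 1).
#' @param cp Exploration constant.
#' @return The score, possibly `Inf`.
#' @export
ucb_score <- function(q, n_child, n_parent, cp = 1 / sqrt(2)) {
  stopifnot(n_child >= 0, n_parent >= 1)
  if (n_child == 0) return(Inf)
  q + 2 * cp * sqrt(log(n_parent) / n_child)
}

new_search_node <- function(smiles, parent = NULL, template = NA_integer_,
                            rank = NA_integer_, depth = 0L) {
  node <- new.env(parent = emptyenv())
  node$smiles <- smiles
  node$parent <- parent
  node$template <- template
  node$rank <- rank
  node$depth <- depth
  node$children <- list()
  node$N <- 0L
  node$W <- 0
  node$expanded <- FALSE
  node$terminal <- FALSE
  class(node) <- "search_node"
  node
}

#' Select a frontier node by UCB descent
#'
#' Descends from the root by argmax UCB until reaching a node that is
#' unexpanded, terminal, or at the depth cap. Ties go to the child with the
#' lowest provenance rank (children are kept in rank order).
#'
#' @param root A `search_node`.
#' @param cfg An [mcts_config()].
#' @return The selected `search_node`.
#' @export
select_node <- function(root, cfg) {
  node <- root
  while (node$expanded && length(node$children) > 0 &&
         node$depth < cfg$max_depth) {
    best <- NULL
    best_score <- -Inf
    for (ch in node$children) {
      sc <- ucb_score(if (ch$N > 0) ch$W / ch$N else 0, ch$N,
                      max(node$N, 1L), cfg$cp)
      if (sc > best_score) {  # strict: first (lowest-rank) child wins ties
        best_score <- sc
        best <- ch
      }
    }
    if (is.null(best)) break
    node <- best
  }
  node
}

#' Propagate a simulated value to the root
#'
#' Every node on the path from `leaf` to the root gains one visit and the
#' value added to its cumulative score.
#'
#' @param leaf A `search_node`.
#' @param value Numeric value in `[0, 1]`.
#' @export
backpropagate <- function(leaf, value) {
  node <- leaf
  while (!is.null(node)) {
    node$N <- node$N + 1L
    node$W <- node$W + value
    node <- node$parent
  }
  invisible(NULL)
}

# route from root to a tree node as a tibble of (smiles, template) steps
node_route <- function(node) {
  steps <- list()
  cur <- node
  while (!is.null(cur$parent)) {
    steps[[length(steps) + 1L]] <-
      tibble::tibble(smiles = cur$smiles, template = cur$template)
    cur <- cur$parent
  }
  dplyr::bind_rows(c(
    list(tibble::tibble(smiles = cur$smiles, template = NA_integer_)),
    rev(steps)))
}

# shared bookkeeping for every molecule created during the search
record_molecule <- function(store, smiles, reward_val, depth, template,
                            rank, route) {
  store$rows[[length(store$rows) + 1L]] <- tibble::tibble(
    smiles = smiles, reward = reward_val, depth = depth,
    template = template, rank = rank, route_id = length(store$rows) + 1L)
  store$routes[[length(store$routes) + 1L]] <- route
  invisible(NULL)
}

expand_node <- function(node, gcn, transformer, templates, reward, cfg,
                        store) {
  node$expanded <- TRUE
  ranking <- predict_templates(gcn, node$smiles, cfg$expansion_k)
  filt <- filter_matching_templates(node$smiles, ranking, templates)
  prods <- enumerate_products(transformer, node$smiles, filt,
                              width = cfg$beam_width)
  store$n_generated <- store$n_generated + nrow(prods)
  sib <- vapply(node$children, function(ch) ch$smiles, character(1))
  base_route <- node_route(node)
  for (i in seq_len(nrow(prods))) {
    s <- prods$product[i]
    if (s %in% sib || identical(s, node$smiles)) {
      store$n_duplicate <- store$n_duplicate + 1L
      next
    }
    child <- new_search_node(s, parent = node,
                             template = prods$template[i],
                             rank = prods$rank[i],
                             depth = node$depth + 1L)
    node$children <- c(node$children, list(child))
    sib <- c(sib, s)
    rv <- reward(s)
    record_molecule(store, s, rv, child$depth, child$template, child$rank,
                    dplyr::bind_rows(base_route,
                                     tibble::tibble(smiles = s,
                                                    template = child$template)))
  }
  if (length(node$children) == 0) node$terminal <- TRUE
  invisible(node)
}

# one fixed-schedule rollout; returns the node value and the number of
# candidates the max was taken over (instrumentation for the 25-cap)
simulate_node <- function(node, gcn, transformer, templates, reward, cfg,
                          store) {
  base_route <- node_route(node)
  sample_products <- function(smiles) {
    ranking <- predict_templates(gcn, smiles, nrow(templates))
    filt <- filter_matching_templates(smiles, ranking, templates)
    if (nrow(filt) == 0) return(NULL)
    k <- min(cfg$sim_templates, nrow(filt))
    pick <- if (nrow(filt) == 1) 1L else
      sample(seq_len(nrow(filt)), k, prob = filt$score)
    out <- enumerate_products(transformer, smiles, filt[pick, , drop = FALSE],
                              width = 1, per_template_cap = cfg$sim_per_template)
    out
  }
  level1 <- sample_products(node$smiles)
  candidates <- character(0)
  lv1_rewards <- numeric(0)
  if (!is.null(level1) && nrow(level1) > 0) {
    store$n_generated <- store$n_generated + nrow(level1)
    for (i in seq_len(nrow(level1))) {
      rv <- reward(level1$product[i])
      lv1_rewards <- c(lv1_rewards, rv)
      record_molecule(store, level1$product[i], rv, node$depth + 1L,
                      level1$template[i], level1$rank[i],
                      dplyr::bind_rows(base_route,
                                       tibble::tibble(smiles = level1$product[i],
                                                      template = level1$template[i])))
    }
    if (cfg$sim_depth >= 2) {
      for (i in seq_len(nrow(level1))) {
        lvl2 <- sample_products(level1$product[i])
        if (is.null(lvl2) || nrow(lvl2) == 0) next
        store$n_generated <- store$n_generated + nrow(lvl2)
        r1 <- dplyr::bind_rows(base_route,
                               tibble::tibble(smiles = level1$product[i],
                                              template = level1$template[i]))
        for (j in seq_len(nrow(lvl2))) {
          rv <- reward(lvl2$product[j])
          candidates <- c(candidates, lvl2$product[j])
          record_molecule(store, lvl2$product[j], rv, node$depth + 2L,
                          lvl2$template[j], lvl2$rank[j],
                          dplyr::bind_rows(r1,
                                           tibble::tibble(smiles = lvl2$product[j],
                                                          template = lvl2$template[j])))
        }
      }
    }
  }
  if (length(candidates) > 0) {
    vals <- vapply(candidates, reward, 0)  # cached: no extra evaluations
    list(value = max(vals), n_candidates = length(candidates))
  } else if (length(lv1_rewards) > 0) {
    list(value = max(lv1_rewards), n_candidates = length(lv1_rewards))
  } else {
    list(value = reward(node$smiles), n_candidates = 1L)
  }
}

#' Run the Monte Carlo tree search
#'
#' Executes `cfg$iterations` selection, expansion, simulation and
#' backpropagation cycles from the starting material and collects every
#' molecule created along the way with its reward, depth and synthetic
#' route.
#'
#' @param start Starting-material SMILES (must parse).
#' @param reward A reward (see [as_reward()]); plain functions and
#'   `qsar_model`s are wrapped automatically.
#' @param gcn A trained `gcn_model`.
#' @param transformer A trained conditional `seq2seq_transformer`.
#' @param templates Template metadata table ([templates_table()]).
#' @param cfg An [mcts_config()].
#' @return Object of class `search_result`: `generated` (deduplicated
#'   tibble: smiles, reward, depth, template, route_id), `routes`,
#'   `counters`, `root_n`, `iterations`, `max_sim_candidates`.
#' @export
run_search <- function(start, reward, gcn, transformer, templates,
                       cfg = mcts_config()) {
  can <- canonical_smiles(start)
  if (is.na(can)) stop("invalid starting material: ", start)
  if (!inherits(reward, "reward_function")) reward <- as_reward(reward)
  store <- new.env(parent = emptyenv())
  store$rows <- list()
  store$routes <- list()
  store$n_generated <- 0L
  store$n_duplicate <- 0L
  root <- new_search_node(can)
  calls0 <- reward_calls(reward)
  max_cand <- 0L
  withr::with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      leaf <- select_node(root, cfg)
      if (!leaf$expanded && leaf$depth < cfg$max_depth) {
        expand_node(leaf, gcn, transformer, templates, reward, cfg, store)
      }
      target <- if (length(leaf$children) > 0) leaf$children[[1]] else leaf
      sim <- simulate_node(target, gcn, transformer, templates, reward, cfg,
                           store)
      max_cand <- max(max_cand, sim$n_candidates)
      backpropagate(target, sim$value)
    }
  })
  rows <- dplyr::bind_rows(store$rows)
  generated <- if (nrow(rows) > 0) {
    dplyr::arrange(
      dplyr::ungroup(dplyr::slice_max(
        dplyr::group_by(rows, .data$smiles), .data$reward, n = 1,
        with_ties = FALSE)),
      dplyr::desc(.data$reward))
  } else {
    rows
  }
  structure(
    list(start = can, generated = generated, routes = store$routes,
         counters = tibble::tibble(
           total_generated = store$n_generated,
           unique_generated = nrow(generated),
           duplicate_children = store$n_duplicate,
           reward_evaluations = reward_calls(reward) - calls0),
         root_n = root$N, iterations = cfg$iterations,
         max_sim_candidates = max_cand, cfg = cfg, root = root),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> start %s; %d iterations, %d unique molecules, best reward %.3f\n",
    x$start, x$iterations, nrow(x$generated),
    if (nrow(x$generated)) max(x$generated$reward) else NA))
  invisible(x)
}

#' Extract the synthetic route of a generated molecule
#'
#' @param result A `search_result`.
#' @param smiles Molecule to trace (defaults to the best-reward molecule).
#' @return Tibble of route steps: `smiles`, `template` (NA for the starting
#'   material); route length equals the molecule's reaction depth.
#' @export
extract_route <- function(result, smiles = NULL) {
  g <- result$generated
  if (is.null(smiles)) {
    if (nrow(g) == 0) {
      return(tibble::tibble(smiles = result$start, template = NA_integer_))
    }
    smiles <- g$smiles[which.max(g$reward)]
  }
  can <- canonical_smiles(smiles)
  if (identical(can, result$start)) {
    return(tibble::tibble(smiles = result$start, template = NA_integer_))
  }
  i <- match(can, g$smiles)
  if (is.na(i)) stop("molecule was not generated in this search: ", smiles)
  result$routes[[g$route_id[i]]]
}

#' Random-rollout baseline with a fixed reward budget
#'
#' Repeated random walks from the starting material: at each step a
#' template is drawn uniformly from the applicable set and one product
#' decoded; every product is scored until `n_evals` distinct reward
#' evaluations are spent. The comparison partner for the guided search.
#'
#' @param start Starting-material SMILES.
#' @param reward A reward function (wrapped as in [run_search()]).
#' @param transformer,templates As in [run_search()].
#' @param n_evals Reward-evaluation budget.
#' @param max_depth Walk-length cap.
#' @param seed Integer seed.
#' @return List with `best` (best reward found) and `n_evals_used`.
#' @export
run_random_baseline <- function(start, reward, transformer, templates,
                                n_evals, max_depth = 10, seed = 1L) {
  can <- canonical_smiles(start)
  if (!inherits(reward, "reward_function")) reward <- as_reward(reward)
  calls0 <- reward_calls(reward)
  best <- -Inf
  stale <- 0L
  withr::with_seed(seed, {
    while (reward_calls(reward) - calls0 < n_evals) {
      before <- reward_calls(reward)
      cur <- can
      for (d in seq_len(max_depth)) {
        idx <- which(vapply(templates$smarts, function(pt) {
          smarts_count(cur, pt) > 0
        }, logical(1)))
        if (length(idx) == 0) break
        ti <- templates[sample(idx, 1), , drop = FALSE]
        prods <- enumerate_products(transformer, cur, ti, width = 1)
        if (nrow(prods) == 0) break
        cur <- prods$product[1]
        best <- max(best, reward(cur))
        if (reward_calls(reward) - calls0 >= n_evals) break
      }
      # random walks revisit cached molecules; stop once the reachable set
      # is exhausted (no new evaluations over many consecutive walks)
      stale <- if (reward_calls(reward) == before) stale + 1L else 0L
      if (stale >= 25L) break
    }
  })
  list(best = best, n_evals_used = reward_calls(reward) - calls0)
}
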