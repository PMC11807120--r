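# Desk-scale synthetic reaction grammar.
#
# A small library of template-labeled single-reactant -> single-product
# transforms (amidation, sulfonamidation, nucleophilic aromatic substitution,
# aryl coupling, etherification, reductive amination, N-alkylation, and three
# deprotection-like reductions/hydrolyses). Transforms are deterministic
# graph edits applied at the SMARTS match with the lowest canonical atom
# rank, so the grammar doubles as the ground-truth oracle for the sequence
# model, the template classifier and the tree search. One reactant typically
# admits several templates with different products, which is exactly the
# ambiguity the condition token is meant to resolve.

# --- graph-edit helpers -----------------------------------------------------

as_editable <- function(smiles) {
  g <- mol_graph(smiles)
  list(atoms = tibble::tibble(symbol = g$atoms$symbol,
                              charge = g$atoms$charge),
       bonds = tibble::tibble(a1 = g$bonds$a1, a2 = g$bonds$a2,
                              order = g$bonds$order))
}

g_add_atoms <- function(g, symbols) {
  start <- nrow(g$atoms)
  g$atoms <- dplyr::bind_rows(
    g$atoms, tibble::tibble(symbol = symbols, charge = 0L))
  attr(g, "new") <- start + seq_along(symbols)
  g
}

g_add_bonds <- function(g, a1, a2, order) {
  g$bonds <- dplyr::bind_rows(
    g$bonds, tibble::tibble(a1 = as.integer(a1), a2 = as.integer(a2),
                            order = as.integer(order)))
  g
}

g_delete_atoms <- function(g, idx) {
  keep <- setdiff(seq_len(nrow(g$atoms)), idx)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  g$bonds <- g$bonds[!(g$bonds$a1 %in% idx) & !(g$bonds$a2 %in% idx), ,
                     drop = FALSE]
  g$bonds$a1 <- remap[g$bonds$a1]
  g$bonds$a2 <- remap[g$bonds$a2]
  g$atoms <- g$atoms[keep, , drop = FALSE]
  g
}

g_set_element <- function(g, i, symbol) {
  g$atoms$symbol[i] <- symbol
  g
}

g_set_charge <- function(g, i, charge) {
  g$atoms$charge[i] <- as.integer(charge)
  g
}

g_set_order <- function(g, a1, a2, order) {
  hit <- (g$bonds$a1 == a1 & g$bonds$a2 == a2) |
         (g$bonds$a1 == a2 & g$bonds$a2 == a1)
  stopifnot(any(hit))
  g$bonds$order[hit] <- as.integer(order)
  g
}

# attach a linear chain of new atoms to an existing atom
g_attach_chain <- function(g, at, symbols, orders) {
  g <- g_add_atoms(g, symbols)
  new <- attr(g, "new")
  g_add_bonds(g, c(at, utils::head(new, -1)), new, orders)
}

# --- template library -------------------------------------------------------

new_toy_template <- function(index, name, smarts, transform,
                             single_product = FALSE) {
  structure(list(index = as.integer(index), name = name, smarts = smarts,
                 transform = transform, single_product = single_product),
            class = "toy_template")
}

#' @export
print.toy_template <- function(x, ...) {
  cat("<toy_template ", x$index, "> ", x$name, "  [", x$smarts, "]",
      if (x$single_product) "  (single product)", "\n", sep = "")
  invisible(x)
}

.amine_primary <- "[NX3;H2;$([N][#6]);!$([N]C=O);!$([N]S)]"
.amine_secondary <- "[NX3;H1;$([N]([#6])[#6]);!$([N]C=O);!$([N]S)]"

#' The built-in toy reaction-template library
#'
#' Ten transforms modeled on common medicinal-chemistry reactions. Partner
#' reactants (acyl chlorides, alkylating agents, boronic acids...) are
#' implicit: each transform adds a fixed building block, mirroring how a
#' reaction-conditioned sequence model learns the partner from the template
#' and the reactant/product difference. Deprotection-like templates are
#' annotated `single_product`.
#'
#' @return Named list of `toy_template` objects (indices 0-9).
#' @export
toy_templates <- function() {
  tpl <- list(
    new_toy_template(0L, "amidation_propionyl", .amine_primary,
      function(g, m) {
        g <- g_add_atoms(g, c("C", "O", "C", "C"))
        new <- attr(g, "new")
        g_add_bonds(g, c(m[1], new[1], new[1], new[3]),
                    c(new[1], new[2], new[3], new[4]), c(1, 2, 1, 1))
      }),
    new_toy_template(1L, "sulfonamidation_mesyl", .amine_primary,
      function(g, m) {
        g <- g_add_atoms(g, c("S", "O", "O", "C"))
        new <- attr(g, "new")
        g_add_bonds(g, c(m[1], new[1], new[1], new[1]),
                    c(new[1], new[2], new[3], new[4]), c(1, 2, 2, 1))
      }),
    new_toy_template(2L, "snar_ethylamine", "[c][Br]",
      function(g, m) {
        g <- g_delete_atoms(g, m[2])
        at <- m[1] - sum(m[2] < m[1])
        g_attach_chain(g, at, c("N", "C", "C"), c(1, 1, 1))
      }),
    new_toy_template(3L, "aryl_coupling_phenyl", "[c][Br]",
      function(g, m) {
        g <- g_delete_atoms(g, m[2])
        at <- m[1] - sum(m[2] < m[1])
        g <- g_add_atoms(g, rep("C", 6))
        new <- attr(g, "new")
        g <- g_add_bonds(g, at, new[1], 1)
        g_add_bonds(g, new, c(new[-1], new[1]), c(2, 1, 2, 1, 2, 1))
      }),
    new_toy_template(4L, "ether_ethylation", "[OX2H][c]",
      function(g, m) g_attach_chain(g, m[1], c("C", "C"), c(1, 1))),
    new_toy_template(5L, "reductive_amination_ethylamine", "[CX3H1]=[OX1]",
      function(g, m) {
        g <- g_set_element(g, m[2], "N")
        g <- g_set_order(g, m[1], m[2], 1)
        g_attach_chain(g, m[2], c("C", "C"), c(1, 1))
      }),
    new_toy_template(6L, "amine_ethylation", .amine_secondary,
      function(g, m) g_attach_chain(g, m[1], c("C", "C"), c(1, 1))),
    new_toy_template(7L, "nitro_reduction", "[NX3+](=[OX1])[OX1-]",
      function(g, m) {
        g <- g_set_charge(g, m[1], 0)
        g_delete_atoms(g, m[2:3])
      }, single_product = TRUE),
    new_toy_template(8L, "ester_hydrolysis_methyl",
      "[CX3](=[OX1])[OX2][CH3]",
      function(g, m) g_delete_atoms(g, m[4]), single_product = TRUE),
    new_toy_template(9L, "boc_deprotection",
      "[NX3][CX3](=[OX1])[OX2][CX4]([CH3])([CH3])[CH3]",
      function(g, m) g_delete_atoms(g, m[2:8]), single_product = TRUE),
    new_toy_template(10L, "acetylation_amine", .amine_primary,
      function(g, m) {
        g <- g_add_atoms(g, c("C", "O", "C"))
        new <- attr(g, "new")
        g_add_bonds(g, c(m[1], new[1], new[1]),
                    c(new[1], new[2], new[3]), c(1, 2, 1))
      }),
    new_toy_template(11L, "snar_methoxylation", "[c][Br]",
      function(g, m) {
        g <- g_delete_atoms(g, m[2])
        at <- m[1] - sum(m[2] < m[1])
        g_attach_chain(g, at, c("O", "C"), c(1, 1))
      }),
    new_toy_template(12L, "phenol_acetylation", "[OX2H][c]",
      function(g, m) {
        g <- g_add_atoms(g, c("C", "O", "C"))
        new <- attr(g, "new")
        g_add_bonds(g, c(m[1], new[1], new[1]),
                    c(new[1], new[2], new[3]), c(1, 2, 1))
      }),
    new_toy_template(13L, "aldehyde_reduction", "[CX3H1]=[OX1]",
      function(g, m) g_set_order(g, m[1], m[2], 1), single_product = TRUE),
    new_toy_template(14L, "ester_aminolysis",
      "[CX3](=[OX1])[OX2][CH3]",
      function(g, m) {
        g <- g_delete_atoms(g, m[4])
        at <- m[3] - sum(m[4] < m[3])
        g <- g_set_element(g, at, "N")
        g_attach_chain(g, at, c("C", "C"), c(1, 1))
      })
  )
  names(tpl) <- purrr::map_chr(tpl, "name")
  tpl
}

#' Template metadata as a table
#'
#' @param templates A list of `toy_template` objects.
#' @return Tibble with `template`, `name`, `smarts`, `single_product` —
#'   the reactant-side metadata consumed by the template filter.
#' @export
templates_table <- function(templates = toy_templates()) {
  tibble::tibble(
    template = purrr::map_int(templates, "index"),
    name = purrr::map_chr(templates, "name"),
    smarts = purrr::map_chr(templates, "smarts"),
    single_product = purrr::map_lgl(templates, "single_product"))
}

#' Apply a toy reaction template to a molecule
#'
#' The transform is applied at the SMARTS match whose (sorted) atom indices
#' in the canonical SMILES parse order are lexicographically smallest — the
#' deterministic stand-in for the selectivity a trained sequence model
#' resolves implicitly.
#'
#' @param smiles Reactant SMILES.
#' @param template A `toy_template`.
#' @return Canonical product SMILES, or `NA` when the pattern does not match.
#' @export
apply_template <- function(smiles, template) {
  stopifnot(inherits(template, "toy_template"))
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("invalid SMILES: ", smiles)
  matches <- smarts_matches(can, template$smarts)
  if (length(matches) == 0) return(NA_character_)
  keys <- vapply(matches, function(m) {
    paste(sprintf("%06d", sort(m)), collapse = "")
  }, character(1))
  m <- matches[[order(keys)[1]]]
  g <- template$transform(as_editable(can), m)
  out <- graph_to_smiles(g$atoms, g$bonds)
  if (is.na(out)) {
    stop("template '", template$name, "' produced invalid chemistry on ", can)
  }
  out
}

#' Indices of templates applicable to a molecule
#'
#' @param smiles A single SMILES.
#' @param templates Template list (see [toy_templates()]).
#' @return Integer vector of 0-based template indices.
#' @export
applicable_templates <- function(smiles, templates = toy_templates()) {
  hit <- purrr::map_lgl(templates, function(t) {
    smarts_count(smiles, t$smarts) > 0
  })
  unname(purrr::map_int(templates, "index")[hit])
}

# --- grammar configuration and dataset generation ---------------------------

.substituents <- tibble::tibble(
  smiles = c("N", "Br", "O", "C=O", "[N+](=O)[O-]", "C(=O)OC", "OC",
             "NC(=O)OC(C)(C)C"),
  weight = c(3.5, 3.5, 1, 1, 1, 1, 0.5, 1))

.scaffold_patterns <- c(
  "c1ccc(%s)cc1%s",  # 1,4-disubstituted benzene
  "c1cc(%s)sc1%s",   # disubstituted thiophene
  "c1nc(%s)ccc1%s")  # disubstituted pyridine

#' Configuration of the synthetic reaction grammar
#'
#' @param n_scaffolds Number of ring scaffolds used (1-4).
#' @param n_substituents Number of substituent types used (2-8).
#' @param n_start Number of starting molecules to sample.
#' @param gen_depth Reaction depth enumerated when building the dataset;
#'   products up to this depth appear as reactants of further records, which
#'   is what makes multi-step routes learnable.
#' @param ambiguity_target Desired mean number of applicable templates per
#'   reactant in the emitted dataset.
#' @param templates Template library.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `grammar_config`.
#' @export
grammar_config <- function(n_scaffolds = 2, n_substituents = 6,
                           n_start = 110, gen_depth = 2, ambiguity_target = 3,
                           templates = toy_templates(), seed = 1L) {
  stopifnot(n_scaffolds >= 1, n_scaffolds <= length(.scaffold_patterns),
            n_substituents >= 2, n_substituents <= nrow(.substituents),
            length(templates) >= 2, ambiguity_target >= 1, gen_depth >= 1)
  structure(list(n_scaffolds = n_scaffolds, n_substituents = n_substituents,
                 n_start = n_start, gen_depth = gen_depth,
                 ambiguity_target = ambiguity_target, templates = templates,
                 seed = as.integer(seed)),
            class = "grammar_config")
}

#' Sample the starting-molecule library of the grammar
#'
#' Disubstituted aromatic scaffolds with substituents drawn (with weights
#' favouring amine and aryl bromide, the two-template groups) from the
#' built-in palette.
#'
#' @param cfg A `grammar_config`.
#' @return Character vector of canonical SMILES.
#' @export
generate_start_molecules <- function(cfg = grammar_config()) {
  subs <- .substituents[seq_len(cfg$n_substituents), ]
  withr::with_seed(cfg$seed, {
    out <- character(0)
    tries <- 0
    while (length(out) < cfg$n_start && tries < 50 * cfg$n_start) {
      tries <- tries + 1
      pat <- .scaffold_patterns[sample.int(cfg$n_scaffolds, 1)]
      ab <- sample(subs$smiles, 2, replace = TRUE, prob = subs$weight)
      s <- canonical_smiles(sprintf(pat, ab[1], ab[2]))
      if (!is.na(s) && !(s %in% out)) out <- c(out, s)
    }
    out
  })
}

#' Generate the template-labeled reaction dataset
#'
#' Enumerates, for every molecule reachable from the starting library within
#' `gen_depth - 1` reaction steps, one record per applicable template with
#' the product given by [apply_template()]. The realized mean ambiguity
#' (records per distinct reactant) must land within 25% of
#' `ambiguity_target`, otherwise the configuration is rejected.
#'
#' @param cfg A `grammar_config`.
#' @return Tibble with columns `reactant`, `product`, `template`, `depth`
#'   (depth of the reactant) and attribute `ambiguity` (realized mean).
#' @export
generate_reaction_dataset <- function(cfg = grammar_config()) {
  start <- generate_start_molecules(cfg)
  seen <- character(0)
  level <- start
  records <- list()
  withr::with_seed(cfg$seed + 1L, {
    for (depth in seq_len(cfg$gen_depth)) {
      level <- setdiff(level, seen)
      if (length(level) > 3L * cfg$n_start) {
        # bound deeper levels so reaction products cannot swamp the
        # group-rich starting molecules entirely
        level <- sort(sample(level, 3L * cfg$n_start))
      }
      if (length(level) == 0) break
      seen <- c(seen, level)
      recs <- purrr::map_dfr(level, function(m) {
        idx <- applicable_templates(m, cfg$templates)
        if (length(idx) == 0) return(NULL)
        tibble::tibble(
          reactant = m,
          product = unname(purrr::map_chr(idx, function(i) {
            apply_template(m, cfg$templates[[i + 1L]])
          })),
          template = unname(idx),
          depth = depth - 1L)
      })
      records[[depth]] <- recs
      level <- unique(recs$product)
    }
  })
  out <- dplyr::bind_rows(records)
  stopifnot(all(is_valid_smiles(out$product)))
  amb <- nrow(out) / dplyr::n_distinct(out$reactant)
  if (abs(amb - cfg$ambiguity_target) > 0.25 * cfg$ambiguity_target) {
    stop("realized mean ambiguity ", round(amb, 2),
         " misses the target ", cfg$ambiguity_target, " by more than 25%")
  }
  multi <- dplyr::count(out, .data$reactant)
  stopifnot(any(multi$n >= 2))
  attr(out, "ambiguity") <- amb
  out
}

#' Best achievable product-prediction accuracy without the template
#'
#' For a predictor that sees only the reactant, the optimum is to emit each
#' reactant's most frequent product; the bound is computed by enumerating
#' the dataset. With mean ambiguity near 3 it sits near 1/3 — the quantity a
#' trained unconditional model plateaus at.
#'
#' @param dataset Reaction tibble from [generate_reaction_dataset()].
#' @return The exact accuracy bound in `[0, 1]`.
#' @export
bayes_accuracy_unconditional <- function(dataset) {
  per <- dplyr::summarise(
    dplyr::group_by(dataset, .data$reactant),
    best = max(table(.data$product)), n = dplyr::n(), .groups = "drop")
  sum(per$best) / sum(per$n)
}

# --- activity rule ----------------------------------------------------------

#' Substructure-driven activity rule
#'
#' Labels are `pharmacophore match XOR Bernoulli(label_noise)`. The default
#' pharmacophore — an N-propionyl amide on a five-membered aromatic ring,
#' i.e. a propionylated aminothiophene within the grammar — is installed by
#' the amidation template, so activity is reachable through the grammar,
#' but specific enough that undirected exploration rarely stumbles on it.
#'
#' @param pharmacophore SMARTS pattern defining activity.
#' @param label_noise Probability of flipping a label, in `[0, 1)`.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `activity_rule`.
#' @export
activity_rule <- function(
    pharmacophore = "[NX3;$(N[c;r5])][CX3](=[OX1])[CH2][CH3]",
    label_noise = 0, seed = 1L) {
  stopifnot(label_noise >= 0, label_noise < 1)
  structure(list(pharmacophore = pharmacophore,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "activity_rule")
}

#' Generate a labeled activity dataset
#'
#' @param molecules Character vector of SMILES.
#' @param rule An [activity_rule()].
#' @return Tibble `smiles`, `label` (0/1) with attribute `n_flipped`.
#' @export
generate_activity_dataset <- function(molecules, rule = activity_rule()) {
  molecules <- unique(stats::na.omit(canonical_smiles(molecules)))
  match <- smarts_count(molecules, rule$pharmacophore) > 0
  if (!any(match)) {
    stop("pharmacophore matches no molecule in the set; adjust the rule")
  }
  flip <- withr::with_seed(
    rule$seed, stats::runif(length(molecules)) < rule$label_noise)
  label <- as.integer(xor(match, flip))
  if (length(unique(label)) < 2) {
    stop("activity labels are single-class; adjust the rule or the noise")
  }
  out <- tibble::tibble(smiles = molecules, label = label)
  attr(out, "n_flipped") <- sum(flip)
  out
}

#' Convert a grammar dataset to the raw-reaction layout
#'
#' @param dataset Tibble from [generate_reaction_dataset()].
#' @return Raw reaction tibble consumable by [pair_reactions()] and
#'   [prepare_reactions()].
#' @export
as_raw_reactions <- function(dataset) {
  tibble::tibble(
    reactants = as.list(dataset$reactant),
    products = as.list(dataset$product),
    template = dataset$template,
    source_id = as.character(seq_len(nrow(dataset))))
}

#' Write grammar fixtures to disk
#'
#' Emits the reaction dataset (CSV: `reactants`, `products`, `template`) and
#' the activity table (CSV: `smiles`, `label`) in the dialect the
#' data-preparation module reads.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A `grammar_config`.
#' @param rule An `activity_rule`.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, cfg = grammar_config(),
                           rule = activity_rule()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_reaction_dataset(cfg)
  rx <- file.path(dir, "reactions.csv")
  utils::write.csv(
    data.frame(reactants = ds$reactant, products = ds$product,
               template = ds$template), rx, row.names = FALSE)
  act <- generate_activity_dataset(unique(c(ds$reactant, ds$product)), rule)
  ac <- file.path(dir, "activity.csv")
  utils::write.csv(as.data.frame(act), ac, row.names = FALSE)
  invisible(c(reactions = rx, activity = ac))
}
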