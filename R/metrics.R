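# Set-level and route-level evaluation metrics, the starting-material
# filters, and the ligand-efficiency helper.

#' Internal diversity of a molecule set
#'
#' \eqn{\mathrm{IntDiv}_p(G) = 1 - (|G|^{-2} \sum_{m_1,m_2 \in G}
#' T(m_1,m_2)^p)^{1/p}} with Tanimoto similarity on 2048-bit ECFP4 and
#' self-pairs included. A single molecule (or a set of copies) has
#' diversity 0.
#'
#' @param smiles Character vector of SMILES (non-empty).
#' @param p Power parameter (integer >= 1).
#' @return Diversity in `[0, 1]`.
#' @export
internal_diversity <- function(smiles, p = 1) {
  if (length(smiles) == 0) stop("empty molecule set")
  internal_diversity_fp(fp_matrix(canonical_smiles(smiles), diameter = 4), p)
}

#' @describeIn internal_diversity Variant on a precomputed 0/1 fingerprint
#'   matrix (one molecule per row).
#' @param fps Fingerprint matrix.
#' @export
internal_diversity_fp <- function(fps, p = 1) {
  stopifnot(nrow(fps) >= 1, p >= 1)
  sim <- tanimoto_matrix(fps)
  1 - mean(sim^p)^(1 / p)
}

#' Uniqueness of a generated set
#'
#' Proportion of distinct canonical molecules among all generated.
#'
#' @param smiles Character vector of generated SMILES.
#' @return Fraction in `[0, 1]`.
#' @export
uniqueness <- function(smiles) {
  if (length(smiles) == 0) stop("empty molecule set")
  length(unique(canonical_smiles(smiles))) / length(smiles)
}

#' Novelty against a reference corpus
#'
#' Fraction of the distinct generated molecules that are absent from the
#' reference set (e.g. the training reactions); 1 when the reference is
#' empty.
#'
#' @param smiles Generated SMILES.
#' @param reference Reference SMILES corpus.
#' @return Fraction in `[0, 1]`.
#' @export
uniqueness_to_reference <- function(smiles, reference) {
  u <- unique(canonical_smiles(smiles))
  if (length(reference) == 0) return(1)
  ref <- unique(canonical_smiles(reference))
  mean(!(u %in% ref))
}

#' Molecules above the reward threshold
#'
#' Count of distinct molecules with reward strictly above `tau`, and the
#' fraction relative to the set's total.
#'
#' @param generated Tibble with `smiles` and `reward` (e.g.
#'   `result$generated`), or a `search_result`.
#' @param tau Threshold (default 0.5).
#' @return Tibble with `count` and `fraction`.
#' @export
fraction_above_threshold <- function(generated, tau = 0.5) {
  if (inherits(generated, "search_result")) generated <- generated$generated
  n <- nrow(generated)
  cnt <- sum(generated$reward > tau)
  tibble::tibble(count = cnt, fraction = if (n > 0) cnt / n else 0)
}

#' Murcko-scaffold retention rate of synthetic routes
#'
#' Fraction of route steps (parent to child) in which the parent's Murcko
#' scaffold is a substructure of the child. Steps whose parent has no
#' scaffold (acyclic) are excluded from the denominator.
#'
#' @param routes A list of route tibbles (`smiles`, `template`) as returned
#'   by [extract_route()], or a `search_result` (all its routes).
#' @return Fraction in `[0, 1]`.
#' @export
scaffold_retention_rate <- function(routes) {
  if (inherits(routes, "search_result")) routes <- routes$routes
  if (inherits(routes, "data.frame")) routes <- list(routes)
  if (length(routes) == 0) stop("no routes supplied")
  kept <- 0L
  total <- 0L
  for (rt in routes) {
    if (nrow(rt) < 2) next
    for (i in seq_len(nrow(rt) - 1)) {
      sc <- murcko_scaffold(rt$smiles[i])
      if (is.na(sc)) next
      total <- total + 1L
      if (isTRUE(has_substructure(rt$smiles[i + 1], sc))) kept <- kept + 1L
    }
  }
  if (total == 0) stop("no scorable route steps (all parents acyclic)")
  kept / total
}

#' Reaction-step distribution of a search
#'
#' Histogram of reaction depths (>= 1) over the deduplicated generated set.
#'
#' @param result A `search_result`.
#' @return Tibble `depth`, `n`; empty when nothing was generated.
#' @export
reaction_step_distribution <- function(result) {
  g <- result$generated
  g <- g[g$depth >= 1, , drop = FALSE]
  if (nrow(g) == 0) return(tibble::tibble(depth = integer(0), n = integer(0)))
  dplyr::count(g, depth = .data$depth)
}

# --- starting-material filters ----------------------------------------------

#' Starting-material filter specification
#'
#' Defaults follow the preparation rules for search starting materials:
#' rings larger than 8 atoms excluded, molecular weight must be below 300,
#' and at least one reactive group — halogen, carbonyl, non-aromatic
#' unsaturated bond, or nucleophilic substituent (hydroxy, primary or
#' secondary amine, thiol) — must be present.
#'
#' @param max_ring_size Largest allowed ring (default 8).
#' @param max_mw Exclusive molecular-weight bound: MW >= this is removed
#'   (default 300).
#' @param required_groups Named character vector of SMARTS; a molecule must
#'   match at least one.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(max_ring_size = 8, max_mw = 300,
                        required_groups = c(
                          halogen = "[F,Cl,Br,I]",
                          carbonyl = "[CX3]=[OX1]",
                          unsaturated = "[C]=[C,N,S]",
                          alkyne = "[C]#[C,N]",
                          hydroxy = "[OX2H]",
                          amine = "[NX3;H1,H2]",
                          thiol = "[SX2H]")) {
  structure(list(max_ring_size = max_ring_size, max_mw = max_mw,
                 required_groups = required_groups),
            class = "filter_spec")
}

#' Filter candidate starting materials
#'
#' Applies, in order: the large-ring rule, the molecular-weight rule and the
#' required-group rule; input order of the survivors is preserved and
#' per-rule removal counts are attached.
#'
#' @param smiles Character vector of SMILES.
#' @param spec A [filter_spec()].
#' @return Tibble `smiles`, `keep`, `rule` (first failed rule or NA), with
#'   attribute `removals` (named counts).
#' @export
filter_starting_materials <- function(smiles, spec = filter_spec()) {
  can <- canonical_smiles(smiles)
  rule <- rep(NA_character_, length(smiles))
  rule[is.na(can)] <- "invalid"
  big <- !is.na(can) & has_large_ring(can, spec$max_ring_size)
  rule[big & is.na(rule)] <- "ring_size"
  mw <- mol_weight(can)
  heavy <- !is.na(can) & mw >= spec$max_mw
  rule[heavy & is.na(rule)] <- "molecular_weight"
  has_group <- rep(FALSE, length(can))
  for (pt in spec$required_groups) {
    has_group <- has_group | (!is.na(can) & smarts_count(can, pt) > 0)
  }
  rule[!has_group & is.na(rule)] <- "no_reactive_group"
  out <- tibble::tibble(smiles = can, keep = is.na(rule), rule = rule)
  attr(out, "removals") <- table(rule, useNA = "no")
  out
}

#' Ligand efficiency
#'
#' Absolute docking score divided by the heavy-atom count.
#'
#' @param docking_score Docking score (kcal/mol, typically negative).
#' @param heavy_atoms Number of heavy atoms (>= 1), or a SMILES string from
#'   which to count them.
#' @return Ligand efficiency.
#' @export
#' @examples
#' ligand_efficiency(-5.1, 7)
ligand_efficiency <- function(docking_score, heavy_atoms) {
  if (is.character(heavy_atoms)) {
    heavy_atoms <- heavy_atom_count(heavy_atoms)
  }
  stopifnot(all(heavy_atoms >= 1))
  abs(docking_score) / heavy_atoms
}

#' Summarize a search the way optimization runs are tabulated
#'
#' One reporting call emitting the column semantics of the structural
#' optimization tables: total molecules generated, uniqueness, novelty to a
#' reference corpus, count and percentage above the reward threshold, and
#' internal diversity of the above-threshold set.
#'
#' @param result A `search_result`.
#' @param reference Reference corpus for novelty (default none).
#' @param tau Reward threshold (default 0.5).
#' @param p Diversity power (default 1).
#' @return One-row tibble: `total`, `unique`, `uniqueness`,
#'   `uniqueness_to_reference`, `above_tau`, `pct_above_tau`, `diversity`,
#'   `mean_depth`.
#' @export
summarize_search <- function(result, reference = character(0), tau = 0.5,
                             p = 1) {
  g <- result$generated
  ft <- fraction_above_threshold(result, tau)
  hi <- g$smiles[g$reward > tau]
  tibble::tibble(
    total = result$counters$total_generated,
    unique = nrow(g),
    uniqueness = if (result$counters$total_generated > 0) {
      nrow(g) / result$counters$total_generated
    } else 0,
    uniqueness_to_reference = uniqueness_to_reference(g$smiles, reference),
    above_tau = ft$count,
    pct_above_tau = 100 * ft$fraction,
    diversity = if (length(hi) > 0) internal_diversity(hi, p) else NA_real_,
    mean_depth = if (nrow(g) > 0) mean(g$depth) else NA_real_)
}
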