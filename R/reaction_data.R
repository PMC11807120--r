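# Reaction-dataset preparation: parsing, reagent removal, Tanimoto pairing,
# conditioned source/target construction and deterministic splits.
#
# A raw reaction table has one row per reaction with list-columns `reactants`
# and `products` (SMILES), an integer `template` in [0, T) and a `source_id`.
# Pairing reduces each reaction to a single (reactant, product) record — the
# training atom of the whole system.

#' Read a reaction table from CSV/TSV
#'
#' Expects columns `reactants`, `products`, `template`; each reaction side may
#' contain several dot-separated SMILES.
#'
#' @param path CSV or TSV file (delimiter chosen by extension).
#' @return A tibble with list-columns `reactants`, `products`, integer
#'   `template` and `source_id`.
#' @export
read_reactions <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("reactants", "products", "template") %in% names(df)))
  tibble::tibble(
    reactants = strsplit(as.character(df$reactants), ".", fixed = TRUE),
    products = strsplit(as.character(df$products), ".", fixed = TRUE),
    template = as.integer(df$template),
    source_id = if ("source_id" %in% names(df)) as.character(df$source_id)
                else as.character(seq_len(nrow(df))))
}

#' Built-in reagent/solvent list
#'
#' Canonical SMILES of species stripped from reaction sides before pairing;
#' seeded with hydrochloric acid, ethyl acetate and dichloromethane and
#' editable via `inst/extdata/reagents.csv`.
#'
#' @return Character vector of canonical SMILES.
#' @export
default_reagents <- function() {
  path <- system.file("extdata", "reagents.csv", package = "synthmcts")
  if (nzchar(path)) {
    canonical_smiles(utils::read.csv(path, stringsAsFactors = FALSE)$smiles)
  } else {
    canonical_smiles(c("Cl", "CCOC(C)=O", "ClCCl"))
  }
}

#' Remove reagents and solvents from reaction sides
#'
#' Deletes any reactant or product whose canonical form is in the reagent
#' list, preserving the order of the survivors. Reactions left with an empty
#' side are flagged (column `flagged`) and the count is reported via message;
#' downstream steps drop flagged rows.
#'
#' @param reactions Raw reaction tibble (see [read_reactions()]).
#' @param reagents Character vector of reagent SMILES (canonicalized here).
#' @return The tibble with cleaned list-columns and a logical `flagged`.
#' @export
remove_reagents <- function(reactions, reagents = default_reagents()) {
  reagents <- stats::na.omit(canonical_smiles(reagents))
  strip <- function(side) {
    if (length(reagents) == 0) return(side)
    side[!(canonical_smiles(side) %in% reagents)]
  }
  out <- reactions
  out$reactants <- lapply(reactions$reactants, strip)
  out$products <- lapply(reactions$products, strip)
  out$flagged <- lengths(out$reactants) == 0 | lengths(out$products) == 0
  if (any(out$flagged)) {
    message(sum(out$flagged),
            " reaction(s) emptied by reagent removal (flagged)")
  }
  out
}

#' Pair one reaction to its most similar reactant/product couple
#'
#' Over all reactant x product combinations, returns the pair with the
#' highest Tanimoto similarity on 2048-bit ECFP4 fingerprints. Ties are
#' broken by lexicographic order of the canonical reactant SMILES, then of
#' the product.
#'
#' @param reactants,products Character vectors of SMILES (non-empty).
#' @return A list with `reactant`, `product` (canonical SMILES) and
#'   `similarity`.
#' @export
pair_reaction <- function(reactants, products) {
  if (length(reactants) == 0 || length(products) == 0) {
    stop("cannot pair a reaction with an empty side")
  }
  r <- sort(unique(stats::na.omit(canonical_smiles(reactants))))
  p <- sort(unique(stats::na.omit(canonical_smiles(products))))
  if (length(r) == 0 || length(p) == 0) stop("no valid molecules to pair")
  best <- NULL
  best_sim <- -1
  for (ri in r) {
    fr <- morgan_fp(ri, diameter = 4)
    for (pi in p) {
      s <- tanimoto(fr, morgan_fp(pi, diameter = 4))
      # strict > keeps the lexicographically first pair on ties
      if (s > best_sim + 1e-12) {
        best_sim <- s
        best <- list(reactant = ri, product = pi, similarity = s)
      }
    }
  }
  best
}

#' Pair every reaction in a table
#'
#' @param reactions Raw reaction tibble; flagged rows (see
#'   [remove_reagents()]) are dropped first.
#' @return Tibble of reaction records: `reactant`, `product` (canonical
#'   SMILES), `template`, `similarity`, `source_id`.
#' @export
pair_reactions <- function(reactions) {
  if (!is.null(reactions$flagged)) {
    reactions <- reactions[!reactions$flagged, , drop = FALSE]
  }
  paired <- purrr::pmap(
    list(reactions$reactants, reactions$products),
    function(r, p) pair_reaction(r, p))
  tibble::tibble(
    reactant = purrr::map_chr(paired, "reactant"),
    product = purrr::map_chr(paired, "product"),
    template = reactions$template,
    similarity = purrr::map_dbl(paired, "similarity"),
    source_id = reactions$source_id)
}

#' Build conditioned source/target token sequences
#'
#' The source is the tokenized reactant, prefixed (when `conditioned`) with
#' the single condition symbol of the reaction template; the target is the
#' tokenized product. Begin/end markers are added by the model layer, not
#' here.
#'
#' @param reactant,product SMILES strings.
#' @param template Integer template index (0-based).
#' @param vocab An `rxn_vocab`; when conditioned, the template symbol must be
#'   in it.
#' @param conditioned Prefix the condition token?
#' @return List with `source` and `target` token vectors.
#' @export
make_training_pair <- function(reactant, product, template, vocab,
                               conditioned = TRUE) {
  src <- tokenize_smiles(reactant)
  if (conditioned) {
    sym <- condition_token(template)
    if (!sym %in% vocab$symbols) {
      stop("condition symbol not in vocabulary: ", sym)
    }
    src <- c(sym, src)
  }
  list(source = src, target = tokenize_smiles(product))
}

#' Deterministic train/validation/test split
#'
#' Exact partition: split sizes are assigned by largest remainder so they sum
#' to the number of rows; the permutation is drawn from the supplied seed
#' only.
#'
#' @param data A data frame (one row per record).
#' @param fractions Named or unnamed numeric vector of positive fractions
#'   summing to 1 (default `c(train = .8, val = .1, test = .1)`).
#' @param seed Integer seed.
#' @return Named list of disjoint data frames covering the input.
#' @export
split_dataset <- function(data,
                          fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 1L) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(data)
  if (n < length(fractions)) {
    stop("fewer records (", n, ") than splits (", length(fractions), ")")
  }
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("split", seq_along(fractions))
  }
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- withr::with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- purrr::map2(starts, ends, function(a, b) {
    data[perm[seq(a, b)], , drop = FALSE]
  })
  names(out) <- names(fractions)
  out
}

#' Run the full reaction-data preparation pipeline
#'
#' Reagent removal, flag-dropping, Tanimoto pairing, deduplication of exact
#' (reactant, product, template) triples, tokenization and vocabulary
#' construction.
#'
#' @param reactions Raw reaction tibble.
#' @param reagents Reagent SMILES (see [default_reagents()]).
#' @param n_templates Number of templates `T`; defaults to
#'   `max(template) + 1`.
#' @param conditioned Build conditioned sources?
#' @return List with `records` (paired tibble), `pairs` (tibble with
#'   list-columns `source`, `target`) and `vocab`.
#' @export
prepare_reactions <- function(reactions, reagents = default_reagents(),
                              n_templates = NULL, conditioned = TRUE) {
  cleaned <- remove_reagents(reactions, reagents)
  records <- pair_reactions(cleaned)
  records <- dplyr::distinct(records, .data$reactant, .data$product,
                             .data$template, .keep_all = TRUE)
  if (is.null(n_templates)) n_templates <- max(records$template) + 1L
  stopifnot(all(records$template >= 0), all(records$template < n_templates))
  vocab <- build_vocab(c(records$reactant, records$product), n_templates)
  pairs <- purrr::pmap(
    list(records$reactant, records$product, records$template),
    function(r, p, t) make_training_pair(r, p, t, vocab, conditioned))
  tbl <- tibble::tibble(
    source = purrr::map(pairs, "source"),
    target = purrr::map(pairs, "target"),
    template = records$template)
  list(records = records, pairs = tbl, vocab = vocab)
}

#' Write token pairs as a two-column TSV
#'
#' One line per pair, `source<TAB>target`, tokens joined by single spaces.
#'
#' @param pairs Tibble with list-columns `source` and `target`.
#' @param path Output file.
#' @export
write_pairs_tsv <- function(pairs, path) {
  lines <- paste(purrr::map_chr(pairs$source, paste, collapse = " "),
                 purrr::map_chr(pairs$target, paste, collapse = " "),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
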