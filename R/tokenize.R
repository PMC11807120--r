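# SMILES tokenization and the sequence vocabulary.
#
# The segmentation follows the convention of transformer-based reaction
# predictors: bracket atoms, two-letter halogens, %nn ring closures and every
# bond/branch symbol are single tokens, so that detokenization is the exact
# inverse of tokenization.

.token_regex <- paste0(
  "^(\\[[^]]+\\]",        # bracket atoms, e.g. [N+], [nH], [C@@H]
  "|Br|Cl",               # two-letter halogens
  "|%[0-9]{2}",           # ring-bond labels >= 10
  "|[BCNOSPFI]|[bcnosp]", # organic-subset atoms
  "|[0-9]",               # ring-bond digits
  "|[()=#+\\\\/.:~@?>*$-]",
  ")")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the vocabulary symbols used by the sequence
#' model. Joining the tokens reproduces the input exactly.
#'
#' @param s A single SMILES string.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize_smiles("c1ccccc1Br")
#' tokenize_smiles("CC(=O)O")
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1, !is.na(s))
  tokens <- character(0)
  rest <- s
  pos <- 1L
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr(.token_regex, rest))
    if (length(m) == 0 || !nzchar(m)) {
      stop("cannot tokenize SMILES at position ", pos, ": \"",
           substr(s, pos, min(pos + 9L, nchar(s))), "\"")
    }
    tokens <- c(tokens, m)
    pos <- pos + nchar(m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  tokens
}

#' Reassemble tokens into a string
#'
#' The exact inverse of [tokenize_smiles()].
#'
#' @param tokens Character vector of tokens.
#' @return A single string.
#' @export
detokenize <- function(tokens) {
  paste0(tokens, collapse = "")
}

# --- vocabulary -------------------------------------------------------------

#' Condition-token symbol for a reaction template
#'
#' @param template_index Integer template indices (0-based).
#' @return Character vector of symbols of the form `<t_i>`.
#' @export
condition_token <- function(template_index) {
  sprintf("<t_%d>", as.integer(template_index))
}

#' Build the sequence-model vocabulary
#'
#' Reserved symbols `<pad>`, `<bos>`, `<eos>`, `<unk>` occupy ids 1-4,
#' followed by one condition symbol per reaction template, followed by the
#' SMILES tokens observed in the corpus (sorted for stability).
#'
#' @param token_lists List of character vectors (tokenized sequences), or a
#'   character vector of SMILES to tokenize.
#' @param n_templates Number of reaction templates `T`; condition symbols
#'   `<t_0>` ... `<t_{T-1}>` are always included.
#' @return An object of class `rxn_vocab`.
#' @export
build_vocab <- function(token_lists, n_templates) {
  stopifnot(n_templates >= 1)
  if (is.character(token_lists)) {
    token_lists <- lapply(token_lists, tokenize_smiles)
  }
  data_tokens <- sort(unique(unlist(token_lists)))
  symbols <- c("<pad>", "<bos>", "<eos>", "<unk>",
               condition_token(seq_len(n_templates) - 1L),
               data_tokens)
  stopifnot(!anyDuplicated(symbols))
  ids <- seq_along(symbols)
  names(ids) <- symbols
  structure(
    list(symbols = symbols, ids = ids, n_templates = as.integer(n_templates),
         pad = 1L, bos = 2L, eos = 3L, unk = 4L),
    class = "rxn_vocab")
}

#' @export
print.rxn_vocab <- function(x, ...) {
  cat("<rxn_vocab> ", length(x$symbols), " symbols (",
      x$n_templates, " condition tokens)\n", sep = "")
  invisible(x)
}

#' Encode tokens as vocabulary ids
#'
#' @param vocab An `rxn_vocab`.
#' @param tokens Character vector of tokens.
#' @param strict Error on unknown tokens instead of mapping to `<unk>`?
#' @return Integer vector of ids.
#' @export
encode_tokens <- function(vocab, tokens, strict = FALSE) {
  ids <- unname(vocab$ids[tokens])
  if (anyNA(ids)) {
    if (strict) stop("tokens outside vocabulary: ",
                     paste(unique(tokens[is.na(ids)]), collapse = " "))
    ids[is.na(ids)] <- vocab$unk
  }
  ids
}

#' Decode vocabulary ids to tokens
#'
#' @param vocab An `rxn_vocab`.
#' @param ids Integer vector of ids.
#' @return Character vector of tokens.
#' @export
decode_ids <- function(vocab, ids) {
  vocab$symbols[ids]
}

#' Save / load a vocabulary as JSON
#'
#' @param vocab An `rxn_vocab`.
#' @param path File path.
#' @return `vocab_from_json` returns the restored `rxn_vocab`.
#' @export
vocab_to_json <- function(vocab, path) {
  jsonlite::write_json(
    list(symbols = vocab$symbols, n_templates = vocab$n_templates),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname vocab_to_json
#' @export
vocab_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  symbols <- x$symbols
  ids <- seq_along(symbols)
  names(ids) <- symbols
  structure(
    list(symbols = symbols, ids = ids,
         n_templates = as.integer(x$n_templates),
         pad = 1L, bos = 2L, eos = 3L, unk = 4L),
    class = "rxn_vocab")
}
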