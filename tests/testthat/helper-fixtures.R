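# Shared fixtures, built lazily and memoized for the whole test run.
#
# The expensive objects (grammar dataset, trained sequence models, template
# classifier, activity model) are the study conditions of the acceptance
# checks and are shared across test files; everything is generated in code
# under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_grammar_cfg <- function() grammar_config(seed = 1L)

fx_transformer_cfg <- function() {
  transformer_config(n_heads = 4, epochs = 250, lr = 2e-3, lr_halflife = 80,
                     batch_size = 16, dropout = 0.1, target_accuracy = 0.95)
}

fx_dataset <- function() {
  fx_get("dataset", function() generate_reaction_dataset(fx_grammar_cfg()))
}

fx_prep <- function() {
  fx_get("prep", function() {
    prepare_reactions(as_raw_reactions(fx_dataset()),
                      reagents = character(0), n_templates = nrow(templates_table()))
  })
}

fx_molecules <- function() {
  ds <- fx_dataset()
  unique(c(ds$reactant, ds$product))
}

fx_cond <- function() {
  fx_get("cond", function() {
    prep <- fx_prep()
    train_seq2seq(prep$pairs, prep$vocab, fx_transformer_cfg(),
                  conditioned = TRUE, seed = 1L, quiet = TRUE)
  })
}

fx_uncond <- function() {
  fx_get("uncond", function() {
    prep <- fx_prep()
    cfg <- fx_transformer_cfg()
    cfg$epochs <- 150
    train_seq2seq(prep$pairs, prep$vocab, cfg,
                  conditioned = FALSE, seed = 1L, quiet = TRUE)
  })
}

fx_gcn <- function() {
  fx_get("gcn", function() {
    ds <- fx_dataset()
    train_gcn(ds, n_templates = nrow(templates_table()), cfg = gcn_config(epochs = 30),
              seed = 1L, quiet = TRUE)
  })
}

fx_qsar <- function() {
  fx_get("qsar", function() {
    act <- generate_activity_dataset(fx_molecules(), activity_rule())
    train_qsar(act, qsar_hyperparams("toy"), seed = 1L)
  })
}

fx_templates <- function() templates_table()

# exhaustive grammar enumeration up to two reaction steps; returns every
# distinct product (the oracle used to prove a high-reward molecule exists)
two_step_products <- function(start) {
  tpl <- toy_templates()
  step <- function(mols) {
    unique(unlist(lapply(mols, function(m) {
      idx <- applicable_templates(m, tpl)
      vapply(idx, function(i) apply_template(m, tpl[[i + 1]]), character(1))
    })))
  }
  l1 <- step(start)
  unique(c(l1, step(l1)))
}

two_step_reachable <- function(start, qsar, tau = 0.5) {
  prods <- two_step_products(start)
  any(vapply(prods, function(s) predict_activity(qsar, s), 0) > tau)
}

# a low-reward starting material whose pharmacophore needs two grammar
# steps (nitro reduction then amidation): nitro present, free amine absent
pick_two_step_start <- function(qsar, rule) {
  fx_get("two_step_start", function() {
    cand <- generate_start_molecules(fx_grammar_cfg())
    cand <- cand[smarts_count(cand, "[NX3+](=[OX1])[OX1-]") > 0 &
                   smarts_count(cand, "[NX3;H2]") == 0 &
                   smarts_count(cand, rule$pharmacophore) == 0]
    rewards <- vapply(cand, function(s) predict_activity(qsar, s), 0)
    cand <- cand[rewards < 0.3]
    stopifnot(length(cand) > 0)
    for (s in cand) {
      if (two_step_reachable(s, qsar, 0.5)) return(s)
    }
    stop("no two-step-reachable starting material in the library")
  })
}
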