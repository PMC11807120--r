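---
title: "Models and methods behind synthmcts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synthmcts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`synthmcts` optimizes molecules under a synthetic-feasibility constraint:
every proposed molecule is the endpoint of a chain of single-step virtual
reactions. This vignette describes the models, the reasoning behind the
parameter defaults, what the bundled synthetic grammar does and does not
emulate, and the numerical choices a maintainer would want written down.

## The optimization loop

A search state is a molecule. One move applies a reaction template `t` to a
molecule `m` and yields a product, realized not by a rule engine but by a
sequence model trained on template-labeled reaction pairs. The Monte Carlo
tree search repeats four phases:

* **Selection.** From the root, descend by maximizing the
  upper-confidence-bound score `Q(s_i) + 2 C_p sqrt(ln N(s_p) / N(s_i))`,
  where `Q = W/N` is a node's mean backed-up value and `N` its visit count.
  Unvisited children score `+Inf` and are therefore explored first, with
  ties resolved toward the lowest beam-rank child; the paper trail of both
  conventions lives in `ucb_score()` and `select_node()`.
* **Expansion.** The template classifier proposes `expansion_k` templates,
  a reactant-side SMARTS filter removes inapplicable ones, and the
  conditional sequence model decodes up to `beam_width` products per
  surviving template (`enumerate_products()`). Products become child nodes;
  each is scored by the reward once (rewards are cached by canonical
  SMILES, so the reward is treated as a pure function). A node is expanded
  at most once; re-selected unexpanded leaves at the depth cap simulate
  instead.
* **Simulation.** A fixed-schedule rollout: sample 5 applicable templates
  (without replacement, weighted by the classifier's filtered softmax
  scores), decode 1 molecule per template, then repeat one level deeper.
  The node value is the maximum reward over the at most 25 second-level
  products, falling back to the first-level products and finally to the
  node's own reward when the grammar dead-ends. We read the schedule's
  "25 or fewer" cap as counting the second-level candidates only — with
  both levels counted the cap could not be met (5 + 25 = 30) — and the
  instrumentation (`max_sim_candidates`) asserts the bound at run time.
* **Backpropagation.** The value is added (`N += 1`, `W += value`) to every
  node from the simulated node to the root.

`C_p` defaults to `1/sqrt(2)`, the standard UCT constant for rewards in
[0, 1]; iterations default to 200, expansion width to 10 and the rollout
schedule to 5 × 1 × 2 as above. The depth cap (10) is a guard against
runaway chains; observed routes use 1–5 steps. Duplicate molecules reached
by different routes remain distinct tree nodes (the tree is not a DAG), but
the reported generated set is deduplicated by canonical SMILES keeping the
maximum-reward route.

## The conditional sequence model

An encoder–decoder transformer in the original post-norm arrangement:
scaled token embeddings plus sinusoidal positions, multi-head self- and
cross-attention, rectifier feed-forward blocks, residual connections and
layer normalization, trained by teacher forcing with Adam. Conditioning is
one extra token: the template index `<t_i>` is prefixed to the *encoder*
input only; the decoder never sees it. Stripping the prefix from the same
prepared pairs trains the unconditional twin, so the two models differ by
exactly one token of information.

Two configurations ship. The full-scale preset mirrors the reference
architecture (dimension 512, 6+6 layers, 8 heads, feed-forward 2048,
dropout 0.1, batch 128). The toy default — dimension 64, 1+1 layers,
4 heads, feed-forward 128, batch 16, learning rate 2e-3 halved every 80
epochs, dropout 0.1 — is the smallest configuration we found to converge
on the bundled grammar; a memorization probe (48 pairs driven to perfect
accuracy) pinned convergence to update count rather than capacity, which is
why the toy preset trades batch size for more optimizer steps.

Numerical choices: beam search scores hypotheses by mean log-probability
(length-normalized); per step only the top-width candidates survive, with
end-marked ones retiring to the finished set, and the search stops once no
active hypothesis's score upper bound (cumulative log-probability over
current length — future tokens only lower the sum) can beat the width-th
finished hypothesis, or after a short patience once the finished set is
full. Note that under length-normalized scoring a wider
beam is not guaranteed to return a better top score; width effects are
therefore characterized empirically (the beam-width/depth trade-off), not
asserted as an identity. Decoding is incremental (per-layer key/value
caches; cross-attention keys projected once per decode) and is tested for
exact equality against a stacked reference implementation. The decode
length cap is 1.5× the longest training target plus 8 tokens; decodes that
fail to parse are dropped and duplicates merged keeping the best rank, with
both counts logged on the result.
Perfect accuracy compares *canonicalized molecules*, not raw strings — the
chemically meaningful reading, and the more permissive one. All forward
and backward passes are hand-written; the attention kernel additionally
exists as a compiled RcppArmadillo path, with tests asserting equality to
the pure-R reference at 1e-12 and a finite-difference gradient check over
every parameter tensor.

## The template classifier

Molecules are `(A, F)` pairs: per-bond-type adjacency indicators over
{single, double, triple, aromatic} and node features (element one-hot over
C/N/O/S/F/Cl/Br/I/other, heavy-degree one-hot, formal charge, aromatic and
ring flags — the composition is our choice; only the tensor form is given
by the architecture). Convolution uses `A~ = D^-1 (A + I)` per bond type —
row normalization with self-loops, our reading of "normalized adjacency" —
followed by sum aggregation and dense layers; defaults follow the selected
full-scale values (dimension 256, one convolution layer, three dense
layers, learning rate 4e-4). Kekulized bond orders inside aromatic rings
are assigned to the aromatic channel only, so resonance spellings cannot
split one ring across channels. Training is plain cross-entropy with
early stopping on validation top-1 accuracy; sum aggregation makes the
network exactly permutation-invariant, which the tests assert by feeding
re-spelled SMILES.

## The reward

A random forest on 2048-bit ECFP6 fingerprints returns the raw averaged
active-class fraction as the activity probability (no calibration — the
0.5 reward threshold applies to raw forest probabilities). The engine
emits 4096-bit fingerprints, folded by OR to 2048. Held-out evaluation
uses a stratified 90/10 split after deduplication by canonical SMILES, so
no molecule can appear on both sides. Full-scale hyperparameter presets
for three protein targets ship for users with real data; note the R forest
expresses the depth bound as a terminal-node cap (`maxnodes`) and has no
minimum-split parameter, so those presets are approximate translations.
No class-imbalance correction is applied. AUC is the trapezoidal ROC area;
a test cross-checks it against a brute-force pairwise concordance count.

## The synthetic grammar

The grammar exists so that every component can be trained and tested
without external data, while keeping the one property the method depends
on: *a single reactant admits several templates with different products*.
Fifteen transforms modeled on common medicinal chemistry (propionylation,
acetylation, mesylation, SNAr amination/methoxylation, aryl coupling,
Williamson and phenol acetylation, reductive amination, N-alkylation,
ester aminolysis, and four single-product reductions/hydrolyses: nitro
reduction, aldehyde reduction, ester hydrolysis, Boc removal) act on
disubstituted benzene and thiophene scaffolds by default (a pyridine
scaffold is available via `n_scaffolds = 3`; it is not in the default set
because the canonical ring direction of pyridines flips with substituent
priority, an orthographic artifact that dominates sequence-model error
without adding chemistry).
Transforms are deterministic graph edits applied at the SMARTS match with
the lowest canonical atom rank — a toy oracle must resolve site selectivity
explicitly where the trained model does so implicitly. Partner reactants
are implicit: each transform adds a fixed building block, which is exactly
what the conditioned model is supposed to infer from template plus
reactant.

Substituents are drawn with weights favouring the amine and aryl-bromide
groups (which carry three templates each) so the realized mean ambiguity
lands near the target of 3; deeper enumeration levels are capped at three
times the starting library so group-poor products do not dilute it. With
the defaults (2 scaffolds, 6 substituent types, 110 starting molecules —
effectively the full combinatorial start space — and 2 enumeration levels)
a dataset holds ~490 records over ~185 reactants with mean ambiguity 2.65
and an unconditional optimum (`bayes_accuracy_unconditional()`, computed by
exact enumeration) of 0.378 — the quantity the unconditional twin is
measured against.

Activity labels follow a hidden substructure rule (default: an N-propionyl
amide on a five-membered aromatic ring — a propionylated aminothiophene)
XOR Bernoulli label noise. The rule is reachable in two grammar steps from
nitrothiophene starting materials (nitro reduction, then propionylation),
but specific enough that undirected rollouts usually miss it, which is what
makes "the guided search must climb from reward ≈ 0 and beat random
exploration" a fair test.

What the grammar does *not* emulate: reagent/solvent noise, multi-reactant
records with ambiguous pairing, template labels that are wrong or
inconsistent, yields, stereochemistry, and the scale (hundreds of
thousands of reactions, 1000 templates) of a patent corpus. Passing tests
on the grammar therefore demonstrate the machinery — conditioning helps
exactly as the ambiguity predicts, the search exploits it — not
patent-scale accuracy numbers.

## Conventions and edge cases

* **Canonicalization** is OpenBabel canonical SMILES, used everywhere
  (pairing, deduplication, uniqueness, caching). "Canonical atom rank"
  means position in the canonical string's parse order.
* **Tokenization** is the reaction-predictor regex dialect: bracket atoms,
  two-letter halogens, `%nn` ring labels and every bond/branch symbol are
  single tokens; join(tokens) reproduces the string exactly, asserted
  corpus-wide.
* **Pairing** maximizes ECFP4/2048 Tanimoto over all reactant × product
  combinations, with ties broken lexicographically on canonical SMILES
  (reactant, then product) — deterministic and order-independent. The
  pairing fingerprint deliberately matches the diversity metric's.
* Identical (reactant, product, template) triples are deduplicated before
  training.
* **Internal diversity** implements the exponent-p form
  `1 - (|G|^-2 Σ T(m1,m2)^p)^(1/p)` with self-pairs included; for `p = 1`
  (used throughout) it coincides with the printed form of the equation,
  whose radical omits the power inside the sum.
* **Starting-material filters**: rings larger than 8 atoms; molecular
  weight ≥ 300 removed (the boundary itself is removed); required groups =
  halogen, carbonyl, non-aromatic unsaturated bond, or nucleophilic
  substituent (hydroxy, primary/secondary amine, thiol) — aromatic rings do
  not count as unsaturation. The SMARTS live in `filter_spec()` and are
  user-editable, since the categories are named but their patterns are a
  convention.
* **Percentages** in search summaries use the total generated count as
  denominator; ligand efficiency divides the absolute docking score by the
  hydrogen-free heavy-atom count.
* **Route replay.** A route step is a virtual reaction, i.e. a decoder
  output under a stored template. Routes therefore replay through the
  (deterministic) decoder; steps carrying rank-1 provenance additionally
  coincide with the grammar oracle's unique product, and the tests assert
  both. Beam candidates at rank ≥ 2 are legitimate search moves that the
  one-product-per-template toy grammar simply cannot reproduce — on real
  reaction corpora they correspond to genuinely alternative outcomes.

## Problem sizes

The test suite and the acceptance script run the whole pipeline at desk
scale: a ~490-record grammar dataset (the full enumeration of the default
grammar to two reaction levels), toy-preset sequence models trained for up
to 250 epochs (six to seven minutes each on one core, with early stopping
at 0.95 validation perfect accuracy), a 30-epoch classifier, a 100-tree
forest, and searches of 25–50 iterations at beam widths 2–10 over ten
seeds. These sizes were chosen as the smallest at which the conditioning
gap, the search behaviour and the beam-width/depth trade-off are stable.

## Known limitations

* The sequence models are CPU-trained at toy scale; the full-scale presets
  are shipped but have never been trained here.
* OpenBabel's canonical order is the hardest part of the toy task: the
  model must reproduce global string reorderings caused by local edits.
  Residual validation errors are near-miss frames (e.g. ring-position
  spellings), not chemical nonsense.
* The unconditional twin is trained to its plateau, which by construction
  sits at the dataset's ambiguity bound, not at zero — a model below the
  bound is undertrained, not evidence of conditioning value. Its perfect
  accuracy is accordingly measured on records drawn from the enumerated
  dataset (the distribution the Bayes bound is computed on): with exactly
  one record per (reactant, template), a record-level holdout would be
  adversarial by construction, because the held-out product is precisely
  the one a reactant-only predictor has never seen for that reactant. The
  conditional model is held to the stricter standard — unseen records.
  At convergence every unconditional greedy decode is a genuine product of
  its reactant (no mode-mixing chimeras), and the measured accuracy matches
  the bound to within a few points.
* `randomForest` cannot express two of the four full-scale preset fields
  exactly (see above).
* The tree search is serial; no transposition tables or value networks.
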