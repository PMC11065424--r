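---
title: "Methods: reconstructing and predicting KEGG metabolic modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and predicting KEGG metabolic modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kopredict)
```

## The problem

Metagenome-assembled and single-amplified genomes are routinely incomplete:
assembly and binning lose genes, so a metabolic pathway that the organism
actually encodes may appear broken when the genome is annotated. kopredict
addresses this in three stages, mirroring how practitioners reason about
metabolic potential:

1. **Reconstruct.** KEGG modules are boolean expressions over KEGG Ortholog
   (KO) gene families, organised as ordered reaction steps. Given a
   genome's KO annotations, each module is evaluated as *complete* or
   *incomplete* against its definition.
2. **Predict.** For incomplete modules, a pair of multi-label feed-forward
   networks estimates the probability that the module is nevertheless
   present — that the gaps are artifacts of genome incompleteness rather
   than true absence. The networks take the genome's full KO
   presence/absence vector as input, so evidence from genes *outside* the
   module (overall gene content, co-occurring pathways) informs the call.
3. **Gap-fill.** Modules predicted present are annotated with the minimal
   set of missing KOs that would complete them, as concrete curation
   candidates.

## Module grammar and completeness

A module definition is parsed with the following precedence, from loosest
to tightest binding: whitespace separates ordered steps (conjunction);
`,` separates alternatives (disjunction) and binds tighter than whitespace
inside parentheses; `+` joins protein-complex subunits and `-` prefixes an
optional (non-essential) component, both binding tighter than `,`; a bare
`--` is a wildcard step, always counted as satisfied; parentheses group
arbitrarily. KEGG never publishes this grammar formally; these conventions
reproduce the published DEFINITION strings' observable structure, and the
treatment of `--` and `-` in presence labelling (both ignored for
completeness) is a convention we expose rather than hide — both are
configurable through the AST if a different reading is wanted.

A module is **complete** for a KO set when at least one combination of KOs
satisfying every step is contained in the set. Completeness is reported as
the fraction of *top-level* steps satisfied; nested sub-expressions do not
contribute fractionally, because presence is defined per reaction step.

Two evaluation routes exist and are cross-checked in the tests:

* **Enumeration** expands the definition into all distinct completion
  sets (deduplicated, ordered by size then lexicographically). The default
  ceiling is 10,000 sets; some real modules explode combinatorially.
* **Recursion** evaluates satisfiability directly on the AST and computes
  the missing-KO remainder by per-branch minimisation (within an
  alternative, the child with the smallest remainder wins; ties break on
  the lexicographically smallest sorted KO tuple). It is used automatically
  past the enumeration ceiling.

The gap-fill suggestion is the smallest-cardinality remainder over all
completion choices, with the same lexicographic tie-break, so results are
deterministic. Adding the suggested KOs always yields a complete module;
this soundness property is fuzz-tested over thousands of random ASTs.

## Feature and label matrices

Features are KO presence/absence bits over a universe fixed at training
time (the union of KOs seen in training annotations and catalog atoms,
sorted). At prediction time, KOs outside the universe are dropped with a
reported count, never appended — the network input width is part of the
model. Presence is binary: multi-copy genes collapse to one bit, matching
the presence/absence feature design. Labels are computed from the module
grammar, one bit per (genome, module).

## The classifier pair

Module prevalence (the fraction of complete training genomes containing
the module) spans several orders of magnitude, and a single multi-label
network trained across that range lets the abundant labels dominate. The
package therefore trains **two** networks on identical features: one for
modules with prevalence in [0.10, 0.90] (inclusive at both ends), one for
the rest. Modules with fewer than `min_positive_count` positive genomes
are excluded entirely; the floor is a count parameter with no hidden
default magic.

The reference architecture — `classifier_config()` defaults — is five
fully connected hidden layers of 2048 ReLU units, sigmoid outputs, binary
cross-entropy loss, Adam at learning rate 0.001, he_uniform
initialisation, dropout of 10% at every layer except the output, and L2
regularisation on hidden-layer weights. The implementation is plain R
matrix code; its gradients are verified against numerical differentiation
in the test suite. Unstated training-loop parameters are exposed with
defaults of 50 epochs, batch 256, early-stopping patience 5 on the
validation loss of an internal stratified 80/20 train/validation split,
and L2 strength 1e-4.

Decisions on the sigmoid output use an inclusive threshold of 0.5
(`probability >= threshold` means predicted present), the conventional
operating point for BCE-trained sigmoid outputs; it is a config field, not
a constant.

Prediction semantics: modules the grammar already evaluates complete are
reported `complete` with probability 1.0 and never reach the network;
incomplete modules get their partition's sigmoid probability; gap-fill
KOs are attached only to predicted-present incomplete modules.

## Multi-label stratified splitting

Train/test splits use iterative stratification: labels are processed from
rarest to most common, and each example carrying the current label goes to
the subset with the greatest remaining demand for that label, ties broken
by remaining capacity and then at random (seeded). Rows with no positive
labels fall back to capacity-proportional random assignment. On the
synthetic worlds used in the tests this keeps every label's train/test
prevalence difference within 0.05 whenever the label has at least 20
positives.

## The synthetic world

Training the real tool requires tens of thousands of annotated genomes;
nothing at desk scale substitutes for that corpus, so the package ships a
generator whose worlds make the *pipeline* testable end to end:

* A catalog of 12 modules over a 120-KO universe. Each module opens with a
  private **signature KO** — a required single-atom step unique to that
  module — and draws its remaining atoms from a 20-KO shared pool reused
  across modules (any pool KO that ends up used by a single module is
  re-drawn onto a shared one). This mirrors real KEGG structure, where
  modules share enzyme subunits but typically retain pathway-specific
  marker genes, and it is what makes the unique-gene baseline behave as it
  does on real data: most of a module's atoms are *not* unique to it.
* Per-module prevalence targets default to (0.03, 0.05, 0.08, 0.10, 0.12,
  0.15, 0.20, 0.25, 0.30, 0.40, 0.55, 0.92): mean positive-class rate
  26.25%, with both the balanced and the imbalanced partition populated.
  Assignment is independent Bernoulli per genome with repair guaranteeing
  at least one positive and one negative per module.
* Positive genomes carry one randomly chosen full completion set; negative
  genomes carry a random partial subset of the module's atoms (each atom
  independently with probability 0.4), repaired — by removing the
  module's signature KO — whenever shared atoms would accidentally
  complete it. Because every completion set contains the signature KO, the
  repair is exact and local to one module.
* KOs used by no module are background, included per genome independently
  at rate 0.10.
* Labels are recomputed from the generated genomes through the module
  grammar and asserted identical to the intended assignment, so generator
  and evaluator can never drift apart silently.

Genome incompleteness is simulated by annotation downsampling: a retained
fraction r keeps round(r·|KOs|) KOs (round half up), sampled uniformly
without replacement, over the grid 10–90% in steps of 10%; the complete
genome's labels are inherited verbatim by every downsampled copy. Each
(genome, fraction) pair derives its own child seed by hashing, so results
do not depend on iteration order. Downsampling acts on distinct KOs, not
on genes with multiplicity — the feature design is presence/absence, so
per-copy sampling would be invisible anyway; the choice is noted as
configurable.

What the generator does **not** emulate: taxonomic correlation structure,
gene copy number, annotation error, shared completion logic between
modules beyond atom sharing, and the long-tailed module-size distribution
of the real catalog. Passing tests on these worlds demonstrate that the
pipeline's machinery — grammar, labelling, training, evaluation — is
correct and that learning signal is recoverable; they say nothing about
accuracy on real genomes.

## Desk-scale experiment design

Two experiment protocols are used by the test suite and the acceptance
script, with problem sizes chosen as the package's own balance between
statistical resolution and run time:

* **Recovery.** A world of 6,000 complete genomes (75/25 stratified
  split). Training on complete genomes only makes the label a noise-free
  deterministic boolean function of the features, so a competent
  implementation should recover it nearly perfectly; per-module F1 on the
  held-out complete genomes is the measure. The size is set by
  measurement resolution and by the rarest class: at 3% prevalence,
  6,000 genomes leave ~135 training positives to learn the module's
  boolean rule from and ~45 held-out positives to score it on, enough
  that a single genome does not dominate a per-module F1. Desk-scale
  training configuration: one hidden layer of 256 units, batch 32, up to
  400 epochs with patience 80 — a single wide ReLU layer is the natural
  representation for step-conjunction rules over 120 features, and the
  reference 5×2048 architecture (sized for an 8,853-KO universe) is gross
  overcapacity here.
* **Degradation and baselines.** A world of 1,000 complete genomes
  expanded with the nine downsampled variants (10,000 observations),
  75/25 stratified split, pair trained on the mixture — the protocol that
  matches how the real tool is trained. Mean per-module recall on
  held-out rows at retain 0.5 versus 0.1 checks the qualitative
  degradation pattern; the benchmark harness then compares the pair
  against the two naive rules at retention 30–70% by macro-F1 over
  modules on held-out complete genomes, and at 10% retention checks the
  proportional rule's degenerate permissiveness (its false-positive rate
  exceeds the pair's). Desk-scale configuration: 2×256
  units, batch 64, up to 200 epochs, patience 30, L2 3e-4 (the mixture's
  inherited labels act as label noise on heavily downsampled rows, and
  the stronger penalty stabilises what the validation loss selects).

## Numerical choices and degenerate inputs

* BCE probabilities are clamped to [1e-7, 1 - 1e-7] before the log.
* Non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* Metrics with zero denominators are `NA`, never 0, and macro-averages
  exclude them with a reported count; zero-filling would bias means
  toward pessimism exactly where classes are rare.
* The positive/negative predictive value formulas are implemented via the
  Bayes route (recall, specificity, prevalence) and fuzz-checked against
  the count route (`tp/(tp+fp)`, `tn/(tn+fn)`) to 1e-12 — an algebraic
  identity that guards both implementations at once.
* An empty genome is legal everywhere: evaluation reports zero steps
  satisfied, downsampling returns it unchanged.
* Ties in gap-filling and completion-set ordering always break
  lexicographically, so every reported set is reproducible.

## Known limitations

* The grammar covers KO-level definitions; reaction/compound-level module
  semantics and KEGG pathway-map topology are out of scope.
* Prevalence partitioning assumes the training label matrix is computed on
  complete genomes; feeding it mixture rows shifts prevalences toward the
  downsampling average.
* The networks are trained fresh per world; no pre-trained weights ship
  with the package.
* Competitor architectures (gradient boosting, stacked ensembles) are not
  implemented; the benchmark harness's classifier interface is the
  extension point.
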