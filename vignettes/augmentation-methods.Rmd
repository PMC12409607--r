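---
title: "SMILES augmentation strategies for chemical language models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SMILES augmentation strategies for chemical language models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Generative chemical language models (CLMs) learn a next-token distribution
over SMILES strings and are sampled to propose de novo molecules.  Their
appetite for data collides with the reality of drug-discovery projects,
where task-specific training sets often hold tens to a few thousand
molecules.  Data augmentation artificially inflates such sets.  The
classical tool is *SMILES enumeration*: the same molecule is rendered as
several different strings by starting the graph traversal from different
atoms.  This package implements enumeration together with four further
augmentation families that perturb the training strings rather than merely
re-rendering them, and the complete evaluation stack needed to compare
them.

## The five strategies

All strategies are driven by `augmentToFold()`, which attempts to attach
`fold - 1` augmented strings to each original training string, enforces
per-molecule textual uniqueness, excludes strings already present in the
training set, and flags molecules whose augmentation space is exhausted as
*saturated* ("augmented until their possible maximum").

* **Enumeration** (`strategy = "enumeration"`): randomized restarts of the
  graph traversal.  Identity-preserving; every variant canonicalizes back
  to its source.
* **Token deletion** (`"deletion"`): each token of the tokenized string is
  deleted independently with probability `p`.  Three variants: `random`
  (anything may go, outputs are usually not valid SMILES and enter
  training as-is), `validity` (draws are repeated up to `max_attempts`
  times until the survivor parses into a valid molecule, otherwise the
  draw is rejected), and `protected` (ring tokens `1`-`9` and `%NN` and
  branch tokens `(`/`)` are never deleted, since broken ring/branch syntax
  is a known CLM failure mode).
* **Atom masking** (`"masking"`): atoms of the molecular graph are
  replaced by the dummy atom `*`.  `random` masks each atom independently
  with probability `p`; `functional_group` masks, per SMARTS-library match,
  all matched atoms with probability `p` per match (overlapping matches
  are unioned).  Masking is performed on the graph and re-emitted in input
  atom order, never on the token text, so ring and branch syntax is always
  intact; the package verifies that the masked and unmasked renderings
  differ only in `*` tokens and retries the draw otherwise.  Both `*` and
  `[*]` surface forms map to the single vocabulary token `*`.
* **Bioisosteric substitution** (`"bioisostere"`): the molecule is cut at
  all BRICS bonds; each fragment found in a replacement table fires
  independently with probability `p` and is swapped for a candidate drawn
  uniformly from the key's top-`k` (default 5) most frequent replacements;
  the fragments are re-assembled over the recorded attachment points and
  sanitized.  Identity-altering but chemistry-preserving by construction.
* **Self-training** (`"self_training"`): a CLM is first trained on the
  original (non-augmented, non-canonical) strings, sampled at low
  temperature (T = 0.5), and the valid, unique and novel samples (by
  canonical form) are attached as synthetic training strings, distributed
  round-robin across the source molecules so fold accounting stays
  per-molecule.

The default perturbation probabilities are the per-strategy optima adopted
as defaults: `p = 0.05` for deletion and random masking, `p = 0.15` for
bioisosteric substitution, `p = 0.30` for functional-group masking.  `p`
is unitless (a per-token, per-atom, per-match or per-fragment Bernoulli
rate).  `fold` counts the original string plus `fold - 1` augmented ones.

Two open points were resolved as package decisions: bioisosteric
substitution fires per-fragment Bernoulli draws (several fragments of one
molecule may be replaced in one augmented copy), and augmented strings
that collide textually across *different* molecules are logged but kept,
since uniqueness is specified per dataset entry, not globally.

## The language model

`trainCLM()` fits a unidirectional stacked LSTM with a softmax output
layer by teacher forcing: at each position the model receives the *input*
tokens up to `t` and is scored against the *target* token at `t + 1`.
For every strategy except masking, input and target sequences are
identical; masking pairs a masked input with the original unmasked target,
so the model learns to restore the hidden atoms.  The cross-entropy
ignores padding exactly (a padding-extension of any batch leaves the loss
bit-identical), gradients are backpropagated through time, and
optimization uses Adam with optional global-norm clipping.  Early stopping
watches the validation loss with patience 10 and minimum improvement
1e-4, and the weights of the best validation epoch are kept.  The full-scale hyperparameter grid (2-3 layers, 256-512 units,
learning rates 1e-3/5e-3/1e-4, batch 32-128) and the pre-training setting
(3 x 512, learning rate 5e-4, batch 512) are all expressible through
`clmConfig()`; fine-tuning defaults to learning rate 5e-7 with clipping
norm 1.  The pre-training learning rate sits outside the grid; both values
are honored as published.

Sampling (`sampleCLM()`) draws each next token from the temperature-scaled
softmax `p_i = exp(z_i/T) / sum_j exp(z_j/T)`, computed with a max-shift.
`T = 1` is plain multinomial sampling, `T < 1` sharpens towards the
arg-max, `T > 1` flattens towards uniform.  Two numerical guards: the
padding and begin tokens are removed from the sampling support (they are
never legitimate emissions and their logits are untrained), and sequences
are cut at `max_len` tokens including both markers.  Repeats use
independently derived seeds; three repeats of 1000 samples is the default
reference protocol.

## Data handling

`curateSmiles()` applies the standard preprocessing chain: keep the
largest covalent fragment, neutralize charges, strip stereochemistry,
sanitize, reject molecules with atoms outside
{C, O, N, S, P, F, Cl, Br, I}, reject canonical SMILES shorter than 6 or
longer than 150 tokens, deduplicate by canonical form, and attach one
randomized SMILES per survivor as the training representation.  Rejections
carry machine-readable codes (`PARSE`, `ATOM`, `LENGTH`, `DUP`).

`scaffoldClusterSplit()` builds size-nested training subsets by spectral
clustering over generic Bemis-Murcko scaffolds followed by stratified
sampling per cluster, so that each smaller subset is contained in every
larger one and cluster proportions are preserved within rounding; each
subset splits 90/10 into train/validation, and a disjoint
cluster-stratified test set is drawn from the remaining pool.  One design
point deserves a note: with scaffold-identity one-hot features the
affinity between any two distinct scaffold classes is zero, which makes
spectral clustering with fewer clusters than classes ill-defined.  The
package therefore uses the Tanimoto similarity of Morgan fingerprints
computed *on the generic scaffolds* as the affinity; identical scaffolds
still coincide exactly, so the identity-based grouping is preserved while
the Laplacian becomes connected.  The cluster count defaults to 10 at
fixture scale.

`similaritySets()` reproduces the two fine-tuning regimes:
agglomerative (complete-linkage) clustering into 20 parent and 40
subclusters followed by a greedy search for a subset with pairwise ECFP
(radius 2, 1024 bits) Tanimoto at least 0.8, and greedy leader selection
for sets with pairwise similarity at most 0.4.  Both return exactly the
requested size or raise an error naming the achievable maximum; the
20/40 constants shrink proportionally below 200 molecules so that fixtures
remain feasible.

## The synthetic fixture generator

`generateFixtureLibrary()` replaces external compound collections in all
tests.  It decorates fifteen ring cores (aromatic and aliphatic, mono- and
bicyclic) with alkyl/ether linkers and a substituent panel covering every
functional group of the bundled SMARTS library, and adds two large analog
series with a single variable site whose members stay above 0.8 pairwise
Tanimoto, making high-similarity fine-tuning sets feasible.  Coverage and
analog entries precede a seed-shuffled sample of the remaining grid, so
any draw of at least 60 molecules covers all functional groups.  The
generator emulates the *formal* properties a curated drug-like corpus
needs (validity, curation survival, scaffold multiplicity, functional-group
coverage, BRICS-matchable fragments) but not the statistical texture of a
real screening library: its property distributions are grid-like, its
scaffold frequencies nearly uniform, and its chemistry small.  Passing
tests therefore demonstrate the correctness of the machinery, not
performance claims on real data.

The bundled bioisostere table is a curated demo of classic
medicinal-chemistry pairs with synthetic frequency ranks (the full
database it stands in for is consumed through the same three-column
schema), and the SMARTS library is an editable default list; both are
documented as replaceable resources.

## Numerical choices

* Descriptors are rounded to 8 decimals: the additive descriptors (MW,
  logP, TPSA) carry ~1e-13 float jitter from atom-ordering, which would
  otherwise break the invariance of KS distances to the SMILES form.
* The KS distance is the exact sup-difference of the two empirical CDFs
  evaluated at all sample points (not an asymptotic approximation).
* Softmax is always max-shifted; probability conservation is tested to
  1e-12.
* Training batches are length-bucketed (sequences grouped by length after
  shuffling, batch order re-shuffled) so each batch is truncated to its
  own maximum length; this changes batch composition, not the loss.
* Retry budgets: `max_attempts` (default 20) draws per requested augmented
  string; self-training samples at most 20x the requested number of
  synthetic strings before saturating.
* Attachment-point correspondence in fragment replacement follows
  ascending label order on both sides; replacements are only accepted at
  equal arity.
* All randomness flows from R seeds (the chemistry backend receives
  explicit integer seeds), so every augmentation, training and sampling
  run is reproducible from its configuration.

## Evaluation definitions

Uniqueness and novelty are molecule-level (canonical SMILES), never raw
text.  The novelty denominator is the unique set, so the chain
`n_raw >= n_valid >= n_unique >= n_novel` always holds; published
reports rarely print their denominator, so this choice is logged in the
report rather than presented as canonical.  Scaffold metrics use
non-generic Bemis-Murcko scaffolds of the valid designs; acyclic
molecules map to the empty scaffold, counted as one class, which keeps
diversity well-defined on acyclic designs.  Generic scaffolds are used
only for clustering.  KS values are reported both on the raw [0, 1] scale
and x100, the display scale used in the literature's tables.

## Problem sizes in the test suite

The packaged checks run the full pipeline at desk scale: fixture libraries
of 40-1000 molecules, toy corpora of 20 strings for memorization, compact
models (1-2 layers, 16-256 units, at most a few hundred epochs), 100-500
samples per evaluation, and three sampling repeats.  These sizes exercise
every contract of the machinery; published headline numbers for these
strategies arise from thousands of LSTMs trained on large curated database
subsets and are not reproducible at these scales, which is why the acceptance suite is
property-based rather than value-matching.

## Known limitations

* Stereochemistry is stripped during curation and the tokenizer does not
  cover stereo bonds inside ring-closure digits; stereo-aware modelling is
  out of scope.
* The chemistry backend is driven through a Python/RDKit helper process;
  an R session without a Python interpreter carrying rdkit on its PATH
  cannot run the chemistry-dependent half of the package
  (`options(smilesaugment.python = ...)` selects the interpreter).
* The LSTM is implemented in base R matrix algebra.  It is exact (the
  test suite checks analytic gradients against numerical differentiation)
  but not fast; database-scale pre-training on millions of strings is
  architecture-supported yet computationally out of reach of this
  implementation.
* `Leader`-style low-similarity selection and the greedy high-similarity
  subset search are heuristics; they guarantee their pairwise bounds but
  not maximal set size.
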