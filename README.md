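# smilesaugment

Data augmentation for generative chemical language models (CLMs) working
on SMILES strings.  CLMs sample de novo drug-like molecules from a learned
next-token distribution, but the task-specific training sets of real
projects are small.  This package implements five augmentation families
for such low-data regimes, the LSTM language model they feed, and the
evaluation suite used to compare them — for computational chemists and
machine-learning practitioners building de novo design pipelines in R.

## Methods at its core

Given a training set of SMILES strings, an *n*-fold augmentation keeps
each original string and adds up to *n − 1* augmented strings per
molecule:

* **SMILES enumeration** — re-render the molecule from random graph
  traversals (the identity-preserving baseline);
* **token deletion** — delete each token with probability *p*
  (variants: `random`, validity-enforced, and `protected`, which never
  touches ring digits `1`–`9`, `%NN` closures, or branch parentheses);
* **atom masking** — replace atoms of the molecular graph by the dummy
  atom `*` with probability *p* (`random` per atom, or `functional_group`
  per SMARTS-library match); the model input is masked but the training
  target remains the unmasked string;
* **bioisosteric substitution** — cut the molecule at BRICS bonds, swap
  fragments found in a replacement table (probability *p*, uniform over
  the top-5 most frequent bioisosteres per fragment) and re-assemble;
* **self-training** — train a CLM on the original strings, sample at
  temperature *T* = 0.5, and keep the valid, unique, novel outputs as
  synthetic training strings.

The CLM is a stacked unidirectional LSTM trained by next-token prediction
(teacher forcing, Adam, early stopping on validation cross-entropy with
patience 10 and minimum improvement 10⁻⁴).  Generation uses temperature
sampling,

$$p_i = \frac{\exp(z_i/T)}{\sum_j \exp(z_j/T)},$$

where $z_i$ is the model's logit for token *i*; *T* = 1 is plain
multinomial sampling, *T* < 1 sharpens, *T* > 1 flattens.  Generated sets
are scored by validity / uniqueness / novelty, by Kolmogorov–Smirnov
distances on eight physico-chemical descriptors (aliphatic and aromatic
ring counts, MW, log P, HBD, HBA, TPSA, rotatable bonds) against the
training molecules, and by Bemis–Murcko scaffold diversity and novelty.

Molecular-graph work (canonicalization, descriptors, scaffolds, BRICS,
fingerprints) is delegated to RDKit through a bundled Python helper; the
R side owns every random decision, so all results are reproducible from R
seeds.

## Worked example

```r
library(smilesaugment)

## a synthetic drug-like corpus (stands in for a curated database export)
lib <- generateFixtureLibrary(40, seed = 1)

## protected token deletion, 3-fold augmentation
cfg <- augmentationConfig("deletion", variant = "protected",
                          fold = 3, seed = 7)
aug <- augmentToFold(lib, cfg)
aug
#> AugmentedSmiles: 40 molecules, 80 augmented strings
#>   strategy: deletion (protected)
#>   achieved mean fold: 3
#>   saturated molecules: 0

head(augmentedStrings(aug)[!augmentedStrings(aug)$is_original,
                           c("source_id", "augmented", "is_valid")], 2)
#>   source_id           augmented is_valid
#> 2         1     1ccc(C(=O)N)cc1    FALSE
#> 3         1      c1ccc((=)N)cc1    FALSE
```

Every molecule received its two augmented strings (mean fold 3, no
saturation).  Deletion outputs keep ring/branch tokens but are usually
not valid molecules — by design, they enter CLM training as noisy copies.
Evaluating a generated set:

```r
m <- generationMetrics(c("CCO", "OCC", "CCN", "C(C"),
                       training_refs = "CCO")
m
#> GenerationMetrics (n_raw = 4 )
#>   validity:    75.0%  (3 valid)
#>   uniqueness:  66.7%  (2 unique)
#>   novelty:     50.0%  (1 novel)

ksDistance(c(1, 2), c(1, 2, 3))
#> [1] 0.3333333
```

`"C(C"` does not parse (validity 3/4), `"CCO"` and `"OCC"` are the same
molecule (uniqueness 2/3), and one of the two unique molecules is already
in the training references (novelty 1/2).

The full pipeline — curation, augmentation, training, sampling,
evaluation — runs through one call:

```r
cfg <- runConfig(input = generateFixtureLibrary(500, seed = 1),
                 strategy = "masking", variant = "random", fold = 3,
                 clm = clmConfig(n_layers = 1, hidden_units = 96,
                                 max_epochs = 40),
                 n_samples = 100, repeats = 3, seed = 1)
res <- runExperiment(cfg)
```

A thin command-line front end over the same functions ships in
`inst/cli/smilesaugment` (subcommands `make-fixtures`, `curate`,
`augment`, `run-experiment`).

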