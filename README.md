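# hierdti

Hierarchical heterogeneous graph neural networks for drug–target
interaction (DTI) prediction, implemented end to end in base R matrix
algebra.

## The problem

Identifying which small molecules bind which proteins is a central step
in drug discovery and repurposing; assaying every pair experimentally is
infeasible, so computational link prediction on the drug–protein
interaction network fills the gap. The hard cases are *cold starts*:
scoring pairs that involve a drug or a target never seen with any
interaction during training, where the model must generalize from
molecular and residue-level structure alone.

`hierdti` is for computational biologists and method developers who want
a self-contained, inspectable R implementation of a two-level graph
neural network for this task — every layer, gradient and training step is
plain R, so the whole method can be read, tested and modified without a
deep-learning framework.

## The model

The data form a hierarchical heterogeneous graph. At the **low level**,
each drug is a molecular graph (atoms, bonds, 28 atom descriptors) parsed
from SMILES, and each protein is a residue graph whose edges come from a
contact-probability map thresholded at 0.5 (backbone always included)
with per-residue descriptors (a PSSM, or a built-in one-hot +
physicochemical stand-in). Three graph-convolution layers

    H^(k) = ReLU( D^{-1/2} (A + I) D^{-1/2} H^(k-1) W^(k) )

followed by global mean pooling turn every entity into an 80-dimensional
vector. At the **high level**, drugs and proteins are nodes of a
bipartite interaction graph (optionally augmented with common-neighbor
similarity edges above a threshold θ). A feature encoder (LeakyReLU dense
layers) and a graph encoder (tanh graph convolutions) each embed the
entity vectors to 20 dimensions, and a structure-and-attribute
information fusion (SAIF) module combines them:

    Z_I = α Z_FE + (1 − α) Z_GE          (α learned, init 0.5)
    Z_L = Â_h Z_I
    S   = row-softmax(Z_L Z_Lᵀ)
    Z̃   = β S Z_L + Z_L                  (β = 0.7)

A decoder symmetric to the graph encoder maps back to 80 dimensions and
every pair is scored as `ŷ = sigmoid(Z Zᵀ)`. Training minimizes the
masked binary cross-entropy over labeled training pairs with Adam
(lr 1e-4, 200 full-batch epochs); held-out interactions are zeroed in the
propagation adjacency and read out at their masked positions
(transductive inference). Cold-start splits S1 (new drug), S2 (new
target) and S3 (both) hold out entities 4:1, with 1:1 negative sampling.

A synthetic-corpus generator (`synth_corpus()`) produces
valence-plausible molecules, sequences with banded contact maps, and
interaction labels from a planted low-rank logistic model whose latent
factors are also injected into the node features — so the entire pipeline
is exercisable and testable with no external data.

## Worked example

```r
library(hierdti)
corpus <- synth_corpus(synth_config())   # 60 drugs x 40 proteins, planted rank-4 signal
corpus
#> DTI corpus: 60 drugs, 40 proteins, 1197 labeled pairs
fit <- hierdti(corpus, control = hierdti_control(seed = 1))
summary(fit)
#> Hierarchical heterogeneous DTI model
#>
#> Cold-start split S1 (seed 1)
#>   drugs: 48 train / 12 test | proteins: 40 train / 0 test
#>   pairs: 1914 train / 480 test
#>
#> Training: 200 epochs, Adam lr 0.0001, d1 = 80, d2 = 20, beta = 0.7
#> Loss: 0.69325 (epoch 1) -> 0.56458 (final)
#> Fusion alpha: 0.4999 -> 0.5130
#>
#> Training pairs:  AUC 0.7717 | AUPR 0.7724 | F1 0.6852 | ACC 0.6860 | PRECISION 0.6784 | RECALL 0.6921
#> Held-out pairs:  AUC 0.7133 | AUPR 0.7193 | F1 0.6707 | ACC 0.6625 | PRECISION 0.6875 | RECALL 0.6548
predict(fit, data.frame(drug = c("D004", "D010"), protein = c("P002", "P017")))
#> [1] 0.2686318 0.7793473
```

The held-out block reports ranking (AUC, AUPR) and thresholded (F1, ACC,
precision, recall) metrics over the 480 pairs touching the 12 held-out
drugs — entities the model never saw interact during training. The two
predicted scores are interaction probabilities for individual
drug–protein queries. `plot(fit)` shows the loss and the fusion
coefficient per epoch; `coef(fit)` returns the learned weights.

Ablation variants (`run_ablation()`): `-L` replaces the low-level GCNs by
sequence label-encoding, `-F` drops the feature encoder and SAIF fusion,
`-W` freezes α at 0.5. `theta_sweep()` tabulates metrics across
similarity thresholds. File-based corpora (drugs.tsv, proteins.fasta,
per-protein `.cmap`/`.feat`, interactions.tsv) go through
`read_corpus()` / `write_fixture()` / `run_pipeline()`, and a thin CLI
lives at `inst/cli/hierdti.R` with subcommands
`simulate | split | train | evaluate | predict | ablate | sweep`.

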