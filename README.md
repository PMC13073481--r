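# GeneEBM

Energy-based generative classification of two-class gene-expression
cohorts, with the full evaluation scaffolding that cross-cohort claims
need: fold-wise differential expression analysis, leakage-safe
preprocessing, gated-recurrent baselines, and a four-protocol validation
harness (seen k-fold, cross-cohort unseen, k-effect, training-fraction
sweep) with reliability statistics and report aggregation.

## Who it is for

Researchers classifying diseased vs. control samples from bulk
transcriptomics (microarray-style log2 expression matrices) who need
more than a within-cohort accuracy number — in particular, evidence that
a model trained on one cohort transfers to an independently collected
one with a bounded performance drop.

## The model

A class-conditioned energy network learns a scalar energy `E(X, Y)`
(ELU MLP over gated features ⊕ class embedding; lower energy = better
class fit), with learnable per-class prototypes, per-gene gates
`g = sigmoid(γ)`, and a normalized gene–gene interaction matrix `Â`.
Samples evolve along the composite field

    F(X, Y) = −∇X E(X, Y) + Â X

integrated by fourth-order Runge–Kutta from the class prototype.
Training minimizes denoising score matching — the batch mean of
`‖ −∇x̃ E(x̃, y) − (x − x̃)/σ² ‖²` on noise-corrupted inputs — plus a
trajectory reconstruction MSE between the generated endpoint and the
real sample, with Adam. Classification scores an input by the energy
difference `E(X, 0) − E(X, 1)` against a Youden-optimal ROC threshold.
All gradients (including the second-order terms DSM needs, and the
discrete adjoint through the RK4 solver) are exact and hand-verified
against finite differences.

## Worked example

```r
library(GeneEBM)

# a synthetic pair of cohorts: 100 control + 100 diseased samples,
# 100 genes, 10 planted DEGs at |log2FC| = 3, noise SD 0.5, and a
# per-gene baseline shift (SD 0.3) in the twin cohort
spec <- cohortSpec(nControl = 100, nDiseased = 100, nGenes = 100,
                   nDeg = 10, effectLog2fc = 3, noiseSd = 0.5,
                   shiftSd = 0.3, seed = 1)
pair <- generateCohortPair(spec)

deg <- runDEA(pair$seen)            # per-gene log2FC, t, BH-adjusted p
sum(deg$selected)
#> [1] 10                            # exactly the planted genes

seen <- runSeenKfold("biogen", pair$seen, k = 5, seed = 1)
unseen <- runUnseen("biogen", pair$seen, pair$unseen, seed = 1,
                    seenResult = seen)
protocolMean(seen); protocolMean(unseen); unseen@pd
#> [1] 100
#> [1] 100
#> [1] 0                             # seen-minus-unseen drop, pp
auditLeakage(seen)
#> [1] TRUE                          # no test id touched a fitted object
```

`protocolMean()` is the across-fold mean accuracy in percent; `@pd` is
the seen-minus-unseen accuracy difference in percentage points (the
generalization headline: below 10 points counts as transferring). On
this strongly separable synthetic signature the classifier is at
ceiling in both paradigms.

A thin command-line wrapper ships in `inst/scripts/geneebm`
(`simulate`, `dea`, `train`, `evaluate`, `benchmark` subcommands over
the same functions).

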