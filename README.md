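# BiotypeGraph

Discovering disorder *biotypes* — data-driven patient subgroups defined by
brain connectivity rather than symptom checklists — from resting-state
functional network connectivity (FNC) and phenotypes. The package is aimed
at neuroimaging researchers who have per-subject component time courses
(or precomputed FNC vectors) plus a phenotype table, and who want subtype
assignments together with the validation evidence that such a claim
requires.

## The model

Each subject contributes the upper triangle of a C × C Pearson correlation
matrix between independent-component time courses (d = C(C−1)/2 features;
1378 in the canonical 53-component, 7-network layout). Subjects form the
nodes of a *population graph* whose edges score phenotypic similarity

    s(u,v) = 1[gender_u = gender_v] + 1[|age_u − age_v| ≤ w],

optionally gated by an FNC-similarity kernel and sparsified to each node's
top-k neighbours. A graph-convolutional autoencoder (encoder
d → 256 → 64, mirrored decoder, propagation Â = D^(−1/2)(A+I)D^(−1/2))
is trained with three coupled losses,

    L = γ1·L_rec + γ2·L_CE + γ3·L_cluster,
    γ1 = 0.01, γ2 = 0.01, γ3 = 0.1, Adam, lr = 0.001,

where `L_rec` is the reconstruction error, `L_CE` is a binary
cross-entropy diagnostic head (patients vs controls), and `L_cluster` is a
deep K-means soft-min on the patient subgraph's embeddings,
annealed to the hard K-means objective. K is chosen by the elbow of the
within-cluster sum-of-squares (CSS) curve on pretrained embeddings;
patients are assigned to their nearest learned centroid, and per-biotype
mean-FNC *templates* (computed from raw FNC) transfer the division to new
cohorts by nearest-template projection.

Validation tooling: Davies–Bouldin and Calinski–Harabasz indices, four
baseline clusterers, 10-fold template-stability analysis,
random-feature ablation, top-k discriminative edges by covariate-adjusted
t-tests grouped into 7×7 network contributions, cross-cohort consistency
correlations, BH-FDR and Cohen's d, and longitudinal mixed-effects
models (`lme4`/`lmerTest`) for biotype-specific medication response —
plus a synthetic-cohort generator with planted biotype structure that
makes the whole pipeline testable without restricted data.

## Worked example

Twenty components allocated proportionally to the 7 canonical networks,
600 subjects, two planted patient subtypes (per-edge standardized effect
0.8, edge noise SD 0.1):

```r
library(BiotypeGraph)
co  <- generateCohort(cohortSpec(nHC = 200, nPatients = 400,
                                 partition = scaledPartition(20), seed = 101))
g   <- cohortGraph(co)
#> PopulationGraph: 600 subjects ( 400 patients ), 190 FNC features, 4790 weighted edges

cfg <- trainingConfig(hiddenDim = 64, embeddingDim = 16,
                      pretrainEpochs = 100, jointEpochs = 100, seed = 1)
selectBiotypeK(g, cfg)$k        # CSS elbow over K = 1..8
#> [1] 2

fit <- trainBiotypeModel(g, cfg)
fit
#> BiotypeModel: K = 2 | embedding dim 16 | biotype sizes: 213/187
#> final losses: rec 0.96518 ce 0.61975 cluster 0.46759 total 0.062608

truth <- subjectTable(co)$trueSubtype[patientMask(g)]
adjustedRand(unname(biotypes(fit)), truth)
#> [1] 0.837
```

The CSS curve drops from 2688.5 (K = 1) to 1145.3 (K = 2) and then
flattens — the elbow rule picks K = 2, the number of planted subtypes —
and the adjusted Rand index of 0.837 says assignments agree strongly with
the hidden ground truth. The discriminative-edge analysis then lands on
the planted network blocks:

```r
top <- topDiscriminativeFNC(nodeFeatures(g)[patientMask(g), ],
         factor(ifelse(unname(biotypes(fit)) == 1, "b1", "b2")), k = 20)
networkContribution(top, scaledPartition(20))
#>    SC AU SM VI CC DM CB
#> SC  0  0  0  0  0  0  0
#> AU  0  0  0  0  0  0  0
#> SM  0  0  0  3  0  0  0
#> VI  0  0  3  0  0  0  5
#> CC  0  0  0  0  0 12  0
#> DM  0  0  0  0 12  0  0
#> CB  0  0  0  5  0  0  0
```

All 20 top edges fall in the CC–DM, SM–VI and VI–CB blocks where the two
subtypes were planted. `runPipeline()` (or the thin CLI in
`inst/scripts/biotype-graph.R`) chains simulate → graph → fit → evaluate →
project with every stage's outputs, resolved configuration and seed
written as delimited text with checksums.

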