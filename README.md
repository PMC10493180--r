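# ddifusion

Multiclass prediction of drug–drug interaction (DDI) *events* — which typed
consequence (a change in metabolism, serum concentration, therapeutic
efficacy, …) follows from co-administering two drugs — from multiple kinds
of binary drug annotations: mono side effects, protein targets, enzymes,
chemical substructures, and pathways. It is aimed at computational
pharmacology work where pairwise screening is infeasible and a ranked list
of high-confidence candidate interactions is the deliverable.

## Method

For each feature modality \(f_k\), a drug \(d_i\) is a binary vector whose
support \(X_{d_i}\) is the set of features it carries. The per-modality
drug–drug similarity is the Jaccard index

```
J(X_di, X_dj) = |X_di ∩ X_dj| / (|X_di| + |X_dj| − |X_di ∩ X_dj|)
```

(with J := 0 when both sets are empty). The p similarity matrices
(each m × m) are concatenated column-wise into a drug feature table of
dimension m × p·m — one fused similarity profile per drug. A drug pair
(i, j) is encoded as the **elementwise sum** of rows i and j (order-invariant
by construction; concatenation and elementwise product are available for
comparison), and a small fully connected network maps the encoding to a
probability distribution over the n event types:

```
input → 512 (ReLU) → dropout 0.3 → 256 (sigmoid) → dropout → 128 (sigmoid)
      → dropout → softmax(n)
```

trained with Adam on cross-entropy for 100 epochs at batch size 128. The
predicted event is the argmax. Evaluation uses stratified 5-fold
cross-validation (nested CV for hyperparameter selection), six metrics
(ACC, AUPR, AUROC, F, precision, recall — the last three micro-averaged,
hence identical in single-label multiclass) plus whole-dataset FP/FN counts,
leave-one-feature-out ablation, feature-subset sweeps, PCA reduction
scenarios, and per-modality model fusion. A synthetic-benchmark generator
with planted latent-group structure makes the whole pipeline testable
without any external downloads.

## Worked example

```r
library(ddifusion)

# benchmark-shaped synthetic data: DS3 layout at 10% scale, 10% label noise
cfg <- make_ds_shaped("DS3", scale = 0.1, seed = 42, label_noise = 0.1)
gen <- generate_bundle(cfg)
gen$bundle
#> <dataset_bundle: 64 drugs, 2 modalities (mono_side_effect, target), 508 pairs, 18 events>

res <- cross_validate(gen$bundle,
                      model_config(hidden_sizes = c(128L, 64L), seed = 42),
                      k = 5, seed = 42)
res$pooled
#> <eval_report: ACC 0.8569  AUPR 0.7835  AUROC 0.9191  F 0.8569  P 0.8569  R 0.8569  FP 73  FN 73>

top_false_positives(gen$bundle$pairs, res$probas, 3)
#>     drug_a   drug_b true_event predicted_event probability
#> 1 drug_028 drug_063  event_017       event_002   0.9158589
#> 2 drug_036 drug_064  event_003       event_002   0.9158302
#> 3 drug_015 drug_030  event_012       event_002   0.9148767
```

Reading: with 10% of labels flipped, held-out accuracy sits near the 90%
noise ceiling; FP == FN because each misclassification is one false positive
for the predicted event and one false negative for the true event; the
ranked table lists the pairs the model contradicts most confidently — on
real data these are the candidate novel interactions worth a second look.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ddifusion.R", package = "ddifusion"))')
Rscript "$CLI" simulate   --out bundle/ --ds-shape DS1 --scale 0.2 --seed 7
Rscript "$CLI" train-eval --bundle bundle/ --out eval/ --k 5 --seed 7
Rscript "$CLI" experiment --bundle bundle/ --out abl/ --variant ablation --seed 7
```

Exit codes: 0 success, 2 validation failure, 1 internal error. Outputs are
TSVs plus a `run_info.txt` with argument and input-hash provenance.

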