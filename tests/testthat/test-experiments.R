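# Experiment tests share one deliberately sparse-pair planted-signal world:
# with few labeled pairs per drug, the network cannot substitute drug-identity
# memorisation (via the fixed fingerprints every similarity block carries,
# diagonal included) for genuine group-profile signal, so excluding the
# signal modality must hurt. See the methods vignette for the analysis.
planted_world <- function(seed = 3L)
  generate_bundle(synth_config(m = 120, p = 3, feature_counts = c(200, 150, 180),
                               n_events = 6, n_pairs = 240, n_groups = 3,
                               signal_modalities = 2L, seed = seed))

test_that("leave-one-feature-out produces one paired result per modality", {
  gen <- small_world()
  res <- suppressWarnings(leave_one_feature_out(gen$bundle, desk_config(epochs = 10L),
                                                k = 3, seed = 2))
  expect_length(res$excluded, 2L)
  expect_equal(res$summary$excluded, names(gen$bundle$features))
  # identical folds across variants: paired deltas
  expect_identical(res$full$fold_split$assignments,
                   res$excluded[[1L]]$fold_split$assignments)
  # re-running the full set reproduces the full-model report exactly
  again <- suppressWarnings(cross_validate(gen$bundle, desk_config(epochs = 10L),
                                           k = 3, seed = 2))
  expect_identical(again$probas, res$full$probas)
  expect_error(leave_one_feature_out(
    dataset_bundle(gen$bundle$features[1], gen$bundle$pairs), desk_config()),
    "at least two")
})

test_that("ablation flags the planted signal modality", {
  gen <- planted_world()
  res <- suppressWarnings(leave_one_feature_out(gen$bundle, desk_config(), k = 5, seed = 3))
  drop_signal <- res$full$pooled$acc - res$excluded[["mod2"]]$pooled$acc
  drop_noise <- res$full$pooled$acc -
    min(res$excluded[["mod1"]]$pooled$acc, res$excluded[["mod3"]]$pooled$acc)
  expect_gte(drop_signal, 0.25)
  expect_lte(drop_noise, 0.05)
})

test_that("feature_combinations sweeps all nonempty subsets on shared folds", {
  gen <- small_world()
  res <- suppressWarnings(feature_combinations(gen$bundle, desk_config(epochs = 10L),
                                               k = 3, seed = 2))
  expect_equal(nrow(res$table), 3L)            # 2^2 - 1
  expect_true(all(diff(res$table$acc) <= 0))   # sorted by accuracy
  full_row <- res$table[res$table$id == "mod1+mod2", ]
  again <- suppressWarnings(cross_validate(gen$bundle, desk_config(epochs = 10L),
                                           k = 3, seed = 2))
  expect_equal(full_row$acc, again$pooled$acc)
})

test_that("best subset contains the planted signal modality", {
  gen <- planted_world(seed = 8L)
  res <- suppressWarnings(feature_combinations(gen$bundle, desk_config(), k = 5, seed = 8))
  expect_equal(nrow(res$table), 7L)
  expect_match(res$table$id[1L], "mod2")
})

test_that("pca_reduce keeps the target variance and drops duplicate-column rank", {
  gen <- small_world()
  # variance_target = 1 on the concatenated table: full rank retained,
  # projection is an isometry of the centered table
  red <- pca_reduce(gen$bundle, scenario = 2L, variance_target = 1)
  full <- build_feature_table(gen$bundle)
  expect_equal(attr(red, "n_components"), qr(scale(full$values, scale = FALSE))$rank)
  # duplicated columns add no components
  b2 <- gen$bundle
  dup <- b2$features[[1L]]
  dup2 <- feature_matrix(cbind(dup$values, dup$values),
                         dup$drug_ids, c(dup$columns, paste0(dup$columns, "_copy")),
                         "mod1")
  b_dup <- dataset_bundle(list(dup2, b2$features[[2L]]), b2$pairs)
  r1 <- pca_reduce(gen$bundle, scenario = 1L, variance_target = 0.95)
  r2 <- pca_reduce(b_dup, scenario = 1L, variance_target = 0.95)
  # identical feature sets give identical similarity matrices, hence identical counts
  expect_equal(attr(r1, "n_components"), attr(r2, "n_components"))
  expect_error(pca_reduce(gen$bundle, scenario = 3L), "scenario")
})

test_that("reduced tables run end-to-end and scenario 2 at target 1 matches unreduced", {
  gen <- small_world(seed = 4L)
  folds <- stratified_kfold(gen$bundle$pairs, 5, 4)
  base <- suppressWarnings(cross_validate(gen$bundle, desk_config(), folds = folds,
                                          table = build_feature_table(gen$bundle)))
  for (scen in c(1L, 2L)) {
    red <- pca_reduce(gen$bundle, scenario = scen)
    r <- suppressWarnings(cross_validate(gen$bundle, desk_config(), folds = folds,
                                         table = red))
    expect_false(anyNA(r$probas))
  }
  red1 <- pca_reduce(gen$bundle, scenario = 2L, variance_target = 1)
  r1 <- suppressWarnings(cross_validate(gen$bundle, desk_config(), folds = folds,
                                        table = red1))
  expect_lt(abs(r1$pooled$acc - base$pooled$acc), 0.01 + 1e-9)
})

test_that("encoding comparison emits three paired runs; sum is order-invariant", {
  gen <- small_world()
  res <- suppressWarnings(compare_pair_encodings(gen$bundle, desk_config(epochs = 10L),
                                                 k = 3, seed = 5))
  expect_equal(res$table$id, c("sum", "concat", "dot"))
  expect_identical(res$runs$sum$fold_split$assignments,
                   res$runs$dot$fold_split$assignments)
})

test_that("fusion combines per-modality models per its rule", {
  gen <- small_world()
  fm <- suppressWarnings(fuse_per_feature_models(gen$bundle, desk_config(epochs = 20L),
                                                 "mean", k = 3, seed = 2))
  fv <- suppressWarnings(fuse_per_feature_models(gen$bundle, desk_config(epochs = 20L),
                                                 "vote", k = 3, seed = 2))
  expect_equal(rowSums(fm$probas), rep(1, nrow(fm$probas)), tolerance = 1e-6)
  # vote shares reproduce plurality with low-index ties by construction
  votes <- vapply(fv$per_modality, function(r) predict_event(r$probas),
                  integer(nrow(gen$bundle$pairs$records)))
  manual <- apply(votes, 1L, function(v) which.max(tabulate(v, 5)))
  expect_equal(predict_event(fv$probas), unname(manual))
  # fusing p copies of the same modality equals the single model
  b_same <- dataset_bundle(list(gen$bundle$features[[1L]],
                                feature_matrix(gen$bundle$features[[1L]]$values,
                                               gen$bundle$features[[1L]]$drug_ids,
                                               gen$bundle$features[[1L]]$columns,
                                               "copy")),
                           gen$bundle$pairs)
  fsame <- suppressWarnings(fuse_per_feature_models(b_same, desk_config(epochs = 20L),
                                                    "vote", k = 3, seed = 2))
  single <- suppressWarnings(cross_validate(b_same, desk_config(epochs = 20L),
                                            k = 3, seed = 2, modalities = "mod1"))
  expect_equal(predict_event(fsame$probas), predict_event(single$probas))
})
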