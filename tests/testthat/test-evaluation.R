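test_that("stratified folds partition records with per-event balance", {
  b <- small_world()$bundle
  fs <- stratified_kfold(b$pairs, k = 5, seed = 1)
  expect_length(fs$assignments, nrow(b$pairs$records))
  expect_true(all(fs$assignments %in% 1:5))
  tab <- table(b$pairs$records$event, fs$assignments)
  expect_true(all(apply(tab, 1, function(r) diff(range(r)) <= 1)))
  # determinism + remainder handling
  expect_identical(fs$assignments, stratified_kfold(b$pairs, 5, seed = 1)$assignments)
  pd <- pair_dataset(paste0("d", 1:10), c(1, 2, 3), c(4, 5, 6), c(1, 1, 1), "e")
  fs3 <- stratified_kfold(pd, k = 3, seed = 2)
  expect_setequal(fs3$assignments, 1:3)       # 3 records, one per fold
  expect_error(stratified_kfold(pd, k = 4, seed = 1), "exceeds record count")
})

test_that("perfect predictions yield all-one metrics and zero errors", {
  y <- c(1L, 2L, 3L, 2L)
  P <- diag(3)[y, ]
  r <- compute_metrics(y, P)
  for (f in c("acc", "aupr", "auroc", "f_score", "precision", "recall"))
    expect_equal(r[[f]], 1)
  expect_equal(r$fp_total, 0L)
  expect_equal(r$fn_total, 0L)
})

test_that("hand-counted confusion: all rows called event 1, truth uniform over 2", {
  N <- 20L
  y <- rep(1:2, each = N / 2)
  P <- matrix(rep(c(0.9, 0.1), each = N), N, 2)
  r <- suppressWarnings(compute_metrics(y, P))
  expect_equal(r$acc, 0.5)
  expect_equal(r$fp_total, N / 2)
  expect_equal(r$fn_total, N / 2)
  expect_equal(r$precision, 0.5)
})

test_that("curve metrics match the reference one-vs-rest values (frozen sklearn oracle)", {
  P <- rbind(c(0.60, 0.30, 0.10),
             c(0.20, 0.50, 0.30),
             c(0.10, 0.20, 0.70),
             c(0.40, 0.40, 0.20),
             c(0.55, 0.25, 0.20),
             c(0.30, 0.30, 0.40),
             c(0.25, 0.50, 0.25),
             c(0.05, 0.15, 0.80))
  y <- c(1L, 2L, 3L, 2L, 1L, 3L, 1L, 3L)
  r <- compute_metrics(y, P, average = "weighted")
  expect_equal(r$auroc, 0.918750000000, tolerance = 1e-10)
  expect_equal(r$aupr, 0.845833333333, tolerance = 1e-10)
  expect_equal(r$acc, 0.75)
  expect_equal(r$fp_total, 2L)
  rm_ <- compute_metrics(y, P, average = "macro")
  expect_equal(rm_$auroc, 0.913888888889, tolerance = 1e-10)
  expect_equal(rm_$aupr, 0.816666666667, tolerance = 1e-10)
})

test_that("accounting identities hold on random inputs (property)", {
  set.seed(77)
  for (rep in 1:40) {
    n_ev <- sample(2:5, 1); N <- sample(5:50, 1)
    y <- sample(seq_len(n_ev), N, replace = TRUE)
    P <- matrix(rexp(N * n_ev), N, n_ev); P <- P / rowSums(P)
    r <- suppressWarnings(compute_metrics(y, P))
    expect_identical(r$fp_total, r$fn_total)
    expect_equal(r$precision, r$recall)
    expect_equal(r$precision, r$f_score)
    expect_equal(r$precision, r$acc)          # micro identity, single run
    # brute-force confusion oracle
    pred <- apply(P, 1, which.max)
    expect_equal(r$fp_total, sum(pred != y))
  }
})

test_that("events absent from truth are excluded from curves with a warning", {
  y <- c(1L, 1L, 2L)
  P <- rbind(c(0.7, 0.2, 0.1), c(0.6, 0.3, 0.1), c(0.2, 0.7, 0.1))
  expect_warning(r <- compute_metrics(y, P), "absent")
  expect_false(is.na(r$auroc))
})

test_that("cross-validation recovers planted structure and is deterministic", {
  gen <- small_world()
  r1 <- suppressWarnings(cross_validate(gen$bundle, desk_config(), k = 5, seed = 2))
  expect_gte(r1$pooled$acc, 0.9)
  # every record scored exactly once
  expect_false(anyNA(r1$probas))
  expect_equal(rowSums(r1$probas), rep(1, nrow(r1$probas)), tolerance = 1e-6)
  r2 <- suppressWarnings(cross_validate(gen$bundle, desk_config(), k = 5, seed = 2))
  expect_identical(r1$probas, r2$probas)
  expect_equal(r1$pooled$fp_total, sum(vapply(r1$folds, `[[`, 0L, "fp_total")))
})

test_that("label shuffling collapses accuracy to the majority baseline", {
  gen <- small_world(n_pairs = 500L)
  p <- gen$bundle$pairs
  set.seed(123)
  ev <- sample(p$records$event)
  bs <- dataset_bundle(gen$bundle$features,
                       pair_dataset(p$drug_ids, p$records$i, p$records$j, ev,
                                    p$event_labels))
  r <- suppressWarnings(cross_validate(bs, desk_config(), k = 5, seed = 2))
  maj <- max(tabulate(ev)) / length(ev)
  expect_lt(abs(r$pooled$acc - maj), 0.07)
})

test_that("nested CV with a singleton grid matches plain CV folds and runs deterministically", {
  gen <- small_world()
  grid <- list(desk_config(epochs = 30L))
  r1 <- suppressWarnings(nested_cv(gen$bundle, grid, outer_k = 3, inner_k = 2, seed = 4))
  r2 <- suppressWarnings(nested_cv(gen$bundle, grid, outer_k = 3, inner_k = 2, seed = 4))
  expect_identical(r1$probas, r2$probas)
  expect_identical(r1$selections, rep(1L, 3))
  expect_gte(r1$pooled$acc, 0.85)
})

test_that("nested CV prefers a sane config over an absurd one", {
  gen <- small_world()
  grid <- list(model_config(hidden_sizes = 1L, epochs = 5L, seed = 1L),   # absurd
               desk_config(epochs = 30L))
  r <- suppressWarnings(nested_cv(gen$bundle, grid, outer_k = 3, inner_k = 2, seed = 6))
  expect_gte(sum(r$selections == 2L), 2L)     # sane config wins in most outer folds
})

test_that("top false positives are ranked by predicted-event probability", {
  pd <- pair_dataset(paste0("d", 1:6), c(1, 2, 3, 4), c(2, 3, 4, 5),
                     c(1L, 1L, 2L, 2L), c("e1", "e2"))
  P <- rbind(c(0.9, 0.1),    # correct
             c(0.2, 0.8),    # FP at 0.8
             c(0.99, 0.01),  # FP at 0.99
             c(0.1, 0.9))    # correct
  out <- top_false_positives(pd, P, k = 2)
  expect_equal(out$probability, c(0.99, 0.8))
  expect_equal(out$drug_a, c("d3", "d2"))
  # zero misclassifications -> empty; fewer than k -> all plus a note
  perfect <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(nrow(top_false_positives(pd, perfect, 5)), 0L)
  one_fp <- top_false_positives(pd, P, k = 5)
  expect_equal(nrow(one_fp), 2L)
  expect_match(attr(one_fp, "note"), "only 2")
})

test_that("report writer emits one row per report", {
  gen <- small_world()
  r <- suppressWarnings(cross_validate(gen$bundle, desk_config(epochs = 5L), k = 3, seed = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  pe <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(c(stats::setNames(r$folds, paste0("fold", 1:3)),
                      list(pooled = r$pooled)), f, pe)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("acc", "aupr", "auroc", "f_score", "precision", "recall",
                    "fp", "fn") %in% names(tab)))
})
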