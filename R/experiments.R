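# Feature-evaluation studies. Every variant of an experiment reuses one
# fold split per seed, so deltas between variants are paired — never
# confounded by resplitting.

#' Leave-one-feature-out ablation
#'
#' For each modality, rebuilds the drug feature table without that
#' modality's similarity block and reruns cross-validation on identical
#' folds. Reports paired accuracy deltas against the full model.
#'
#' @param bundle a [dataset_bundle] with p >= 2 modalities.
#' @param config a [model_config].
#' @param k folds; `seed` controls the (shared) fold split.
#' @param seed integer seed.
#' @param average curve-metric averaging.
#' @return Object of class `ablation_result`: `full` (cv_result),
#'   `excluded` (named list of cv_result, one per left-out modality), and
#'   `summary` data frame with accuracy deltas.
#' @export
leave_one_feature_out <- function(bundle, config = model_config(), k = 5L,
                                  seed = 1L, average = "weighted") {
  mods <- names(bundle$features)
  if (length(mods) < 2L) stop("leave_one_feature_out: need at least two modalities")
  folds <- stratified_kfold(bundle$pairs, k, seed)
  sims <- lapply(bundle$features, similarity_matrix)
  run_with <- function(keep)
    cross_validate(bundle, config, k, seed, folds = folds,
                   table = concat_similarities(sims[keep]), average = average)
  full <- run_with(mods)
  excluded <- lapply(mods, function(mo) run_with(setdiff(mods, mo)))
  names(excluded) <- mods
  summary <- data.frame(
    excluded = mods,
    acc = vapply(excluded, function(r) r$pooled$acc, 0),
    delta_acc = vapply(excluded, function(r) r$pooled$acc - full$pooled$acc, 0),
    delta_fp = vapply(excluded, function(r) r$pooled$fp_total - full$pooled$fp_total, 0))
  structure(list(full = full, excluded = excluded, summary = summary),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result: full ACC %.4f>\n", x$full$pooled$acc))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cross-validate every nonempty modality subset
#'
#' One cross-validation per nonempty subset of modalities (2^p - 1 runs),
#' all on the same fold split; results sorted by pooled accuracy.
#'
#' @inheritParams leave_one_feature_out
#' @return List: `table` (data frame, one row per subset, sorted by
#'   descending accuracy), `runs` (named list of cv_result).
#' @export
feature_combinations <- function(bundle, config = model_config(), k = 5L,
                                 seed = 1L, average = "weighted") {
  mods <- names(bundle$features)
  if (length(mods) > 6L)
    stop("feature_combinations: p > 6 (", 2^length(mods) - 1, " runs) refused")
  folds <- stratified_kfold(bundle$pairs, k, seed)
  sims <- lapply(bundle$features, similarity_matrix)
  subsets <- unlist(lapply(seq_along(mods), function(sz)
    utils::combn(mods, sz, simplify = FALSE)), recursive = FALSE)
  runs <- lapply(subsets, function(ss)
    cross_validate(bundle, config, k, seed, folds = folds,
                   table = concat_similarities(sims[ss]), average = average))
  names(runs) <- vapply(subsets, paste, "", collapse = "+")
  tab <- do.call(rbind, Map(function(r, nm) report_row(r$pooled, nm), runs, names(runs)))
  tab <- tab[order(-tab$acc), ]
  rownames(tab) <- NULL
  list(table = tab, runs = runs)
}

#' PCA reduction of the drug feature table
#'
#' Scenario 1 projects each modality's similarity matrix separately onto the
#' minimal number of principal components reaching `variance_target`, then
#' concatenates the projections; scenario 2 concatenates first and projects
#' once. Columns are mean-centered, not variance-scaled (similarities share
#' a \[0, 1\] scale). Component counts are data-dependent and reported, not
#' asserted.
#'
#' @param bundle a [dataset_bundle].
#' @param scenario 1 (reduce then concatenate) or 2 (concatenate then reduce).
#' @param variance_target fraction of variance to retain, in (0, 1\].
#' @return A `drug_feature_table`-like object (no similarity blocks) with
#'   attribute `n_components` (named per modality for scenario 1, scalar for
#'   scenario 2).
#' @export
pca_reduce <- function(bundle, scenario = 2L, variance_target = 0.95) {
  if (!scenario %in% c(1L, 2L)) stop("pca_reduce: scenario must be 1 or 2")
  if (variance_target <= 0 || variance_target > 1)
    stop("pca_reduce: variance_target must be in (0, 1]")
  project <- function(M, label) {
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    if (sum(v) <= 0) stop("pca_reduce: degenerate (zero-variance) matrix for ", label)
    ncomp <- which(cumsum(v) / sum(v) >= variance_target - 1e-12)[1L]
    pc$x[, seq_len(ncomp), drop = FALSE]
  }
  ids <- bundle$features[[1L]]$drug_ids
  if (scenario == 1L) {
    proj <- lapply(names(bundle$features), function(mo)
      project(similarity_matrix(bundle$features[[mo]])$values, mo))
    names(proj) <- names(bundle$features)
    values <- do.call(cbind, proj)
    ncomp <- vapply(proj, ncol, 0L)
  } else {
    full <- build_feature_table(bundle)
    values <- project(full$values, "concatenated table")
    ncomp <- ncol(values)
  }
  structure(list(drug_ids = ids, values = values,
                 blocks = list(reduced = seq_len(ncol(values)))),
            class = "drug_feature_table", n_components = ncomp)
}

#' Compare pair-encoding operators
#'
#' Three cross-validations differing only in how the two drugs' rows are
#' combined: elementwise sum (default), concatenation, elementwise product.
#' Identical folds across the three runs.
#'
#' @inheritParams leave_one_feature_out
#' @return List: `table` (one metrics row per mode), `runs` (named list of
#'   cv_result).
#' @export
compare_pair_encodings <- function(bundle, config = model_config(), k = 5L,
                                   seed = 1L, average = "weighted") {
  folds <- stratified_kfold(bundle$pairs, k, seed)
  table <- build_feature_table(bundle)
  runs <- lapply(c(sum = "sum", concat = "concat", dot = "dot"), function(mode)
    cross_validate(bundle, config, k, seed, folds = folds, table = table,
                   encoding = mode, average = average))
  tab <- do.call(rbind, Map(function(r, nm) report_row(r$pooled, nm), runs, names(runs)))
  rownames(tab) <- NULL
  list(table = tab, runs = runs)
}

#' Per-modality model fusion
#'
#' Trains one network per modality on that modality's m-column similarity
#' block (pairs sum-encoded), then fuses held-out predictions: `mean`
#' averages the p probability rows before the argmax; `vote` takes each
#' model's argmax and the plurality event, ties to the lowest event index.
#' The contrast of interest is fusion versus the concatenated-table model.
#'
#' @inheritParams leave_one_feature_out
#' @param mode `"mean"` or `"vote"`.
#' @return List: `pooled` (eval_report on fused predictions), `probas`
#'   (fused probability matrix; for `vote`, normalized vote shares),
#'   `per_modality` (named list of single-modality cv_result).
#' @export
fuse_per_feature_models <- function(bundle, config = model_config(),
                                    mode = c("mean", "vote"), k = 5L, seed = 1L,
                                    average = "weighted") {
  mode <- match.arg(mode)
  mods <- names(bundle$features)
  if (length(mods) < 2L) stop("fuse_per_feature_models: need at least two modalities")
  folds <- stratified_kfold(bundle$pairs, k, seed)
  runs <- lapply(mods, function(mo)
    cross_validate(bundle, config, k, seed, folds = folds,
                   table = concat_similarities(list(similarity_matrix(bundle$features[[mo]]))),
                   average = average))
  names(runs) <- mods
  n_events <- length(bundle$pairs$event_labels)
  if (mode == "mean") {
    fused <- Reduce(`+`, lapply(runs, `[[`, "probas")) / length(runs)
  } else {
    votes <- vapply(runs, function(r) predict_event(r$probas),
                    integer(nrow(bundle$pairs$records)))
    fused <- t(apply(votes, 1L, tabulate, nbins = n_events)) / length(runs)
  }
  rec <- bundle$pairs$records
  fold_reports <- lapply(seq_len(folds$k), function(f) {
    te <- folds$assignments == f
    if (!any(te)) return(NULL)
    suppressWarnings(compute_metrics(rec$event[te], fused[te, , drop = FALSE], average))
  })
  list(pooled = pool_fold_reports(Filter(Negate(is.null), fold_reports)),
       probas = fused, per_modality = runs, mode = mode)
}
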