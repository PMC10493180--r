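# Evaluation apparatus: stratified fold construction, the six multiclass
# metrics (ACC, AUPR, AUROC, F_score, precision, recall) plus FP/FN
# accounting, plain and nested cross-validation, and ranked false-positive
# tables.
#
# Averaging conventions, stated once:
#  * precision / recall / F are micro-averaged one-vs-rest over events. In
#    single-label multiclass every misclassification is simultaneously one
#    FP (for the predicted event) and one FN (for the true event), so micro
#    precision == micro recall == micro F, and fp_total == fn_total.
#  * AUROC / AUPR are one-vs-rest per event, averaged with support weights
#    by default (macro available via `average`).
#  * In cross-validation the six metrics are averaged over folds while
#    FP/FN are summed over folds (a whole-dataset error count).

# ---- fold construction ---------------------------------------------------

# Internal: per-class round-robin fold assignment of a label vector after a
# seeded shuffle. Guarantees per-event counts across folds differ by <= 1.
stratify_labels <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2L) stop("stratified folds: k must be >= 2")
  if (k > n) stop("stratified folds: k = ", k, " exceeds record count ", n)
  assign <- integer(n)
  with_seed(seed, {
    for (e in sort(unique(labels))) {
      idx <- which(labels == e)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      assign[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
  })
  assign
}

#' Stratified k-fold split of a pair dataset
#'
#' Records of each event are shuffled (seeded) then dealt round-robin to the
#' k folds, so per-event counts across folds differ by at most one. Events
#' with fewer than k records land in some folds' test sets only.
#'
#' @param pairs a [pair_dataset].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Object of class `fold_split`: `k`, `assignments` (fold index per
#'   record), `stratified`, `seed`.
#' @export
stratified_kfold <- function(pairs, k = 5L, seed = 1L) {
  structure(list(k = as.integer(k),
                 assignments = stratify_labels(pairs$records$event, k, seed),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "fold_split")
}

# ---- curve metrics -------------------------------------------------------

# Mann-Whitney AUROC with tie correction (equals trapezoidal ROC area).
binary_auroc <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# Average precision (step-wise PR area, thresholds at distinct scores).
binary_aupr <- function(scores, positive) {
  np <- sum(positive)
  if (np == 0L || np == length(positive)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- positive[o]; s <- scores[o]
  tp <- cumsum(lab)
  at <- c(which(diff(s) != 0), length(s))    # last index of each tie group
  prec <- tp[at] / at
  rec <- tp[at] / np
  sum(prec * diff(c(0, rec)))
}

# ---- report --------------------------------------------------------------

#' Compute the six evaluation metrics plus FP/FN accounting
#'
#' Hard calls are the per-row argmax of `probas` (ties to the lowest event
#' index). ACC is the fraction of correct calls; precision/recall/F are
#' micro-averaged (hence identical for single-label data); AUROC/AUPR are
#' one-vs-rest per event, support-weighted by default. Events absent from
#' `y_true` are excluded from curve averaging with a warning.
#'
#' @param y_true integer event indices (1-based).
#' @param probas row-stochastic matrix, one column per event.
#' @param average `"weighted"` (support weights) or `"macro"` for the curve
#'   metrics.
#' @return Object of class `eval_report`: `acc`, `aupr`, `auroc`, `f_score`,
#'   `precision`, `recall`, `fp_total`, `fn_total`, `per_event` (data frame
#'   of per-event precision/recall/F/support), `average`.
#' @export
compute_metrics <- function(y_true, probas, average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (is.null(dim(probas))) probas <- matrix(probas, nrow = 1L)
  if (length(y_true) != nrow(probas))
    stop("compute_metrics: ", length(y_true), " labels but ", nrow(probas), " probability rows")
  n_events <- ncol(probas)
  y_true <- as.integer(y_true)
  pred <- predict_event(probas)
  acc <- mean(pred == y_true)

  tp <- fp <- fn <- integer(n_events)
  for (e in seq_len(n_events)) {
    tp[e] <- sum(pred == e & y_true == e)
    fp[e] <- sum(pred == e & y_true != e)
    fn[e] <- sum(pred != e & y_true == e)
  }
  micro_p <- sum(tp) / max(1L, sum(tp) + sum(fp))
  micro_r <- sum(tp) / max(1L, sum(tp) + sum(fn))
  micro_f <- if (micro_p + micro_r > 0) 2 * micro_p * micro_r / (micro_p + micro_r) else 0

  support <- tabulate(y_true, nbins = n_events)
  present <- which(support > 0L)
  if (length(present) < n_events)
    warning("compute_metrics: ", n_events - length(present),
            " event(s) absent from y_true excluded from curve averaging")
  auroc_e <- aupr_e <- rep(NA_real_, n_events)
  for (e in present) {
    pos <- y_true == e
    auroc_e[e] <- binary_auroc(probas[, e], pos)
    aupr_e[e] <- binary_aupr(probas[, e], pos)
  }
  wts <- if (average == "weighted") support[present] else rep(1L, length(present))
  wmean <- function(v) {
    ok <- !is.na(v[present])
    if (!any(ok)) NA_real_ else sum(v[present][ok] * wts[ok]) / sum(wts[ok])
  }
  per_event <- data.frame(
    event = seq_len(n_events),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), 0),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), 0),
    support = support)
  per_event$f_score <- ifelse(per_event$precision + per_event$recall > 0,
                              2 * per_event$precision * per_event$recall /
                                (per_event$precision + per_event$recall), 0)
  structure(list(acc = acc, aupr = wmean(aupr_e), auroc = wmean(auroc_e),
                 f_score = micro_f, precision = micro_p, recall = micro_r,
                 fp_total = sum(fp), fn_total = sum(fn),
                 per_event = per_event, average = average),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report: ACC %.4f  AUPR %.4f  AUROC %.4f  ",
                     "F %.4f  P %.4f  R %.4f  FP %d  FN %d>\n"),
              x$acc, x$aupr, x$auroc, x$f_score, x$precision, x$recall,
              x$fp_total, x$fn_total))
  invisible(x)
}

report_row <- function(report, id = "run") {
  data.frame(id = id, acc = report$acc, aupr = report$aupr, auroc = report$auroc,
             f_score = report$f_score, precision = report$precision,
             recall = report$recall, fp = report$fp_total, fn = report$fn_total)
}

#' Write evaluation reports as TSV
#'
#' One metrics row per named report, plus (optionally) the per-event table
#' of the first report.
#'
#' @param reports a single `eval_report` or named list of them.
#' @param path output TSV path for the metrics table.
#' @param per_event_path optional path for the per-event table.
#' @export
write_eval_report <- function(reports, path, per_event_path = NULL) {
  if (inherits(reports, "eval_report")) reports <- list(run = reports)
  rows <- do.call(rbind, Map(report_row, reports, names(reports)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(per_event_path))
    utils::write.table(reports[[1L]]$per_event, per_event_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- cross-validation ----------------------------------------------------

# One full CV pass over precomputed folds. Returns held-out probabilities
# for every record (each record is a test item exactly once), per-fold
# reports, and the fold-averaged pooled report.
cv_run <- function(table, pairs, config, folds, encoding = "sum",
                   average = "weighted") {
  rec <- pairs$records
  n_events <- length(pairs$event_labels)
  probas <- matrix(NA_real_, nrow(rec), n_events)
  fold_reports <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    tr <- folds$assignments != f
    te <- !tr
    if (!any(te)) next                     # empty test fold: skip (stays NULL)
    Xtr <- encode_pairs(table, rec$i[tr], rec$j[tr], encoding)
    Xte <- encode_pairs(table, rec$i[te], rec$j[te], encoding)
    cfg <- config
    cfg$seed <- config$seed + f            # distinct init per fold, replayable
    model <- suppressWarnings(fit_ddi_net(Xtr, rec$event[tr], cfg, n_events))
    probas[te, ] <- predict_proba(model, Xte)
    fold_reports[[f]] <- suppressWarnings(
      compute_metrics(rec$event[te], probas[te, , drop = FALSE], average))
  }
  fold_reports <- Filter(Negate(is.null), fold_reports)
  pooled <- pool_fold_reports(fold_reports)
  list(pooled = pooled, folds = fold_reports, probas = probas,
       predicted = predict_event(probas))
}

# Fold-level aggregation: metrics averaged, FP/FN summed.
pool_fold_reports <- function(fold_reports) {
  stopifnot(length(fold_reports) > 0)
  avg <- function(field) mean(vapply(fold_reports, `[[`, 0, field), na.rm = TRUE)
  structure(list(acc = avg("acc"), aupr = avg("aupr"), auroc = avg("auroc"),
                 f_score = avg("f_score"), precision = avg("precision"),
                 recall = avg("recall"),
                 fp_total = sum(vapply(fold_reports, `[[`, 0L, "fp_total")),
                 fn_total = sum(vapply(fold_reports, `[[`, 0L, "fn_total")),
                 per_event = fold_reports[[1L]]$per_event[0, ],
                 average = fold_reports[[1L]]$average),
            class = "eval_report")
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Builds the drug feature table (all modalities unless restricted), splits
#' pairs into stratified folds, trains one network per fold on the remaining
#' folds and scores the held-out pairs. Metrics are averaged over folds;
#' FP/FN are summed over folds (a whole-dataset error count). With
#' `repeats > 1` the whole procedure is repeated on reseeded splits and a
#' per-iteration table is returned alongside iteration-averaged metrics.
#'
#' @param bundle a [dataset_bundle].
#' @param config a [model_config].
#' @param k number of folds.
#' @param seed seed for fold construction (model seeds derive from
#'   `config$seed`).
#' @param modalities optional subset of modality names to use.
#' @param encoding pair encoding mode (`"sum"`, `"concat"`, `"dot"`).
#' @param folds optional precomputed [stratified_kfold()] split, used to pair
#'   experiment variants on identical folds.
#' @param table optional precomputed feature table (overrides `modalities`).
#' @param repeats repeat count for iterated CV (default 1).
#' @param average curve-metric averaging, see [compute_metrics()].
#' @return Object of class `cv_result`: `pooled` (eval_report), `folds`
#'   (per-fold reports), `probas` (held-out probability row per record),
#'   `predicted`, `fold_split`, and for `repeats > 1` a `per_iteration`
#'   data frame.
#' @export
cross_validate <- function(bundle, config = model_config(), k = 5L, seed = 1L,
                           modalities = NULL, encoding = "sum", folds = NULL,
                           table = NULL, repeats = 1L, average = "weighted") {
  if (is.null(table))
    table <- build_feature_table(bundle,
                                 if (is.null(modalities)) names(bundle$features) else modalities)
  if (is.null(folds)) folds <- stratified_kfold(bundle$pairs, k, seed)
  run1 <- cv_run(table, bundle$pairs, config, folds, encoding, average)
  out <- c(run1, list(fold_split = folds, config = config, encoding = encoding))
  if (repeats > 1L) {
    rows <- report_row(run1$pooled, "iter1")
    for (r in 2L:repeats) {
      fr <- stratified_kfold(bundle$pairs, k, seed + r - 1L)
      rr <- cv_run(table, bundle$pairs, config, fr, encoding, average)
      rows <- rbind(rows, report_row(rr$pooled, paste0("iter", r)))
    }
    out$per_iteration <- rows
    mean_rep <- out$pooled
    for (fld in c("acc", "aupr", "auroc", "f_score", "precision", "recall"))
      mean_rep[[fld]] <- mean(rows[[fld]])
    mean_rep$fp_total <- sum(rows$fp); mean_rep$fn_total <- sum(rows$fn)
    out$pooled_mean <- mean_rep
  }
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, encoding '%s'>\n", x$fold_split$k, x$encoding))
  print(x$pooled)
  invisible(x)
}

#' Nested cross-validation with inner-loop hyperparameter selection
#'
#' For each outer fold, an inner stratified k-fold CV on the outer training
#' pairs scores every candidate config by pooled (fold-averaged) accuracy;
#' the winner (ties to the earliest grid entry) is refit on the full outer
#' training set and evaluated on the outer test fold.
#'
#' @param bundle a [dataset_bundle].
#' @param grid non-empty list of [model_config] candidates.
#' @param outer_k,inner_k fold counts.
#' @param seed seed for fold construction.
#' @inheritParams cross_validate
#' @return List with `pooled` (eval_report over outer folds), `selections`
#'   (chosen grid index per outer fold), `outer_folds`, `probas`.
#' @export
nested_cv <- function(bundle, grid, outer_k = 5L, inner_k = 5L, seed = 1L,
                      modalities = NULL, encoding = "sum", average = "weighted") {
  if (!length(grid)) stop("nested_cv: empty config grid")
  table <- build_feature_table(bundle,
                               if (is.null(modalities)) names(bundle$features) else modalities)
  pairs <- bundle$pairs
  rec <- pairs$records
  n_events <- length(pairs$event_labels)
  outer <- stratified_kfold(pairs, outer_k, seed)
  probas <- matrix(NA_real_, nrow(rec), n_events)
  fold_reports <- vector("list", outer_k)
  selections <- integer(outer_k)
  for (f in seq_len(outer_k)) {
    tr_idx <- which(outer$assignments != f)
    te_idx <- which(outer$assignments == f)
    inner_assign <- stratify_labels(rec$event[tr_idx], inner_k, seed + 100L + f)
    inner_acc <- numeric(length(grid))
    for (g in seq_along(grid)) {
      accs <- numeric(inner_k)
      for (fi in seq_len(inner_k)) {
        itr <- tr_idx[inner_assign != fi]
        ite <- tr_idx[inner_assign == fi]
        if (!length(ite)) { accs[fi] <- NA; next }
        cfg <- grid[[g]]; cfg$seed <- cfg$seed + f * 10L + fi
        m <- suppressWarnings(fit_ddi_net(
          encode_pairs(table, rec$i[itr], rec$j[itr], encoding),
          rec$event[itr], cfg, n_events))
        pp <- predict_proba(m, encode_pairs(table, rec$i[ite], rec$j[ite], encoding))
        accs[fi] <- mean(predict_event(pp) == rec$event[ite])
      }
      inner_acc[g] <- mean(accs, na.rm = TRUE)
    }
    selections[f] <- which.max(inner_acc)    # ties -> earliest grid entry
    cfg <- grid[[selections[f]]]; cfg$seed <- cfg$seed + f
    m <- suppressWarnings(fit_ddi_net(
      encode_pairs(table, rec$i[tr_idx], rec$j[tr_idx], encoding),
      rec$event[tr_idx], cfg, n_events))
    probas[te_idx, ] <- predict_proba(
      m, encode_pairs(table, rec$i[te_idx], rec$j[te_idx], encoding))
    fold_reports[[f]] <- suppressWarnings(
      compute_metrics(rec$event[te_idx], probas[te_idx, , drop = FALSE], average))
  }
  list(pooled = pool_fold_reports(fold_reports), folds = fold_reports,
       selections = selections, outer_folds = outer, probas = probas)
}

# ---- ranked false positives ---------------------------------------------

#' Highest-confidence false positives
#'
#' Among records whose predicted event differs from the recorded event, the
#' k with the largest predicted-event probability, descending (ties by
#' record index). These are the candidate novel interactions.
#'
#' @param pairs the evaluated [pair_dataset].
#' @param probas held-out probability matrix (e.g. `cv_result$probas`).
#' @param k number of pairs to return.
#' @return data frame with drug_a, drug_b, true_event, predicted_event,
#'   probability; if fewer than `k` false positives exist, all are returned
#'   and attribute `note` says so.
#' @export
top_false_positives <- function(pairs, probas, k = 5L) {
  rec <- pairs$records
  pred <- predict_event(probas)
  p_pred <- probas[cbind(seq_len(nrow(probas)), pred)]
  fp <- which(pred != rec$event)
  o <- fp[order(-p_pred[fp], fp)]
  out <- data.frame(drug_a = pairs$drug_ids[rec$i[o]],
                    drug_b = pairs$drug_ids[rec$j[o]],
                    true_event = pairs$event_labels[rec$event[o]],
                    predicted_event = pairs$event_labels[pred[o]],
                    probability = p_pred[o])
  if (nrow(out) < k)
    attr(out, "note") <- sprintf("only %d false positives available (asked for %d)",
                                 nrow(out), k)
  utils::head(out, k)
}
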