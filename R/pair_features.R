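# Aggregation: concatenate per-modality similarity matrices into the drug
# feature table (m rows, p*m columns), then encode a drug pair as a single
# vector. The default encoding sums the two drugs' rows, which makes the
# pair representation order-invariant; concatenation and elementwise product
# exist for the aggregation-operator comparison.

#' Concatenate per-modality similarity matrices into a drug feature table
#'
#' Horizontal concatenation in the given modality order; each modality's
#' column range is recorded in `blocks` by name so downstream ablation
#' bookkeeping never relies on position.
#'
#' @param mats list of `similarity_matrix` objects sharing `drug_ids`.
#' @return Object of class `drug_feature_table`: `drug_ids`, `values`
#'   (m x p*m matrix), `blocks` (named list of column index ranges).
#' @export
concat_similarities <- function(mats) {
  if (!length(mats)) stop("concat_similarities: empty modality list")
  ids <- mats[[1L]]$drug_ids
  for (sm in mats)
    if (!identical(sm$drug_ids, ids))
      stop("concat_similarities: modality '", sm$modality, "' disagrees on drug ids")
  values <- do.call(cbind, lapply(mats, `[[`, "values"))
  m <- length(ids)
  blocks <- stats::setNames(
    lapply(seq_along(mats), function(k) ((k - 1L) * m + 1L):(k * m)),
    vapply(mats, `[[`, "", "modality"))
  structure(list(drug_ids = ids, values = values, blocks = blocks),
            class = "drug_feature_table")
}

#' @export
print.drug_feature_table <- function(x, ...) {
  cat(sprintf("<drug_feature_table: %d drugs x %d columns (%s)>\n",
              nrow(x$values), ncol(x$values), paste(names(x$blocks), collapse = " | ")))
  invisible(x)
}

#' Extract one modality's block from a drug feature table
#' @param table a `drug_feature_table`.
#' @param modality block name.
#' @return The m x m similarity block as a plain matrix.
#' @export
table_block <- function(table, modality) {
  if (!modality %in% names(table$blocks))
    stop("table_block: no block named '", modality, "'")
  table$values[, table$blocks[[modality]], drop = FALSE]
}

#' Encode one drug pair as a model input vector
#'
#' `sum` adds the two drugs' feature-table rows (entries in \[0, 2\],
#' swap-invariant, the default everywhere); `concat` appends row j after row
#' i (order-dependent); `dot` takes the elementwise product (swap-invariant).
#'
#' @param table a `drug_feature_table`.
#' @param i,j distinct drug row indices.
#' @param mode one of `"sum"`, `"concat"`, `"dot"`.
#' @return Numeric vector of length p*m (`sum`, `dot`) or 2*p*m (`concat`).
#' @export
encode_pair <- function(table, i, j, mode = c("sum", "concat", "dot")) {
  mode <- match.arg(mode)
  if (i == j) stop("encode_pair: self-pair (i == j) is undefined")
  drop(encode_pairs(table, i, j, mode))
}

#' Encode many drug pairs at once
#'
#' Vectorised form of [encode_pair()]; one output row per pair.
#'
#' @param table a `drug_feature_table`.
#' @param i,j equal-length integer vectors of drug indices, elementwise distinct.
#' @param mode encoding mode, see [encode_pair()].
#' @return Numeric matrix, one encoded pair per row.
#' @export
encode_pairs <- function(table, i, j, mode = c("sum", "concat", "dot")) {
  mode <- match.arg(mode)
  if (length(i) != length(j)) stop("encode_pairs: i and j lengths differ")
  if (any(i == j)) stop("encode_pairs: self-pair at position ", which(i == j)[1L])
  V <- table$values
  if (any(c(i, j) < 1L) || any(c(i, j) > nrow(V)))
    stop("encode_pairs: drug index out of range")
  switch(mode,
         sum    = V[i, , drop = FALSE] + V[j, , drop = FALSE],
         concat = cbind(V[i, , drop = FALSE], V[j, , drop = FALSE]),
         dot    = V[i, , drop = FALSE] * V[j, , drop = FALSE])
}

#' Build the drug feature table for a bundle
#'
#' Convenience wrapper: Jaccard similarity per modality, then concatenation.
#' `modalities` restricts/reorders the blocks (used by ablation and subset
#' sweeps); default is the bundle's own modality order.
#'
#' @param bundle a [dataset_bundle].
#' @param modalities character vector of modality names to include.
#' @return A `drug_feature_table`.
#' @export
build_feature_table <- function(bundle, modalities = names(bundle$features)) {
  missing <- setdiff(modalities, names(bundle$features))
  if (length(missing))
    stop("build_feature_table: unknown modality: ", paste(missing, collapse = ", "))
  concat_similarities(lapply(bundle$features[modalities], similarity_matrix))
}
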