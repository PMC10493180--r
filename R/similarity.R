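# Per-modality Jaccard similarity.
#
# For drugs di, dj with feature index sets X_di, X_dj (columns equal to 1 in
# their rows of one modality's binary matrix):
#   J(X_di, X_dj) = |X_di n X_dj| / (|X_di| + |X_dj| - |X_di n X_dj|)
# The 0/0 case (both sets empty) is defined as 0: absence of evidence must
# not assert maximal similarity. That convention lives here and nowhere else.

#' Jaccard similarity of two binary feature rows
#'
#' @param x,y binary (0/1) vectors of equal length.
#' @return Scalar in \[0, 1\]; 0 when both index sets are empty.
#' @export
jaccard <- function(x, y) {
  if (length(x) != length(y))
    stop("jaccard: length mismatch (", length(x), " vs ", length(y), ")")
  if (length(x) < 1L) stop("jaccard: empty vectors")
  inter <- sum(x == 1 & y == 1)
  uni <- sum(x == 1) + sum(y == 1) - inter
  if (uni == 0) 0 else inter / uni
}

#' All-pairs Jaccard similarity matrix for one modality
#'
#' Computes the m x m matrix with entry (i, j) = `jaccard(row_i, row_j)` via
#' a dense cross-product (intersections = M M'), exactly equivalent to the
#' set-based definition. Diagonal entries are 1 for any drug with at least
#' one feature present, 0 for all-zero rows (the 0/0 convention).
#'
#' @param fm a [feature_matrix].
#' @return Object of class `similarity_matrix`: fields `modality`,
#'   `drug_ids`, `values` (symmetric m x m matrix in \[0, 1\]).
#' @export
similarity_matrix <- function(fm) {
  if (!inherits(fm, "feature_matrix")) stop("similarity_matrix: need a feature_matrix")
  M <- fm$values
  storage.mode(M) <- "double"
  inter <- tcrossprod(M)                 # |X_i n X_j|
  sz <- rowSums(M)
  uni <- outer(sz, sz, `+`) - inter      # |X_i| + |X_j| - |X_i n X_j|
  S <- ifelse(uni > 0, inter / uni, 0)
  S <- (S + t(S)) / 2                    # exact symmetry against fp jitter
  dimnames(S) <- list(fm$drug_ids, fm$drug_ids)
  structure(list(modality = fm$modality, drug_ids = fm$drug_ids, values = S),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix '%s': %d x %d, mean off-diagonal %.3f>\n",
              x$modality, nrow(x$values), ncol(x$values),
              mean(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

#' Write a similarity matrix to TSV for inspection
#'
#' @param sm a `similarity_matrix`.
#' @param path output file.
#' @export
write_similarity_matrix <- function(sm, path) {
  df <- data.frame(drug_id = sm$drug_ids, sm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
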