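# ---- constructors & validators ------------------------------------------

#' Binary drug feature matrix for one modality
#'
#' A `feature_matrix` holds one modality's drugs x features binary incidence
#' matrix: entry (i, j) is 1 when drug i carries feature j (a mono side
#' effect, a protein target, an enzyme, a chemical substructure bit, a
#' pathway), 0 otherwise.
#'
#' @param values integer/numeric matrix of 0/1 values, drugs in rows.
#' @param drug_ids character vector of unique drug identifiers (row labels).
#' @param columns character vector of unique feature identifiers.
#' @param modality short label for the feature type (e.g. "target").
#' @return An object of class `feature_matrix` with fields `modality`,
#'   `drug_ids`, `columns`, `values` (a 0/1 integer matrix).
#' @export
feature_matrix <- function(values, drug_ids, columns, modality) {
  values <- as.matrix(values)
  if (nrow(values) != length(drug_ids))
    stop("feature_matrix: ", nrow(values), " rows but ", length(drug_ids), " drug ids")
  if (ncol(values) != length(columns))
    stop("feature_matrix: ", ncol(values), " columns but ", length(columns), " feature ids")
  if (ncol(values) < 1L) stop("feature_matrix: must have at least one feature column")
  if (anyDuplicated(drug_ids)) stop("feature_matrix: duplicate drug id: ",
                                    drug_ids[duplicated(drug_ids)][1L])
  if (anyDuplicated(columns)) stop("feature_matrix: duplicate feature id: ",
                                   columns[duplicated(columns)][1L])
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("feature_matrix: non-binary value %s at drug '%s', feature '%s'",
                 format(values[i, j]), drug_ids[i], columns[j]))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(drug_ids, columns)
  structure(list(modality = as.character(modality),
                 drug_ids = as.character(drug_ids),
                 columns  = as.character(columns),
                 values   = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s': %d drugs x %d features, density %.3f>\n",
              x$modality, nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Labeled drug-pair dataset
#'
#' Records of (drug i, drug j, event) triples over a fixed drug universe.
#' Each unordered pair appears at most once (single-label formulation: when a
#' pair has several reported adverse effects upstream, only one label — by
#' convention the most frequent effect — is kept).
#'
#' @param drug_ids character vector of drug identifiers (the universe).
#' @param i,j integer indices into `drug_ids` (1-based), `i != j`.
#' @param event integer event indices in `1..n_events`.
#' @param event_labels character vector of event names, in index order.
#' @return Object of class `pair_dataset` with fields `drug_ids`, `records`
#'   (data.frame with columns i, j, event) and `event_labels`.
#' @export
pair_dataset <- function(drug_ids, i, j, event, event_labels) {
  m <- length(drug_ids)
  i <- as.integer(i); j <- as.integer(j); event <- as.integer(event)
  if (length(i) != length(j) || length(i) != length(event))
    stop("pair_dataset: i, j, event lengths differ")
  if (anyDuplicated(drug_ids)) stop("pair_dataset: duplicate drug ids")
  if (length(i) && (any(i < 1L | i > m) || any(j < 1L | j > m)))
    stop("pair_dataset: drug index out of range 1..", m)
  if (any(i == j)) stop("pair_dataset: self-pair at record ", which(i == j)[1L])
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("pair_dataset: duplicate unordered pair {",
         paste(drug_ids[as.integer(strsplit(d, " ")[[1L]])], collapse = ", "), "}")
  }
  n <- length(event_labels)
  if (length(event) && (any(event < 1L) || any(event > n)))
    stop("pair_dataset: event index out of range 1..", n)
  if (length(event) && !all(seq_len(n) %in% event))
    warning("pair_dataset: some event labels have no records")
  structure(list(drug_ids = as.character(drug_ids),
                 records = data.frame(i = i, j = j, event = event),
                 event_labels = as.character(event_labels)),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset: %d pairs over %d drugs, %d event types>\n",
              nrow(x$records), length(x$drug_ids), length(x$event_labels)))
  invisible(x)
}

#' Bundle of aligned feature matrices and a pair dataset
#'
#' All members must agree on `drug_ids` and their order; this is the unit the
#' whole pipeline consumes (the analogue of one benchmark dataset).
#'
#' @param features list of [feature_matrix] objects with identical `drug_ids`.
#' @param pairs a [pair_dataset] on the same `drug_ids`.
#' @return Object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(features, pairs) {
  if (!length(features)) stop("dataset_bundle: need at least one feature matrix")
  ids <- features[[1L]]$drug_ids
  for (fm in features) {
    if (!inherits(fm, "feature_matrix")) stop("dataset_bundle: features must be feature_matrix objects")
    if (!identical(fm$drug_ids, ids))
      stop("dataset_bundle: modality '", fm$modality, "' disagrees on drug ids/order")
  }
  if (!identical(pairs$drug_ids, ids))
    stop("dataset_bundle: pair dataset disagrees on drug ids/order")
  names(features) <- vapply(features, function(f) f$modality, character(1L))
  if (anyDuplicated(names(features))) stop("dataset_bundle: duplicate modality names")
  structure(list(features = features, pairs = pairs), class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle: %d drugs, %d modalities (%s), %d pairs, %d events>\n",
              length(x$features[[1L]]$drug_ids), length(x$features),
              paste(names(x$features), collapse = ", "),
              nrow(x$pairs$records), length(x$pairs$event_labels)))
  invisible(x)
}

# ---- file I/O ------------------------------------------------------------
# One dialect only: tab-separated UTF-8, header row, first column "drug_id".

#' Read a binary feature matrix from a TSV file
#'
#' Expects a header row of feature identifiers with leading column `drug_id`,
#' then one row per drug with 0/1 entries. Non-binary cells and duplicate
#' drug ids are hard errors (the offending cell is named).
#'
#' @param path file path.
#' @param modality modality label to attach.
#' @return A [feature_matrix]; row order is preserved from the file.
#' @export
load_feature_matrix <- function(path, modality) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "drug_id")
    stop("load_feature_matrix: first column of ", path, " must be 'drug_id'")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(num)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(num)) + 1L
    stop(sprintf("load_feature_matrix: non-binary cell '%s' at drug '%s', feature '%s' in %s",
                 vals[i, j], ids[i], colnames(vals)[j], path))
  }
  feature_matrix(num, ids, colnames(vals), modality)
}

#' Read a DDI event table from a TSV file
#'
#' Expects columns `drug_a`, `drug_b`, `event`. Drug names are resolved
#' against `drug_ids`; event labels are assigned contiguous indices in order
#' of first appearance, so reports are reproducible run to run. Duplicate
#' unordered pairs are rejected (conflicting labels are listed).
#'
#' @param path file path.
#' @param drug_ids ordered drug identifier universe.
#' @param event_labels optional fixed label order; overrides first-appearance
#'   indexing (used by [load_bundle()] to make round trips exact). Labels in
#'   the file but not in this list are an error.
#' @return A [pair_dataset].
#' @export
load_ddi_table <- function(path, drug_ids, event_labels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("drug_a", "drug_b", "event")
  if (!all(need %in% names(df)))
    stop("load_ddi_table: ", path, " must have columns drug_a, drug_b, event")
  ia <- match(df$drug_a, drug_ids)
  ib <- match(df$drug_b, drug_ids)
  if (anyNA(ia) || anyNA(ib)) {
    unk <- unique(c(df$drug_a[is.na(ia)], df$drug_b[is.na(ib)]))
    stop("load_ddi_table: unknown drug(s): ", paste(unk, collapse = ", "))
  }
  labels <- if (is.null(event_labels)) unique(df$event) else as.character(event_labels)
  ev <- match(df$event, labels)
  if (anyNA(ev))
    stop("load_ddi_table: event label(s) not in supplied event_labels: ",
         paste(unique(df$event[is.na(ev)]), collapse = ", "))
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup][1L], key)
    other <- which(dup)[1L]
    msg <- if (ev[first] != ev[other]) " with conflicting labels" else ""
    stop(sprintf("load_ddi_table: duplicate pair {%s, %s}%s",
                 df$drug_a[other], df$drug_b[other], msg))
  }
  pair_dataset(drug_ids, ia, ib, ev, labels)
}

#' Write a dataset bundle to a directory
#'
#' Emits one `<modality>.tsv` per feature matrix, `ddi.tsv` for the pair
#' table, and a `manifest.txt` (key: value lines) recording the file names
#' and the expected drug, modality and event counts. `load_bundle()` of the
#' result reproduces the bundle exactly.
#'
#' @param bundle a [dataset_bundle].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("write_bundle: cannot create directory ", dir)
  files <- character(0)
  for (fm in bundle$features) {
    f <- file.path(dir, paste0(fm$modality, ".tsv"))
    df <- data.frame(drug_id = fm$drug_ids, fm$values, check.names = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  p <- bundle$pairs
  f <- file.path(dir, "ddi.tsv")
  df <- data.frame(drug_a = p$drug_ids[p$records$i],
                   drug_b = p$drug_ids[p$records$j],
                   event  = p$event_labels[p$records$event])
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  mf <- file.path(dir, "manifest.txt")
  writeLines(c(paste0("modalities: ", paste(names(bundle$features), collapse = ",")),
               "ddi_file: ddi.tsv",
               paste0("event_labels: ", paste(p$event_labels, collapse = ",")),
               paste0("n_drugs: ", length(p$drug_ids)),
               paste0("n_modalities: ", length(bundle$features)),
               paste0("n_events: ", length(p$event_labels))),
             mf)
  invisible(c(files, mf))
}

#' Load a dataset bundle written by [write_bundle()]
#'
#' @param dir directory containing `manifest.txt` and the TSV files.
#' @return A [dataset_bundle].
#' @export
load_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop("load_bundle: no manifest.txt in ", dir)
  kv <- read_kv_file(mf)
  mods <- strsplit(kv[["modalities"]], ",", fixed = TRUE)[[1L]]
  feats <- lapply(mods, function(mo)
    load_feature_matrix(file.path(dir, paste0(mo, ".tsv")), mo))
  ids <- feats[[1L]]$drug_ids
  labels <- if (!is.null(kv[["event_labels"]]) && nzchar(kv[["event_labels"]]))
    strsplit(kv[["event_labels"]], ",", fixed = TRUE)[[1L]] else NULL
  pairs <- load_ddi_table(file.path(dir, kv[["ddi_file"]]), ids, labels)
  b <- dataset_bundle(feats, pairs)
  chk <- c(n_drugs = length(ids), n_modalities = length(feats),
           n_events = length(pairs$event_labels))
  for (k in names(chk)) {
    if (!is.null(kv[[k]]) && as.integer(kv[[k]]) != chk[[k]])
      stop("load_bundle: manifest expects ", k, " = ", kv[[k]], " but found ", chk[[k]])
  }
  b
}

# Flat "key: value" file reader (manifest and run configs share the dialect).
read_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed key:value line in ", path, ": ", lines[bad][1L])
  stats::setNames(lapply(m, `[`, 3L), trimws(vapply(m, `[`, "", 2L)))
}
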