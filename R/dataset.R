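#' Tabular categorical dataset with an optional train/test split
#'
#' A thin wrapper around a data.frame of factors. Every column carries its
#' full declared level set (not just the levels observed in the rows), the
#' target column is named, and an optional split partitions the rows into
#' disjoint train and test index sets.
#'
#' @param df data.frame; non-factor columns are converted to factors using
#'   the levels observed (sorted) unless `levels` supplies the domain.
#' @param target name of the target column, or `NULL`.
#' @param levels optional named list giving the full level domain of each
#'   column (ground-truth codebook); values outside the domain are an error.
#' @param train,test optional disjoint integer row indices.
#' @return the data.frame with class `md_dataset` and attributes `target`,
#'   `train`, `test`.
#' @export
tabular_dataset <- function(df, target = NULL, levels = NULL,
                            train = NULL, test = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in names(df)) {
    dom <- if (!is.null(levels)) levels[[j]] else NULL
    if (is.null(dom)) {
      dom <- if (is.factor(df[[j]])) base::levels(df[[j]]) else
        sort(unique(as.character(df[[j]])))
    }
    vals <- as.character(df[[j]])
    if (!all(vals %in% dom))
      stop("column '", j, "' contains values outside its declared levels")
    df[[j]] <- factor(vals, levels = dom)
  }
  if (!is.null(target) && !target %in% names(df))
    stop("target column '", target, "' not present")
  if (!is.null(train) || !is.null(test)) {
    if (length(intersect(train, test)) > 0)
      stop("train and test rows must be disjoint")
    stopifnot(all(c(train, test) %in% seq_len(nrow(df))))
  }
  structure(df, target = target, train = train, test = test,
            class = c("md_dataset", "data.frame"))
}

#' Split the first `n_train` rows as train and the next `n_test` as test
#' @param data an [tabular_dataset()] (or plain data.frame).
#' @param n_train,n_test split sizes; must not exceed `nrow(data)`.
#' @inheritParams tabular_dataset
#' @return an `md_dataset` with the split attributes set.
#' @export
split_dataset <- function(data, n_train, n_test, target = attr(data, "target")) {
  if (n_train + n_test > nrow(data))
    stop("split sizes exceed the number of rows")
  tabular_dataset(data, target = target,
                  levels = lapply(data, base::levels),
                  train = seq_len(n_train),
                  test = n_train + seq_len(n_test))
}

train_rows <- function(data) {
  idx <- attr(data, "train")
  if (is.null(idx)) stop("dataset has no train split")
  data[idx, , drop = FALSE]
}

test_rows <- function(data) {
  idx <- attr(data, "test")
  if (is.null(idx)) stop("dataset has no test split")
  data[idx, , drop = FALSE]
}

#' Write / read a dataset as CSV (header row, level labels as strings)
#' @param data dataset to write.
#' @param path file path.
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = TRUE)
}

#' @rdname write_dataset_csv
#' @param target,levels forwarded to [tabular_dataset()].
#' @export
read_dataset_csv <- function(path, target = NULL, levels = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  tabular_dataset(df, target = target, levels = levels)
}
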