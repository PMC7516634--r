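#' Assemble a labelled dataset
#'
#' Light container for a design matrix plus integer class labels, the unit of
#' training input for [mlp_train()]. Labels are 0-based so they map directly
#' onto output-unit indices.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y integer vector of labels in `[0, n_classes)`, one per row of `x`.
#' @param class_names optional character vector naming the label values.
#' @return An object of class `motif_dataset`: a list with elements `x`, `y`
#'   and `class_names`.
#' @export
motif_dataset <- function(x, y, class_names = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) {
    stop("number of rows of `x` must equal length of `y`")
  }
  if (length(y) > 0L && min(y) < 0L) stop("labels must be non-negative")
  if (is.null(class_names) && length(y) > 0L) {
    class_names <- as.character(seq_len(max(y) + 1L) - 1L)
  }
  structure(list(x = x, y = y, class_names = class_names),
            class = "motif_dataset")
}

#' @export
print.motif_dataset <- function(x, ...) {
  cat(sprintf("<motif_dataset> %d samples x %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(unique(x$y))))
  tab <- table(x$y)
  cat("label counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.motif_dataset <- function(x) dim(x$x)

#' Sample covariance matrix of a dataset
#'
#' Feature-by-feature sample covariance of the design matrix. For the
#' binary-tree environment this exhibits a nested hierarchical structure; for
#' the independent-clusters environment it is block diagonal up to the glassy
#' background induced by the constant non-selected features.
#'
#' @param dataset a [motif_dataset()].
#' @return Symmetric positive semidefinite numeric matrix of size
#'   `n_features x n_features`.
#' @export
covariance_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "motif_dataset"))
  if (nrow(dataset$x) < 2L) stop("need at least 2 samples for a covariance")
  stats::cov(dataset$x)
}

#' Within- versus between-block covariance contrast
#'
#' Summarizes the block structure of a covariance matrix given a grouping of
#' features: mean absolute covariance over within-group (off-diagonal) cells
#' and over between-group cells. For the independent-clusters dataset the
#' within-group mean exceeds the between-group mean.
#'
#' @param dataset a [motif_dataset()].
#' @param groups integer vector assigning each feature to a group.
#' @return A list with numeric scalars `within` and `between`.
#' @export
covariance_block_contrast <- function(dataset, groups = NULL) {
  if (is.null(groups)) groups <- attr(dataset, "node_groups")
  if (is.null(groups)) stop("feature `groups` must be supplied")
  cv <- covariance_matrix(dataset)
  if (length(groups) != ncol(cv)) stop("`groups` must have one entry per feature")
  same <- outer(groups, groups, "==")
  off <- !diag(TRUE, ncol(cv))
  list(within  = mean(abs(cv[same & off])),
       between = mean(abs(cv[!same])))
}

#' Write a dataset to CSV
#'
#' One sample per line; feature columns first, final column `label` holds the
#' integer class.
#'
#' @param dataset a [motif_dataset()].
#' @param path file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "motif_dataset"))
  df <- as.data.frame(dataset$x)
  names(df) <- sprintf("f%02d", seq_len(ncol(dataset$x)) - 1L)
  df$label <- dataset$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path file path; expects a header row and a final `label` column.
#' @return A [motif_dataset()].
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("CSV must contain a `label` column")
  y <- as.integer(df$label)
  x <- as.matrix(df[setdiff(names(df), "label")])
  motif_dataset(x, y)
}
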