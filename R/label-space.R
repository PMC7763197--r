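#' The six-compartment miRNA label space
#'
#' Ordered label names for the subcellular compartments a mature human miRNA
#' may occupy. The order is fixed and defines the column index of every label
#' vector, score matrix and prediction file produced by the package.
#'
#' @return A character vector of length 6.
#' @export
#' @examples
#' mirna_label_space()
mirna_label_space <- function() {
  c("exosome", "cytoplasm", "mitochondrion", "microvesicle",
    "circulating", "nucleus")
}

check_label_space <- function(label_space) {
  if (!is.character(label_space) || length(label_space) < 1) {
    abort("`label_space` must be a non-empty character vector")
  }
  if (anyDuplicated(label_space)) {
    abort("`label_space` contains duplicated label names")
  }
  label_space
}

#' Convert label sets to a binary indicator matrix
#'
#' @param labels A list of character vectors (one label set per example).
#' @param label_space Ordered label names defining the columns.
#' @return A 0/1 integer matrix with one row per example and
#'   `length(label_space)` columns, named by label.
#' @export
labels_to_matrix <- function(labels, label_space = mirna_label_space()) {
  check_label_space(label_space)
  m <- matrix(0L, nrow = length(labels), ncol = length(label_space),
              dimnames = list(NULL, label_space))
  for (i in seq_along(labels)) {
    li <- labels[[i]]
    if (length(li)) {
      bad <- setdiff(li, label_space)
      if (length(bad)) {
        abort(paste0("unknown label(s) in example ", i, ": ",
                     paste(bad, collapse = ", ")))
      }
      m[i, match(li, label_space)] <- 1L
    }
  }
  m
}

#' Convert a binary indicator matrix back to label sets
#'
#' @param m A 0/1 matrix whose columns follow `label_space`.
#' @inheritParams labels_to_matrix
#' @return A list of character vectors.
#' @export
matrix_to_labels <- function(m, label_space = colnames(m)) {
  check_label_space(label_space)
  stopifnot(ncol(m) == length(label_space))
  lapply(seq_len(nrow(m)), function(i) label_space[m[i, ] != 0])
}

# Normalize truth/estimate arguments: accept a list of label sets or a
# binary matrix; return a list of character sets.
as_label_sets <- function(x, label_space = NULL) {
  if (is.matrix(x)) {
    ls <- colnames(x) %||% label_space
    if (is.null(ls)) abort("matrix input needs column names or `label_space`")
    return(matrix_to_labels(x, ls))
  }
  if (is.list(x)) return(lapply(x, as.character))
  abort("expected a list of label sets or a binary indicator matrix")
}
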