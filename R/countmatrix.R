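#' Count matrix with tumor/normal labels
#'
#' Bundles an integer gene-by-sample count matrix with a per-sample class
#' label (`"tumor"` or `"normal"`) and the per-sample library sizes (column
#' sums). This is the container every downstream stage consumes.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Entries must be non-negative.
#' @param labels character or factor of length `ncol(counts)` with values
#'   `"tumor"` / `"normal"`, in column order.
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `labels` (factor with levels `normal`, `tumor`) and `library_sizes`.
#' @export
count_matrix <- function(counts, labels) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' needs both rownames (genes) and colnames (samples)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must contain non-negative integers")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(counts)) {
    stop("'labels' must have one entry per sample column")
  }
  bad <- setdiff(unique(labels), c("tumor", "normal"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      counts = counts,
      labels = factor(labels, levels = c("normal", "tumor")),
      library_sizes = colSums(counts)
    ),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf(
    "CountMatrix: %d genes x %d samples (%d tumor, %d normal)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$labels == "tumor"), sum(x$labels == "normal")
  ))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Write a count matrix and its labels to TSV files
#'
#' The counts file has a `gene` first column and one column per sample; the
#' labels file has two columns, `sample` and `label`.
#'
#' @param x a [count_matrix()] object.
#' @param counts_file,labels_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(x, counts_file, labels_file) {
  stopifnot(inherits(x, "CountMatrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(sample = colnames(x$counts), label = as.character(x$labels)),
    labels_file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(counts_file, labels_file))
}

#' Read a count matrix and labels from TSV files
#'
#' @param counts_file TSV with a `gene` first column and sample columns.
#' @param labels_file two-column TSV (`sample`, `label`).
#' @return A [count_matrix()] object; samples are put in the counts file's
#'   column order and labels matched by sample id.
#' @export
read_count_matrix <- function(counts_file, labels_file) {
  df <- read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  lab <- read.delim(labels_file, stringsAsFactors = FALSE)
  idx <- match(colnames(mat), lab$sample)
  if (anyNA(idx)) {
    stop("samples missing from the labels file: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  }
  count_matrix(mat, lab$label[idx])
}
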