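#' Gene-by-sample count matrix with metadata and spike-in flags
#'
#' Lightweight container for non-negative integer counts, optional per-sample
#' metadata (`sample`, `condition`, `timepoint_h`, `replicate`) and a logical
#' spike-in flag per gene. Spike-in rows are recognised by the `"ERCC-"` id
#' prefix unless an explicit flag vector is given.
#'
#' @param counts numeric matrix (genes x samples) of non-negative counts with
#'   unique gene ids as rownames.
#' @param meta optional `data.frame` of per-sample metadata containing a
#'   `sample` column matching `colnames(counts)`.
#' @param spike optional logical vector, one entry per gene; defaults to
#'   `grepl("^ERCC-", rownames(counts))`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `meta` and `spike`.
#' @export
count_matrix <- function(counts, meta = NULL, spike = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)))
    stop("`counts` must carry gene ids as rownames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(spike)) {
    spike <- grepl("^ERCC-", rownames(counts))
  } else {
    if (!is.logical(spike) || length(spike) != nrow(counts))
      stop("`spike` must be a logical vector with one entry per gene")
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"sample" %in% names(meta))
      stop("`meta` must contain a `sample` column")
    if (!setequal(meta$sample, colnames(counts)))
      stop("`meta$sample` must match the count matrix columns")
    meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(counts = counts, meta = meta, spike = spike),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d spike-in rows)\n",
              nrow(x$counts), ncol(x$counts), sum(x$spike)))
  if (!is.null(x$meta)) {
    cat("metadata columns:", paste(setdiff(names(x$meta), "sample"),
                                   collapse = ", "), "\n")
  }
  n <- min(5L, nrow(x$counts))
  m <- min(5L, ncol(x$counts))
  print(x$counts[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' Subset a count matrix by gene
#'
#' @param x a [count_matrix()].
#' @param genes logical or character index of rows to keep.
#' @return A `count_matrix` restricted to the selected genes.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.character(genes)) genes <- match(genes, rownames(x$counts))
  count_matrix(x$counts[genes, , drop = FALSE], meta = x$meta,
               spike = x$spike[if (is.logical(genes)) which(genes) else genes])
}
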