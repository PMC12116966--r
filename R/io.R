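#' @keywords internal
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con, sep = "\n")
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE)
      else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row naming the samples, a first column of unique gene ids,
#' and non-negative integer cells. Rows whose id starts with `"ERCC-"` are
#' flagged as spike-ins. If a metadata sidecar `<path minus .tsv>.meta.tsv`
#' exists (columns `sample`, `condition`, `timepoint_h`, `replicate` as
#' available) it is joined; `meta_path` overrides the sidecar convention.
#'
#' @param path TSV file of counts.
#' @param meta_path optional metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 2) stop("counts TSV needs a gene column plus >=1 sample")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  samples <- colnames(df)[-1]
  mat <- matrix(NA_real_, nrow(df), length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad))
      stop(sprintf("non-integer or negative count at row '%s', column '%s': %s",
                   genes[bad[1]], samples[j], raw[bad[1]]))
    mat[, j] <- val
  }
  meta <- NULL
  if (is.null(meta_path)) {
    cand <- sub("\\.tsv$", ".meta.tsv", path)
    if (cand != path && file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path))
    meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                              check.names = FALSE)
  count_matrix(mat, meta = meta)
}

#' Write a count matrix as canonical TSV
#'
#' Canonical formatting: tab-separated, `gene` as the first header field, LF
#' line endings, integer cells. `write_counts(read_counts(x))` reproduces a
#' canonically formatted file byte for byte. When metadata is present it is
#' written to the `.meta.tsv` sidecar.
#'
#' @param x a [count_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$counts)))
    df[[colnames(x$counts)[j]]] <- sprintf("%d", as.integer(x$counts[, j]))
  write_tsv(df, path)
  if (!is.null(x$meta)) {
    cand <- sub("\\.tsv$", ".meta.tsv", path)
    if (cand == path) cand <- paste0(path, ".meta.tsv")
    write_tsv(x$meta, cand)
  }
  invisible(path)
}

#' Read a transcript length table
#'
#' Two-column TSV (`transcript`, `length_nt`), lengths positive integers.
#'
#' @param path TSV path.
#' @return Named integer vector of lengths.
#' @export
read_transcript_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("transcript length table needs two columns")
  len <- as.numeric(df[[2]])
  if (any(is.na(len) | len <= 0 | len != floor(len)))
    stop("transcript lengths must be positive integers")
  if (anyDuplicated(df[[1]])) stop("duplicate transcript ids in ", path)
  stats::setNames(as.integer(len), as.character(df[[1]]))
}

#' Paired per-transcript IP/input coverage
#'
#' @param transcript transcript id.
#' @param ip,input per-nucleotide depth vectors of equal length.
#' @param ip_total,input_total library totals (sum of depths across the whole
#'   library); default to the per-transcript sums.
#' @return An object of class `coverage_pair`.
#' @export
coverage_pair <- function(transcript, ip, input,
                          ip_total = sum(ip), input_total = sum(input)) {
  if (length(ip) != length(input))
    stop("IP and input tracks must have equal length")
  if (any(ip < 0) || any(input < 0)) stop("coverage depths must be >= 0")
  if (ip_total <= 0 || input_total <= 0)
    stop("library totals must be positive")
  structure(list(transcript = as.character(transcript),
                 length = length(ip),
                 ip = as.numeric(ip), input = as.numeric(input),
                 ip_total = as.numeric(ip_total),
                 input_total = as.numeric(input_total)),
            class = "coverage_pair")
}

#' @export
print.coverage_pair <- function(x, ...) {
  cat(sprintf(
    "coverage_pair %s: %d nt, mean IP depth %.2f, mean input depth %.2f\n",
    x$transcript, x$length, mean(x$ip), mean(x$input)))
  invisible(x)
}

# Expand one bedGraph file into dense per-nt tracks over the declared
# transcripts. Intervals are 0-based half-open; absent positions are depth 0;
# overlapping intervals with conflicting values are rejected.
read_bedgraph <- function(path, lengths) {
  tracks <- lapply(lengths, function(n) numeric(n))
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      col.names = c("transcript", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) return(tracks)
  seen <- lapply(lengths, function(n) logical(n))
  for (i in seq_len(nrow(raw))) {
    tx <- raw$transcript[i]
    if (!tx %in% names(lengths))
      stop("bedGraph transcript '", tx, "' missing from length table")
    s <- raw$start[i]; e <- raw$end[i]; v <- raw$value[i]
    if (s < 0 || e <= s || e > lengths[[tx]])
      stop(sprintf("interval %s:[%d,%d) outside transcript length %d",
                   tx, s, e, lengths[[tx]]))
    if (v < 0) stop("negative coverage value in ", path)
    idx <- (s + 1L):e
    clash <- seen[[tx]][idx] & tracks[[tx]][idx] != v
    if (any(clash))
      stop(sprintf("overlapping intervals with conflicting values at %s:%d",
                   tx, s + which(clash)[1] - 1L))
    tracks[[tx]][idx] <- v
    seen[[tx]][idx] <- TRUE
  }
  tracks
}

#' Read a paired IP/input bedGraph into dense coverage
#'
#' bedGraph coordinates are transcript-relative, 0-based half-open; positions
#' absent from a file have depth 0. Library totals default to the sum of
#' depths over the whole file (all transcripts) and can be overridden.
#'
#' @param ip_path,input_path bedGraph files for the IP and input libraries.
#' @param lengths named vector of transcript lengths, or a path readable by
#'   [read_transcript_lengths()].
#' @param ip_total,input_total optional library-total overrides.
#' @return Named list of [coverage_pair()] objects, one per transcript.
#' @export
read_bedgraph_pair <- function(ip_path, input_path, lengths,
                               ip_total = NULL, input_total = NULL) {
  if (is.character(lengths) && length(lengths) == 1 && file.exists(lengths))
    lengths <- read_transcript_lengths(lengths)
  ip <- read_bedgraph(ip_path, lengths)
  input <- read_bedgraph(input_path, lengths)
  if (is.null(ip_total)) ip_total <- sum(vapply(ip, sum, numeric(1)))
  if (is.null(input_total)) input_total <- sum(vapply(input, sum, numeric(1)))
  pairs <- lapply(names(lengths), function(tx)
    coverage_pair(tx, ip[[tx]], input[[tx]],
                  ip_total = ip_total, input_total = input_total))
  stats::setNames(pairs, names(lengths))
}

#' Write dense tracks as bedGraph
#'
#' Adjacent equal-valued positions are merged into one interval; zero-depth
#' runs are omitted (absent means 0).
#'
#' @param tracks named list of per-nt depth vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (tx in names(tracks)) {
    r <- rle(tracks[[tx]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", tx, starts[keep], ends[keep],
                         format(r$values[keep], digits = 15, trim = TRUE,
                                scientific = FALSE)),
                 con, sep = "\n")
  }
  invisible(path)
}

#' Write called peaks as BED6
#'
#' One row per peak: transcript, start, end (0-based half-open), name
#' `peak_N`, score `min(round(100 * fold), 1000)`, strand `"+"`. Peaks must be
#' sorted and non-overlapping within each transcript (merging is
#' [call_peaks()]'s job). An empty peak table yields a file holding only the
#' header comment.
#'
#' @param peaks data.frame with columns `transcript`, `start`, `end`, `score`
#'   (the peak's maximum window fold).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# transcript\tstart\tend\tname\tscore\tstrand", con, sep = "\n")
  if (!is.null(peaks) && nrow(peaks)) {
    for (tx in unique(peaks$transcript)) {
      p <- peaks[peaks$transcript == tx, , drop = FALSE]
      if (is.unsorted(p$start, strictly = FALSE) ||
          any(p$start[-1] < p$end[-nrow(p)]))
        stop("overlapping or unsorted peaks on transcript ", tx)
    }
    score <- pmin(round(100 * peaks$score), 1000)
    writeLines(sprintf("%s\t%d\t%d\tpeak_%d\t%d\t+",
                       peaks$transcript, as.integer(peaks$start),
                       as.integer(peaks$end), seq_len(nrow(peaks)),
                       as.integer(score)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (first four+ columns used; `#` comments skipped).
#' @return data.frame with `transcript`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw))
    return(data.frame(transcript = character(), start = integer(),
                      end = integer()))
  out <- data.frame(transcript = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$score <- as.numeric(raw[[5]])
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `term`, `description`, then member
#' genes, tab-separated.
#'
#' @param path GMT path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need term, description, >=1 gene): ", ln)
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}
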