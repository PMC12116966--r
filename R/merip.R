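#' RPKM of a coverage window
#'
#' Reads per kilobase per million mapped reads for a transcript window,
#' treating per-nucleotide depth as read-equivalents:
#' `rpkm = mean_depth * 1e9 / library_total`
#' (i.e. depth summed over the window, divided by window length in kb and by
#' library total in millions). A uniform depth of 1 with a library of 10^6
#' gives rpkm 1000 for any window; doubling the library total halves the rpkm.
#'
#' @param track per-nt depth vector.
#' @param start,end 0-based half-open window bounds.
#' @param library_total total mapped read-equivalents in the library (> 0).
#' @return RPKM, a single number.
#' @export
window_rpkm <- function(track, start, end, library_total) {
  if (library_total <= 0) stop("library_total must be > 0")
  if (end <= start) stop("zero-length window")
  if (start < 0 || end > length(track)) stop("window outside track")
  mean(track[(start + 1L):end]) * 1e9 / library_total
}

# Sliding-window grid: starts at 0, step_nt, 2*step_nt, ...; the terminal
# truncated window is kept iff its length is >= step_nt.
window_grid <- function(len, window_nt, step_nt) {
  if (len < step_nt) return(NULL)
  starts <- seq.int(0L, len - 1L, by = step_nt)
  ends <- pmin(starts + window_nt, len)
  keep <- (ends - starts) >= step_nt
  cbind(start = starts[keep], end = ends[keep])
}

#' Sliding-window IP/input enrichment over one transcript
#'
#' Slides `window_nt`-wide windows every `step_nt` nt along the transcript
#' (terminal truncated windows are kept only if at least `step_nt` long),
#' computes IP and input RPKM per window, and the pseudocounted fold
#' `(ip_rpkm + pseudo_rpkm) / (input_rpkm + pseudo_rpkm)`. Windows whose raw
#' IP+input read-equivalents fall below `min_window_reads` fail the coverage
#' gate and can never be called enriched; among gated windows, enrichment is
#' `fold >= min_fold` (inclusive).
#'
#' @param pair a [coverage_pair()].
#' @param window_nt,step_nt window geometry (nt), `window_nt >= step_nt`.
#' @param pseudo_rpkm symmetric pseudo-RPKM.
#' @param min_window_reads coverage gate on raw IP+input depth sum.
#' @param min_fold inclusive enrichment threshold.
#' @return data.frame of window records: `transcript`, `start`, `end`,
#'   `ip_rpkm`, `input_rpkm`, `fold`, `gate_pass`, `enriched`. Empty (with a
#'   warning) for transcripts shorter than `step_nt`.
#' @export
window_enrichment <- function(pair, window_nt = 100, step_nt = 50,
                              pseudo_rpkm = 0.5, min_window_reads = 10,
                              min_fold = 4) {
  stopifnot(inherits(pair, "coverage_pair"))
  if (window_nt < step_nt || step_nt < 1)
    stop("need window_nt >= step_nt >= 1")
  grid <- window_grid(pair$length, window_nt, step_nt)
  if (is.null(grid)) {
    warning("transcript ", pair$transcript, " shorter than step_nt (",
            pair$length, " < ", step_nt, "): no windows")
    return(data.frame(transcript = character(), start = integer(),
                      end = integer(), ip_rpkm = numeric(),
                      input_rpkm = numeric(), fold = numeric(),
                      gate_pass = logical(), enriched = logical()))
  }
  cs_ip <- c(0, cumsum(pair$ip))
  cs_in <- c(0, cumsum(pair$input))
  ip_sum <- cs_ip[grid[, "end"] + 1L] - cs_ip[grid[, "start"] + 1L]
  in_sum <- cs_in[grid[, "end"] + 1L] - cs_in[grid[, "start"] + 1L]
  w <- grid[, "end"] - grid[, "start"]
  ip_rpkm <- ip_sum / w * 1e9 / pair$ip_total
  input_rpkm <- in_sum / w * 1e9 / pair$input_total
  fold <- (ip_rpkm + pseudo_rpkm) / (input_rpkm + pseudo_rpkm)
  gate <- (ip_sum + in_sum) >= min_window_reads
  data.frame(transcript = pair$transcript, start = grid[, "start"],
             end = grid[, "end"], ip_rpkm = ip_rpkm,
             input_rpkm = input_rpkm, fold = fold, gate_pass = gate,
             enriched = gate & fold >= min_fold,
             stringsAsFactors = FALSE)
}

#' Merge enriched windows into peaks
#'
#' A window is enriched when it passes the coverage gate and its fold is at
#' least `min_fold` (inclusive, per the ">= fourfold" rule). Enriched windows
#' on the same transcript that overlap or are book-ended (gap <= 0) merge into
#' a single peak spanning their union; the peak score is the maximum member
#' fold.
#'
#' @param windows window table from [window_enrichment()] (one or more
#'   transcripts; must be sorted by start within transcript). A missing
#'   `gate_pass` column is treated as all-pass.
#' @param min_fold inclusive fold threshold.
#' @return data.frame of peaks: `transcript`, `start`, `end`, `score`,
#'   `n_windows`.
#' @export
call_peaks <- function(windows, min_fold = 4) {
  empty <- data.frame(transcript = character(), start = integer(),
                      end = integer(), score = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (is.null(windows) || nrow(windows) == 0) return(empty)
  gate <- if ("gate_pass" %in% names(windows)) windows$gate_pass else TRUE
  out <- list()
  for (tx in unique(windows$transcript)) {
    sel <- windows$transcript == tx
    w <- windows[sel, , drop = FALSE]
    if (is.unsorted(w$start))
      stop("windows unsorted on transcript ", tx)
    g <- if (length(gate) == 1) rep(gate, nrow(w)) else gate[sel]
    enr <- g & w$fold >= min_fold
    if (!any(enr)) next
    w <- w[enr, , drop = FALSE]
    cur_s <- w$start[1]; cur_e <- w$end[1]; cur_f <- w$fold[1]; cur_n <- 1L
    for (i in seq_len(nrow(w))[-1]) {
      if (w$start[i] <= cur_e) {          # overlapping or book-ended
        cur_e <- max(cur_e, w$end[i])
        cur_f <- max(cur_f, w$fold[i])
        cur_n <- cur_n + 1L
      } else {
        out[[length(out) + 1L]] <- data.frame(
          transcript = tx, start = cur_s, end = cur_e, score = cur_f,
          n_windows = cur_n, stringsAsFactors = FALSE)
        cur_s <- w$start[i]; cur_e <- w$end[i]; cur_f <- w$fold[i]
        cur_n <- 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      transcript = tx, start = cur_s, end = cur_e, score = cur_f,
      n_windows = cur_n, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-transcript m6A peak-coverage summary
#'
#' Summaries are computed over the union of the peak intervals, so they are
#' invariant to how that union is split into adjacent peaks: number of
#' distinct peak regions, total peak nucleotides, mean IP RPKM and mean
#' pseudocounted IP/input fold within the union. A transcript with no peaks
#' reports zeros.
#'
#' @param peaks peak table from [call_peaks()], restricted to this
#'   transcript's peaks (a foreign transcript id is an error).
#' @param pair the transcript's [coverage_pair()].
#' @param pseudo_rpkm pseudo-RPKM used for the fold.
#' @return One-row data.frame: `transcript`, `n_peaks`, `peak_nt`,
#'   `mean_ip_rpkm`, `mean_fold`.
#' @export
transcript_peak_coverage <- function(peaks, pair, pseudo_rpkm = 0.5) {
  stopifnot(inherits(pair, "coverage_pair"))
  if (!is.null(peaks) && nrow(peaks)) {
    foreign <- setdiff(unique(peaks$transcript), pair$transcript)
    if (length(foreign))
      stop("peaks on foreign transcript(s): ", paste(foreign, collapse = ", "))
  }
  mask <- logical(pair$length)
  if (!is.null(peaks) && nrow(peaks))
    for (i in seq_len(nrow(peaks)))
      mask[(peaks$start[i] + 1L):peaks$end[i]] <- TRUE
  if (!any(mask))
    return(data.frame(transcript = pair$transcript, n_peaks = 0L,
                      peak_nt = 0L, mean_ip_rpkm = 0, mean_fold = 0,
                      stringsAsFactors = FALSE))
  runs <- rle(mask)
  n_peaks <- sum(runs$values)
  peak_nt <- sum(mask)
  ip_rpkm <- mean(pair$ip[mask]) * 1e9 / pair$ip_total
  input_rpkm <- mean(pair$input[mask]) * 1e9 / pair$input_total
  data.frame(transcript = pair$transcript, n_peaks = n_peaks,
             peak_nt = peak_nt, mean_ip_rpkm = ip_rpkm,
             mean_fold = (ip_rpkm + pseudo_rpkm) / (input_rpkm + pseudo_rpkm),
             stringsAsFactors = FALSE)
}

#' Call peaks across a set of coverage pairs
#'
#' Convenience wrapper: window enrichment then merging for every transcript.
#'
#' @param pairs named list of [coverage_pair()] objects.
#' @param config a [pipeline_config()].
#' @return list with `windows` (all window records) and `peaks` (merged
#'   peaks across transcripts).
#' @export
call_peaks_all <- function(pairs, config = pipeline_config()) {
  wins <- lapply(pairs, function(p)
    suppressWarnings(window_enrichment(
      p, window_nt = config$window_nt, step_nt = config$step_nt,
      pseudo_rpkm = config$pseudo_rpkm,
      min_window_reads = config$min_window_reads,
      min_fold = config$min_fold)))
  wins <- do.call(rbind, wins)
  rownames(wins) <- NULL
  list(windows = wins, peaks = call_peaks(wins, min_fold = config$min_fold))
}
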