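# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package code.

# Mask-based peak caller: enumerate every window, paint enriched windows onto
# a per-nt mask, and read peaks off the contiguous runs.
oracle_call_peaks <- function(pair, window_nt = 100, step_nt = 50,
                              pseudo = 0.5, min_reads = 10, min_fold = 4) {
  len <- pair$length
  mask <- logical(len)
  recs <- NULL
  for (s in seq(0, max(len - 1, 0), by = step_nt)) {
    e <- min(s + window_nt, len)
    if (e - s < step_nt) next
    idx <- (s + 1):e
    ipr <- mean(pair$ip[idx]) * 1e9 / pair$ip_total
    inr <- mean(pair$input[idx]) * 1e9 / pair$input_total
    fold <- (ipr + pseudo) / (inr + pseudo)
    gate <- (sum(pair$ip[idx]) + sum(pair$input[idx])) >= min_reads
    if (gate && fold >= min_fold) {
      mask[idx] <- TRUE
      recs <- rbind(recs, c(s, e, fold))
    }
  }
  if (is.null(recs))
    return(data.frame(transcript = character(), start = integer(),
                      end = integer(), score = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- data.frame(transcript = pair$transcript,
                    start = starts[r$values], end = ends[r$values],
                    stringsAsFactors = FALSE)
  out$score <- vapply(seq_len(nrow(out)), function(i)
    max(recs[recs[, 1] >= out$start[i] & recs[, 2] <= out$end[i], 3]),
    numeric(1))
  out$n_windows <- vapply(seq_len(nrow(out)), function(i)
    sum(recs[, 1] >= out$start[i] & recs[, 2] <= out$end[i]), integer(1),
    USE.NAMES = FALSE)
  out
}

# Exhaustive hypergeometric upper tail by direct combinatorics.
oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Row-by-row DEG classifier following the stated threshold rules literally.
oracle_classify <- function(df, mode, lfc = 1, fc = 1.5, pcut = 0.05) {
  vapply(seq_len(nrow(df)), function(i) {
    if (mode == "log2fc") {
      if (df$log2fc[i] >= lfc) "up"
      else if (df$log2fc[i] <= -lfc) "down"
      else "ns"
    } else {
      fold <- 2^df$log2fc[i]
      p <- df$p[i]
      if (!is.na(p) && p < pcut && fold > fc) "up"
      else if (!is.na(p) && p < pcut && fold < 1 / fc) "down"
      else "ns"
    }
  }, character(1))
}

# Score called peaks against a planted truth table: a truth peak is recovered
# when an overlapping called peak has both boundaries within `slack` nt.
score_peak_recovery <- function(called, truth, slack = 50) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    p <- called[called$transcript == truth$transcript[i], , drop = FALSE]
    if (!nrow(p)) return(FALSE)
    ov <- p$start < truth$end[i] & p$end > truth$start[i]
    any(ov & abs(p$start - truth$start[i]) <= slack &
          abs(p$end - truth$end[i]) <= slack)
  }, logical(1))
  mean(hit)
}

expect_same_files <- function(a, b) {
  fa <- sort(list.files(a, full.names = TRUE))
  fb <- sort(list.files(b, full.names = TRUE))
  expect_equal(basename(fa), basename(fb))
  expect_equal(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
}
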