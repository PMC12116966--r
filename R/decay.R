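#' ERCC spike-in size factors
#'
#' Per-sample factor = (spike-in total of the sample) / (geometric mean of the
#' spike-in totals across samples). Dividing each sample by its factor
#' equalizes spike totals; the factors have geometric mean 1 and the operation
#' is idempotent. Spike-ins are added in fixed amount per unit RNA, so they
#' track library-scale distortions but not global mRNA decay — which is what
#' makes them the right anchor in an actinomycin-D chase.
#'
#' @param x a [count_matrix()] with at least one spike row, or a numeric
#'   matrix together with `spike`.
#' @param spike logical spike-row flags when `x` is a bare matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
spike_in_size_factors <- function(x, spike = NULL) {
  if (inherits(x, "count_matrix")) {
    spike <- x$spike
    x <- x$counts
  }
  if (is.null(spike) || !any(spike)) stop("no spike-in rows flagged")
  totals <- colSums(x[spike, , drop = FALSE])
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("zero spike-in total in sample(s): ", paste(zero, collapse = ", "))
  totals / exp(mean(log(totals)))
}

#' RUV-style removal of unwanted variation anchored on spike-ins
#'
#' Estimates unwanted factors as the top `k_factors` left singular vectors of
#' the gene-centred spike-in submatrix and subtracts their least-squares
#' contribution from every gene column. With orthonormal factors this is a
#' projection, so re-applying it changes nothing (up to numerical noise), and
#' it minimizes the residual spike variance over rank-`k_factors` corrections.
#'
#' @param log_counts samples x genes matrix on the log scale.
#' @param spike_mask logical, one entry per gene column.
#' @param k_factors number of factors to remove; 0 returns the input
#'   unchanged.
#' @return Adjusted samples x genes matrix.
#' @export
ruv_factor_removal <- function(log_counts, spike_mask, k_factors = 1) {
  if (!is.matrix(log_counts)) stop("`log_counts` must be a matrix")
  if (length(spike_mask) != ncol(log_counts))
    stop("`spike_mask` must flag each gene column")
  if (k_factors == 0) return(log_counts)
  n <- nrow(log_counts)
  if (k_factors >= n)
    stop("k_factors must be smaller than the number of samples")
  if (sum(spike_mask) < k_factors)
    stop("need at least k_factors spike-in genes")
  Z <- log_counts[, spike_mask, drop = FALSE]
  Zc <- sweep(Z, 2, colMeans(Z))
  sv <- svd(Zc)
  keep <- which(sv$d > max(sv$d[1], 1) * 1e-10)
  k <- min(k_factors, length(keep))
  if (k == 0) return(log_counts)
  W <- sv$u[, seq_len(k), drop = FALSE]
  Yc <- sweep(log_counts, 2, colMeans(log_counts))
  log_counts - W %*% (t(W) %*% Yc)
}

#' Fit first-order decay per gene
#'
#' Ordinary least squares of `ln(count + 0.5)` on time. The decay constant is
#' `k = max(0, -slope)` (actinomycin D precludes synthesis, so apparent gains
#' are treated as noise) and the half-life is `ln(2)/k`, infinite when
#' `k = 0`. Genes with all-zero counts are reported as missing (`NA` fit).
#'
#' @param counts gene x timepoint matrix of (normalized) counts; replicate
#'   samples should already be averaged per timepoint.
#' @param timepoints hours, same length as `ncol(counts)`; must contain 0 and
#'   at least two distinct values.
#' @return data.frame of class `decay_fits`: `gene`, `k` (1/h), `half_life`
#'   (h), `r2`, `n_points`.
#' @export
fit_decay <- function(counts, timepoints) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (length(timepoints) != ncol(counts))
    stop("timepoints must match the count columns")
  if (length(unique(timepoints)) < 2 || !0 %in% timepoints)
    stop("need >=2 distinct timepoints including 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  t0 <- timepoints - mean(timepoints)
  sxx <- sum(t0^2)
  y <- log(counts + 0.5)
  slope <- as.numeric(y %*% t0) / sxx
  ybar <- rowMeans(y)
  fitted <- outer(slope, t0) + ybar
  ss_res <- rowSums((y - fitted)^2)
  ss_tot <- rowSums((y - ybar)^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, 1 - ss_res / ss_tot), NA_real_)
  k <- pmax(0, -slope)
  hl <- ifelse(k > 0, log(2) / k, Inf)
  missing <- rowSums(counts) == 0
  k[missing] <- NA_real_; hl[missing] <- NA_real_; r2[missing] <- NA_real_
  out <- data.frame(gene = rownames(counts), k = k, half_life = hl, r2 = r2,
                    n_points = length(timepoints), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("decay_fits", "data.frame")
  out
}

#' @export
print.decay_fits <- function(x, ...) {
  ok <- !is.na(x$k)
  cat(sprintf("decay_fits: %d genes (%d fitted), median half-life %.2f h\n",
              nrow(x), sum(ok),
              stats::median(x$half_life[ok & is.finite(x$half_life)])))
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Estimate half-lives from an actinomycin-D chase count matrix
#'
#' Full decay pipeline: ERCC spike-in size factors, optional RUV-style
#' factor removal on the log scale, averaging of replicate samples within
#' each timepoint, then per-gene first-order fits with [fit_decay()].
#' Spike-in rows are excluded from the fits.
#'
#' @param cm a [count_matrix()] whose metadata carries `timepoint_h`, or a
#'   bare matrix with `timepoints` giving each sample's hour.
#' @param timepoints per-sample hours; defaults to `meta$timepoint_h`.
#' @param ruv_k unwanted-variation factors to remove (0 disables).
#' @param normalize set `FALSE` to skip spike-in normalization (used to
#'   demonstrate why the anchor is needed; not recommended for analysis).
#' @return `decay_fits` table with the size factors in
#'   `attr(, "size_factors")`.
#' @export
estimate_half_lives <- function(cm, timepoints = NULL, ruv_k = 0,
                                normalize = TRUE) {
  if (inherits(cm, "count_matrix")) {
    if (is.null(timepoints)) {
      if (is.null(cm$meta) || !"timepoint_h" %in% names(cm$meta))
        stop("no `timepoint_h` metadata; pass `timepoints`")
      timepoints <- cm$meta$timepoint_h
    }
    counts <- cm$counts
    spike <- cm$spike
  } else {
    counts <- cm
    spike <- grepl("^ERCC-", rownames(counts))
    if (is.null(timepoints)) stop("pass `timepoints` for a bare matrix")
  }
  sf <- spike_in_size_factors(counts, spike)
  norm <- if (normalize) sweep(counts, 2, sf, "/") else counts
  if (ruv_k > 0) {
    L <- t(log(norm + 0.5))
    L <- ruv_factor_removal(L, spike_mask = spike, k_factors = ruv_k)
    norm <- pmax(t(exp(L)) - 0.5, 0)
  }
  tps <- sort(unique(timepoints))
  avg <- vapply(tps, function(tp)
    rowMeans(norm[, timepoints == tp, drop = FALSE]), numeric(nrow(norm)))
  colnames(avg) <- paste0("t", tps, "h")
  fits <- fit_decay(avg[!spike, , drop = FALSE], tps)
  attr(fits, "size_factors") <- sf
  fits
}

#' Compare decay between conditions and call stabilized genes
#'
#' A gene is stabilized (degradation-inhibited) in the treatment when both
#' fits pass the quality gate (`r2 >= min_r2`, or a flat profile with
#' `k = 0`), the control actually decays (`k_ctrl > 0`), the treatment decays
#' more slowly (`k_trt < k_ctrl`), and the half-life ratio
#' `half_life_trt / half_life_ctrl = k_ctrl / k_trt` is at least `ratio_cut`.
#' The table is sorted by half-life ratio, descending.
#'
#' @param fits_ctrl,fits_trt `decay_fits` tables sharing gene ids.
#' @param ratio_cut minimum half-life ratio (treatment over control).
#' @param min_r2 fit-quality gate.
#' @return data.frame: `gene`, `k_ctrl`, `k_trt`, `hl_ratio`, `stabilized`.
#' @export
compare_stability <- function(fits_ctrl, fits_trt, ratio_cut = 1.5,
                              min_r2 = 0.5) {
  shared <- intersect(fits_ctrl$gene, fits_trt$gene)
  if (!length(shared)) stop("no shared genes between the fit tables")
  a <- fits_ctrl[match(shared, fits_ctrl$gene), ]
  b <- fits_trt[match(shared, fits_trt$gene), ]
  gate <- function(f) !is.na(f$k) & (f$k == 0 | (!is.na(f$r2) & f$r2 >= min_r2))
  hl_ratio <- ifelse(!is.na(a$k) & !is.na(b$k),
                     ifelse(b$k == 0,
                            ifelse(a$k == 0, 1, Inf),
                            a$k / b$k),
                     NA_real_)
  stabilized <- gate(a) & gate(b) & !is.na(hl_ratio) &
    a$k > 0 & b$k < a$k & hl_ratio >= ratio_cut
  out <- data.frame(gene = shared, k_ctrl = a$k, k_trt = b$k,
                    hl_ratio = hl_ratio, stabilized = stabilized,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hl_ratio), ]
  rownames(out) <- NULL
  out
}
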