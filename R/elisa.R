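#' Fit an m6A-ELISA standard curve
#'
#' Ordinary least squares of optical density on the amount of m6A positive
#' control per well (the kit's standard range is 0.02-0.4 ng/well):
#' `OD = slope * ng + intercept`. A non-positive slope means the colorimetric
#' reaction failed and is an error.
#'
#' @param ng amounts of positive control per well (ng); at least two distinct
#'   values.
#' @param od measured optical densities, same length.
#' @return Object of class `standard_curve`: `slope` (OD per ng),
#'   `intercept` (OD), `r2`, `n`.
#' @export
fit_standard_curve <- function(ng, od) {
  if (length(ng) != length(od)) stop("ng and od must have equal length")
  if (length(unique(ng)) < 2)
    stop("standard curve needs >= 2 distinct amounts")
  fit <- stats::lm(od ~ ng)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("failed assay: standard curve slope is not positive")
  res <- stats::residuals(fit)
  ss_tot <- sum((od - mean(od))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n = length(ng)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("m6A standard curve: OD = %.4f * ng + %.4f (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Convert sample ODs to m6A percentage of input mRNA
#'
#' Inverts the standard curve to an m6A amount,
#' `amount_ng = (OD - intercept) / slope`, floors negative amounts at zero
#' (flagged below detection), and applies
#' `m6A% = (m6A amount / input mRNA amount) * 100`.
#'
#' @param od_sample optical density (vectorized).
#' @param curve a [fit_standard_curve()] result.
#' @param input_ng input mRNA immobilized per well (ng, default 200).
#' @return data.frame: `od`, `amount_ng`, `m6a_percent`, `below_detection`.
#' @export
m6a_percent <- function(od_sample, curve, input_ng = 200) {
  stopifnot(inherits(curve, "standard_curve"))
  if (input_ng <= 0) stop("input_ng must be > 0")
  amount <- (od_sample - curve$intercept) / curve$slope
  below <- amount < 0
  amount <- pmax(amount, 0)
  data.frame(od = od_sample, amount_ng = amount,
             m6a_percent = amount / input_ng * 100,
             below_detection = below)
}
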