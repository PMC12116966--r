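#' Pipeline configuration
#'
#' Central defaults for every stage. Window geometry and the fold threshold
#' follow the sliding-window m6A caller (100-nt windows, 50-nt step, >= 4-fold
#' IP/input enrichment, inclusive); DEG thresholds carry both published rules
#' (log2 fold-change >= 1; fold change > 1.5 with P < 0.05); the decay design
#' is the 0/4/8 h actinomycin-D chase; clustering defaults to nine fuzzy
#' c-means clusters with fuzzifier 2.
#'
#' @param window_nt sliding window width, nt.
#' @param step_nt window step, nt; must satisfy `window_nt >= step_nt >= 1`.
#' @param min_fold minimum IP/input fold enrichment (inclusive) for an
#'   enriched window.
#' @param pseudo_rpkm symmetric pseudo-RPKM added to IP and input before the
#'   ratio.
#' @param min_window_reads minimum raw IP+input read-equivalents for a window
#'   to be eligible.
#' @param decay_timepoints actinomycin-D chase timepoints, hours.
#' @param deg_lfc_cut log2 fold-change cut for `log2fc`-mode DEG calls.
#' @param deg_fc_cut,deg_p_cut fold-change and p-value cuts for `fc_p`-mode
#'   DEG calls.
#' @param cluster_count number of fuzzy c-means clusters.
#' @param fuzzifier fuzzy c-means fuzzifier m (> 1).
#' @param ratio_cut,min_r2 half-life ratio and fit-quality gates for
#'   stabilization calls.
#' @param ruv_k number of unwanted-variation factors removed before decay
#'   fitting.
#' @param n_top_variable genes kept for the PCA trajectory.
#' @param seed default random seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_nt = 100, step_nt = 50, min_fold = 4,
                            pseudo_rpkm = 0.5, min_window_reads = 10,
                            decay_timepoints = c(0, 4, 8),
                            deg_lfc_cut = 1, deg_fc_cut = 1.5,
                            deg_p_cut = 0.05, cluster_count = 9,
                            fuzzifier = 2, ratio_cut = 1.5, min_r2 = 0.5,
                            ruv_k = 1, n_top_variable = 500, seed = 1) {
  cfg <- list(window_nt = window_nt, step_nt = step_nt, min_fold = min_fold,
              pseudo_rpkm = pseudo_rpkm, min_window_reads = min_window_reads,
              decay_timepoints = decay_timepoints, deg_lfc_cut = deg_lfc_cut,
              deg_fc_cut = deg_fc_cut, deg_p_cut = deg_p_cut,
              cluster_count = cluster_count, fuzzifier = fuzzifier,
              ratio_cut = ratio_cut, min_r2 = min_r2, ruv_k = ruv_k,
              n_top_variable = n_top_variable, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(window_nt >= step_nt && step_nt >= 1))
      stop("need window_nt >= step_nt >= 1")
    if (min_fold <= 0) stop("min_fold must be > 0")
    if (pseudo_rpkm < 0) stop("pseudo_rpkm must be >= 0")
    if (any(c(deg_lfc_cut, deg_fc_cut, deg_p_cut) <= 0))
      stop("DEG cuts must be > 0")
    if (cluster_count < 1) stop("cluster_count must be >= 1")
    if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  })
  invisible(cfg)
}

#' Read a YAML configuration, merged over the built-in defaults
#'
#' Precedence is CLI flag > config file > built-in default; this function
#' implements the file-over-default layer. Unknown keys are an error.
#'
#' @param path YAML file of configuration overrides.
#' @param base configuration to merge onto (default [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, base = pipeline_config()) {
  over <- yaml::read_yaml(path)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(over)) base[[k]] <- over[[k]]
  validate_config(base)
  structure(base, class = "pipeline_config")
}
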