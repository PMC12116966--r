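#' Default temporal expression templates
#'
#' Nine relative-expression trajectories over a three-timepoint course
#' (arbitrary units): monotone rises and falls of two steepnesses, transient
#' peaks/dips, and early/late switches. They play the role of cluster mean
#' trajectories when planting ground-truth structure. Amplitudes are chosen
#' so the set is time-balanced (per-timepoint template totals are equal), so
#' a library built from all nine keeps a constant expected size over the
#' course.
#'
#' @return Named list of length-3 numeric templates.
#' @export
default_timecourse_patterns <- function() {
  list(rise_steep      = c(0.587, 1.761, 5.283),
       rise_gentle     = c(1.814, 2.721, 4.082),
       fall_steep      = c(9.216, 3.072, 1.024),
       fall_gentle     = c(4.698, 3.132, 2.088),
       transient_up    = c(1.485, 8.910, 1.485),
       transient_down  = c(3.090, 0.515, 3.090),
       early_rise      = c(1.047, 5.235, 5.758),
       late_rise       = c(0.716, 0.859, 3.580),
       early_fall      = c(4.675, 1.122, 0.935))
}

normalize_patterns <- function(patterns) {
  if (is.null(names(patterns)))
    names(patterns) <- paste0("pattern_", seq_along(patterns))
  for (nm in names(patterns)) {
    p <- patterns[[nm]]
    if (!is.numeric(p) || !any(p != 0) || any(p < 0))
      stop("pattern '", nm, "' must be non-negative with a nonzero entry")
  }
  patterns
}

#' Simulate a time-course count matrix with planted cluster patterns
#'
#' Genes are assigned to temporal patterns (templates of relative expression
#' per timepoint); expected counts are the templates scaled by a single
#' global factor chosen so the mean expected library size equals `depth`
#' (exactly `depth` at every timepoint when the pattern set is
#' time-balanced, as the defaults are), and counts are drawn from a
#' negative binomial with the given dispersion (Poisson when
#' `dispersion = 0`). Conditions and replicates replicate the same design,
#' emulating a days-3/5/7 course with two biological replicates per
#' condition. The same seed reproduces the output exactly.
#'
#' @param patterns named list of templates, one value per timepoint (see
#'   [default_timecourse_patterns()]).
#' @param genes_per_pattern genes planted per pattern.
#' @param timepoints timepoint labels (hours or days), one per template
#'   entry.
#' @param conditions condition labels.
#' @param replicates biological replicates per condition/timepoint.
#' @param depth expected library size per sample.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 means Poisson.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()] with `condition`,
#'   `timepoint_h`, `replicate` metadata) and `truth` (data.frame `gene`,
#'   `pattern_id`).
#' @export
simulate_timecourse_counts <- function(patterns = default_timecourse_patterns(),
                                       genes_per_pattern = 50,
                                       timepoints = c(3, 5, 7),
                                       conditions = c("NC", "STM2457"),
                                       replicates = 2,
                                       depth = 1e6, dispersion = 0.05,
                                       seed = NULL) {
  if (!length(patterns)) stop("need at least one pattern")
  patterns <- normalize_patterns(patterns)
  bad <- names(patterns)[vapply(patterns, length, 1L) != length(timepoints)]
  if (length(bad))
    stop("template length must match timepoints for pattern(s): ",
         paste(bad, collapse = ", "))
  if (depth <= 0) stop("depth must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  genes <- unlist(lapply(names(patterns), function(nm)
    paste0(nm, "_g", seq_len(genes_per_pattern))))
  truth <- data.frame(gene = genes,
                      pattern_id = rep(names(patterns),
                                       each = genes_per_pattern),
                      stringsAsFactors = FALSE)
  tmpl <- do.call(rbind, lapply(patterns, function(p)
    matrix(rep(p, each = genes_per_pattern), genes_per_pattern,
           length(timepoints))))
  meta <- expand.grid(replicate = seq_len(replicates),
                      timepoint_h = timepoints, condition = conditions,
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_t%g_r%d", meta$condition, meta$timepoint_h,
                         meta$replicate)
  meta <- meta[, c("sample", "condition", "timepoint_h", "replicate")]
  counts <- matrix(0, nrow(tmpl), nrow(meta),
                   dimnames = list(genes, meta$sample))
  # one global scale so planted shapes survive untouched; with a
  # time-balanced pattern set the expected library size is exactly `depth`
  scale_total <- sum(rowMeans(tmpl))
  for (s in seq_len(nrow(meta))) {
    ti <- match(meta$timepoint_h[s], timepoints)
    mu <- depth * tmpl[, ti] / scale_total
    counts[, s] <- if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  list(counts = count_matrix(counts, meta = meta), truth = truth)
}

#' Simulate an actinomycin-D decay experiment with ERCC spike-ins
#'
#' Gene expected counts follow first-order decay,
#' `baseline * 2^(-t / half_life)`, multiplied by a per-sample library-scale
#' distortion; spike-in expected counts are constant per sample (they are
#' added per unit RNA and do not decay) times the same distortion. Counts are
#' Poisson. One sample per timepoint.
#'
#' @param truths data.frame with `gene`, `half_life` (hours, may be `Inf`)
#'   and `baseline` (> 0 expected count at t = 0).
#' @param timepoints chase timepoints in hours; must include 0.
#' @param spike_defs named vector of spike-in expected counts; names must
#'   carry the `"ERCC-"` prefix.
#' @param scale_distortion per-sample multiplier, one per timepoint.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()], spike rows flagged) and
#'   `truth` (the input table).
#' @export
simulate_decay_experiment <- function(truths, timepoints = c(0, 4, 8),
                                      spike_defs = default_spike_defs(),
                                      scale_distortion = rep(1, length(timepoints)),
                                      seed = NULL) {
  truths <- as.data.frame(truths)
  stopifnot(all(c("gene", "half_life", "baseline") %in% names(truths)))
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (any(truths$half_life <= 0)) stop("half_life must be > 0")
  if (any(truths$baseline <= 0)) stop("baseline must be > 0")
  if (length(scale_distortion) != length(timepoints))
    stop("scale_distortion must have one entry per sample")
  if (any(scale_distortion <= 0)) stop("distortion must be > 0")
  if (!length(spike_defs)) stop("spike_defs must be non-empty")
  if (is.null(names(spike_defs)) || !all(grepl("^ERCC-", names(spike_defs))))
    stop("spike_defs names must carry the 'ERCC-' prefix")
  if (!is.null(seed)) set.seed(seed)
  samples <- paste0("t", timepoints, "h")
  mu_gene <- outer(seq_len(nrow(truths)), seq_along(timepoints),
                   function(i, j) truths$baseline[i] *
                     2^(-timepoints[j] / truths$half_life[i]) *
                     scale_distortion[j])
  mu_spike <- outer(spike_defs, scale_distortion)
  mu <- rbind(mu_gene, mu_spike)
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                   dimnames = list(c(truths$gene, names(spike_defs)),
                                   samples))
  meta <- data.frame(sample = samples, condition = "ActD",
                     timepoint_h = timepoints,
                     replicate = 1L, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, meta = meta), truth = truths)
}

#' Default ERCC-like spike-in definition
#'
#' Twenty synthetic spike-ins with expected counts spanning ~50-5000,
#' geometrically spaced — enough dynamic range for stable size factors.
#'
#' @return Named numeric vector of expected counts.
#' @export
default_spike_defs <- function() {
  stats::setNames(round(50 * (5000 / 50)^(seq(0, 1, length.out = 20))),
                  sprintf("ERCC-%05d", seq_len(20)))
}

#' Simulate paired MeRIP IP/input coverage with planted peaks
#'
#' Input depth is Poisson(`background_depth`) per nucleotide; IP depth is
#' Poisson with the same mean outside planted peaks and
#' `background_depth * enrichment` inside them. Library totals are the summed
#' depths over all transcripts per library. The planted table is the ground
#' truth against which called peaks are scored.
#'
#' @param transcript_lengths named vector of transcript lengths (nt).
#' @param planted data.frame `transcript`, `start`, `end` (0-based
#'   half-open), `enrichment` (>= 1); may be empty.
#' @param background_depth mean background reads per nt (> 0).
#' @param seed integer seed.
#' @return list with `pairs` (named list of [coverage_pair()], library-wide
#'   totals) and `truth` (the planted table).
#' @export
simulate_merip_coverage <- function(transcript_lengths, planted = NULL,
                                    background_depth = 30, seed = NULL) {
  if (background_depth <= 0) stop("background_depth must be > 0")
  if (is.null(planted))
    planted <- data.frame(transcript = character(), start = integer(),
                          end = integer(), enrichment = numeric())
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    if (any(!planted$transcript %in% names(transcript_lengths)))
      stop("planted peak on unknown transcript")
    len <- transcript_lengths[planted$transcript]
    if (any(planted$start < 0 | planted$end <= planted$start |
            planted$end > len))
      stop("planted peak outside its transcript")
    if (any(planted$enrichment < 1)) stop("enrichment must be >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  ip <- list(); input <- list()
  for (tx in names(transcript_lengths)) {
    n <- transcript_lengths[[tx]]
    mu_ip <- rep(background_depth, n)
    rows <- which(planted$transcript == tx)
    for (i in rows)
      mu_ip[(planted$start[i] + 1L):planted$end[i]] <-
        background_depth * planted$enrichment[i]
    input[[tx]] <- stats::rpois(n, background_depth)
    ip[[tx]] <- stats::rpois(n, mu_ip)
  }
  ip_total <- sum(vapply(ip, sum, numeric(1)))
  input_total <- sum(vapply(input, sum, numeric(1)))
  pairs <- lapply(names(transcript_lengths), function(tx)
    coverage_pair(tx, ip[[tx]], input[[tx]],
                  ip_total = ip_total, input_total = input_total))
  list(pairs = stats::setNames(pairs, names(transcript_lengths)),
       truth = planted)
}

#' Write a planted-peak truth table as BED
#'
#' Sidecar serialization of the ground truth: BED-style 0-based half-open
#' rows with the planted fold enrichment in the score column.
#'
#' @param truth planted table from [simulate_merip_coverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# transcript\tstart\tend\tname\tenrichment\tstrand", con,
             sep = "\n")
  if (nrow(truth))
    writeLines(sprintf("%s\t%d\t%d\ttruth_%d\t%s\t+",
                       truth$transcript, as.integer(truth$start),
                       as.integer(truth$end), seq_len(nrow(truth)),
                       format(truth$enrichment, digits = 15, trim = TRUE)),
               con, sep = "\n")
  invisible(path)
}
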