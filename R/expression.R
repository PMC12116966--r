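#' Drop genes with negligible total counts
#'
#' Keeps exactly the rows whose total count across samples is greater than 1;
#' row order is preserved. Warns when nothing survives.
#'
#' @param x a [count_matrix()] or numeric matrix.
#' @return Object of the same kind, restricted to the retained genes.
#' @export
filter_low_expression <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  keep <- rowSums(counts) > 1
  if (!any(keep)) warning("no genes pass the low-expression filter")
  if (inherits(x, "count_matrix")) subset_genes(x, keep)
  else x[keep, , drop = FALSE]
}

#' Median-of-ratios size factors and normalization
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the gene's count
#' to its geometric mean across samples; normalized counts are the raw counts
#' divided by the sample's factor.
#'
#' @param counts numeric gene x sample matrix (or [count_matrix()]).
#' @return list with `normalized` (matrix) and `size_factors`.
#' @export
median_of_ratios_normalize <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in every sample")
  geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE] / geo, 2, stats::median)
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

# Vectorized two-sided Welch t-test on the rows of two matrices.
welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) return(rep(NA_real_, nrow(a)))
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- NA_real_            # both groups constant: untestable
  p
}

#' Differential expression between two sample groups
#'
#' Log2 fold change is `log2((meanB + 1) / (meanA + 1))` on normalized counts;
#' p-values come from a two-sided Welch t-test on `log2(norm + 1)` (requires
#' two samples per group; otherwise classification is fold-change-only), and
#' `padj` is Benjamini-Hochberg over the tested genes. With duplicate-level
#' replication the test is severely underpowered; the returned table carries a
#' `note` attribute saying so, and writers emit it as a header comment.
#'
#' @param norm_counts normalized gene x sample matrix.
#' @param group_a,group_b column names (or indices) of the two groups
#'   (control, treatment); must not overlap.
#' @return data.frame: `gene`, `mean_a`, `mean_b`, `log2fc`, `p`, `padj`.
#' @export
differential_expression <- function(norm_counts, group_a, group_b) {
  if (inherits(norm_counts, "count_matrix")) norm_counts <- norm_counts$counts
  if (is.character(group_a)) group_a <- match(group_a, colnames(norm_counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(norm_counts))
  if (anyNA(group_a) || anyNA(group_b)) stop("unknown sample name in groups")
  if (length(intersect(group_a, group_b)))
    stop("groups must not share samples")
  a <- norm_counts[, group_a, drop = FALSE]
  b <- norm_counts[, group_b, drop = FALSE]
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  log2fc <- log2((mean_b + 1) / (mean_a + 1))
  p <- welch_p(log2(a + 1), log2(b + 1))
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(gene = rownames(norm_counts), mean_a = mean_a,
                    mean_b = mean_b, log2fc = log2fc, p = p, padj = padj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (min(length(group_a), length(group_b)) <= 2)
    attr(out, "note") <-
      "p-values from n<=2 replicates per group are low-power"
  out
}

#' Classify genes as up/down/ns under either published threshold rule
#'
#' Mode `"log2fc"`: up when `log2fc >= lfc_cut` (inclusive), down when
#' `log2fc <= -lfc_cut`. Mode `"fc_p"`: up when the fold change is strictly
#' greater than `fc_cut` and `p < p_cut`; down symmetrically
#' (fold `< 1/fc_cut`). A fold of exactly `fc_cut` is not significant.
#'
#' @param table DEG table from [differential_expression()].
#' @param mode `"log2fc"` or `"fc_p"`.
#' @param lfc_cut,fc_cut,p_cut thresholds.
#' @return The table with a `klass` column (`up`, `down`, `ns`).
#' @export
classify_deg <- function(table, mode = c("log2fc", "fc_p"), lfc_cut = 1,
                         fc_cut = 1.5, p_cut = 0.05) {
  mode <- match.arg(mode)
  klass <- rep("ns", nrow(table))
  if (mode == "log2fc") {
    klass[table$log2fc >= lfc_cut] <- "up"
    klass[table$log2fc <= -lfc_cut] <- "down"
  } else {
    if (!"p" %in% names(table) || all(is.na(table$p)))
      stop("mode 'fc_p' needs p-values")
    fold <- 2^table$log2fc
    sig <- !is.na(table$p) & table$p < p_cut
    klass[sig & fold > fc_cut] <- "up"
    klass[sig & fold < 1 / fc_cut] <- "down"
  }
  table$klass <- klass
  table
}

#' Venn partition of 2-4 named gene sets
#'
#' Counts every region of the Venn partition (elements belonging to exactly
#' that combination of sets) and returns the genes common to all sets.
#'
#' @param sets named list of 2-4 character vectors.
#' @return list with `regions` (data.frame `region`, `count`) and `common`
#'   (character vector of the full intersection).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4)
    stop("overlap_sets handles 2-4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  region <- apply(combos, 1, function(z)
    paste(names(sets)[as.logical(z)], collapse = "&"))
  count <- apply(combos, 1, function(z)
    if (length(universe) == 0) 0L
    else sum(apply(member, 1, function(m) all(m == as.logical(z)))))
  common <- Reduce(intersect, sets)
  list(regions = data.frame(region = region, count = as.integer(count),
                            stringsAsFactors = FALSE),
       common = common)
}

#' PCA trajectory of samples
#'
#' Transforms normalized counts as `log2(norm + 1)`, restricts to the
#' `n_top_variable` most variable genes, gene-centres, and runs PCA on the
#' samples. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive so results do not flip between
#' runs.
#'
#' @param norm_counts normalized gene x sample matrix (>= 3 samples,
#'   >= 2 genes).
#' @param n_top_variable genes kept, by decreasing variance.
#' @return list with `coordinates` (data.frame, samples x PCs),
#'   `var_explained` (fractions, non-increasing) and `loadings`.
#' @export
pca_trajectory <- function(norm_counts, n_top_variable = 500) {
  if (inherits(norm_counts, "count_matrix")) norm_counts <- norm_counts$counts
  if (ncol(norm_counts) < 3) stop("PCA trajectory needs >= 3 samples")
  if (nrow(norm_counts) < 2) stop("need >= 2 genes")
  y <- log2(norm_counts + 1)
  v <- apply(y, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_variable, nrow(y)))]
  yc <- y[keep, , drop = FALSE] - rowMeans(y[keep, , drop = FALSE])
  pc <- stats::prcomp(t(yc), center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.frame(sample = colnames(norm_counts), pc$x,
                       stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  list(coordinates = coords, var_explained = var_frac,
       loadings = pc$rotation)
}

#' Standardize temporal profiles per gene
#'
#' Centres and scales each row to mean 0, sd 1 across timepoints, dropping
#' zero-variance rows (they carry no temporal shape and would break the
#' clustering distance).
#'
#' @param mat gene x timepoint matrix.
#' @return Standardized matrix, possibly with fewer rows.
#' @export
standardize_profiles <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  s <- apply(mat, 1, stats::sd)
  keep <- s > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance profile(s) dropped")
  mat <- mat[keep, , drop = FALSE]
  (mat - rowMeans(mat)) / apply(mat, 1, stats::sd)
}

#' Fuzzy c-means clustering of standardized profiles
#'
#' Standard fuzzy c-means: memberships `u_ij` proportional to
#' `dist(x_i, c_j)^(-2/(m-1))`, centroids the `u^m`-weighted means, iterated
#' until the objective `sum u^m d^2` changes by less than `tol` or `max_iter`
#' is reached. Memberships rows sum to 1; the same seed reproduces the same
#' model; hard labels are the argmax membership with ties going to the lowest
#' cluster index. Zero-variance profiles must be removed beforehand (see
#' [standardize_profiles()]).
#'
#' @param x gene x timepoint matrix of standardized profiles.
#' @param centers number of clusters c (1 <= c <= genes).
#' @param fuzzifier fuzzifier m > 1.
#' @param seed integer seed for the random membership initialization.
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @return Object of class `fuzzy_cmeans`: `centroids` (c x T),
#'   `membership` (G x c), `objective`, `objective_trace`, `hard_labels`,
#'   `iterations`, `converged`, `fuzzifier`, `seed`.
#' @export
fuzzy_cmeans <- function(x, centers, fuzzifier = 2, seed = NULL,
                         tol = 1e-6, max_iter = 500) {
  if (is.data.frame(x)) x <- as.matrix(x)
  G <- nrow(x)
  if (centers > G) stop("more clusters than genes")
  if (centers < 1) stop("centers must be >= 1")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (any(apply(x, 1, stats::sd) == 0))
    stop("zero-variance profile present; standardize and filter first")
  if (!is.null(seed)) set.seed(seed)
  U <- matrix(stats::runif(G * centers), G, centers)
  U <- U / rowSums(U)
  m <- fuzzifier
  obj_trace <- numeric(0)
  obj_old <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    Um <- U^m
    C <- (t(Um) %*% x) / colSums(Um)
    # squared Euclidean distances gene x cluster
    D2 <- outer(rowSums(x^2), rep(1, centers)) +
      outer(rep(1, G), rowSums(C^2)) - 2 * x %*% t(C)
    D2[D2 < 0] <- 0
    obj <- sum(Um * D2)
    obj_trace <- c(obj_trace, obj)
    if (abs(obj_old - obj) < tol) { converged <- TRUE; break }
    obj_old <- obj
    W <- D2^(-1 / (m - 1))
    zero <- D2 <= .Machine$double.eps
    hit <- rowSums(zero) > 0
    U <- W / rowSums(W)
    if (any(hit)) {
      U[hit, ] <- 0
      U[cbind(which(hit), max.col(-D2[hit, , drop = FALSE],
                                  ties.method = "first"))] <- 1
    }
  }
  hard <- max.col(U, ties.method = "first")
  rownames(U) <- rownames(x)
  rownames(C) <- paste0("cluster_", seq_len(centers))
  colnames(U) <- rownames(C)
  structure(list(centroids = C, membership = U, objective = obj_trace[it],
                 objective_trace = obj_trace, hard_labels = hard,
                 iterations = it, converged = converged, fuzzifier = m,
                 seed = seed),
            class = "fuzzy_cmeans")
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf(paste0("fuzzy c-means: %d clusters, %d genes, m = %g, ",
                     "objective %.6g (%d iterations%s)\n"),
              nrow(x$centroids), nrow(x$membership), x$fuzzifier,
              x$objective, x$iterations,
              if (x$converged) "" else ", not converged"))
  cat("cluster sizes (hard labels):",
      paste(tabulate(x$hard_labels, nbins = nrow(x$centroids)),
            collapse = " "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions; 1 means identical
#' partitions, 0 is the expectation under independent random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}
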