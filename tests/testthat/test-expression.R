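test_that("low-expression filter keeps exactly rows with total count > 1", {
  m <- matrix(c(0, 0, 1, 0, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  kept <- filter_low_expression(m)
  expect_equal(rownames(kept), "c")
  expect_warning(filter_low_expression(m * 0), "no genes pass")
  # integer equivalence with a brute-force sum >= 2 scan
  set.seed(5)
  big <- matrix(rpois(600, 0.6), 200, 3,
                dimnames = list(paste0("g", 1:200), NULL))
  expect_equal(nrow(filter_low_expression(big)), sum(rowSums(big) >= 2))
})

test_that("median-of-ratios size factors follow their closed form", {
  m <- matrix(rpois(40, 50) + 1, 20, 2,
              dimnames = list(paste0("g", 1:20), c("a", "b")))
  same <- median_of_ratios_normalize(cbind(a = m[, 1], b = m[, 1]))
  expect_equal(unname(same$size_factors), c(1, 1))
  # sample b = 3 x sample a
  tripled <- median_of_ratios_normalize(cbind(a = m[, 1], b = 3 * m[, 1]))
  expect_equal(tripled$size_factors[["b"]] / tripled$size_factors[["a"]], 3)
  expect_equal(tripled$normalized[, "a"] / tripled$normalized[, "b"],
               setNames(rep(1, 20), rownames(m)), tolerance = 1e-12)
  # genes zero in any sample are excluded from factor estimation
  with0 <- rbind(m, z = c(0, 100))
  expect_equal(median_of_ratios_normalize(with0)$size_factors,
               median_of_ratios_normalize(m)$size_factors)
  expect_error(median_of_ratios_normalize(
    matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), NULL))),
    "no gene has nonzero")
})

test_that("differential expression reproduces fold-change and BH arithmetic", {
  m <- matrix(c(100, 100, 900, 900,
                50, 50, 50, 50), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  deg <- differential_expression(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(deg$log2fc[1], log2(901 / 101), tolerance = 1e-12)
  expect_equal(deg$log2fc[2], 0)
  # identical groups give log2fc 0 everywhere
  deg0 <- differential_expression(cbind(m, m), c(1, 2), c(5, 6))
  expect_equal(deg0$log2fc, c(0, 0))
  expect_error(differential_expression(m, c("a1", "b1"), c("b1", "b2")),
               "share samples")
  # BH closed form on three p-values
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # Welch p agrees with stats::t.test on log scale
  set.seed(9)
  mm <- matrix(rpois(4 * 30, 100), 30, 4,
               dimnames = list(paste0("g", 1:30), c("a1", "a2", "b1", "b2")))
  dd <- differential_expression(mm, c("a1", "a2"), c("b1", "b2"))
  for (i in c(1, 7, 20)) {
    ref <- t.test(log2(mm[i, 1:2] + 1), log2(mm[i, 3:4] + 1))$p.value
    expect_equal(dd$p[i], ref, tolerance = 1e-12)
  }
  expect_match(attr(dd, "note"), "low-power")
})

test_that("DEG classification honours both rules including boundary cases", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    log2fc = c(1, -1, 0, log2(1.5), 2, -2),
                    p = c(0.01, 0.01, 0.01, 0.01, 0.2, 0.04))
  lf <- classify_deg(tab, "log2fc")
  expect_equal(lf$klass, c("up", "down", "ns", "ns", "up", "down"))
  fp <- classify_deg(tab, "fc_p")
  # fold exactly 1.5 with small p is ns (strict >); p 0.2 blocks the call
  expect_equal(fp$klass, c("up", "down", "ns", "ns", "ns", "down"))
  expect_error(classify_deg(tab[, 1:2], "fc_p"), "needs p-values")
  expect_error(classify_deg(tab, "nope"))
  # brute-force equivalence on random tables under both modes
  set.seed(33)
  for (mode in c("log2fc", "fc_p")) {
    rnd <- data.frame(gene = paste0("r", 1:300),
                      log2fc = round(runif(300, -3, 3), 2),
                      p = round(runif(300), 3))
    rnd$log2fc[1:10] <- c(1, -1, log2(1.5), -log2(1.5), 0, 1, -1, 2, -2, 0.99)
    got <- classify_deg(rnd, mode)$klass
    expect_identical(got, oracle_classify(rnd, mode))
  }
})

test_that("Venn partition counts match set enumeration", {
  r <- overlap_sets(list(X = c("A", "B", "C"), Y = c("B", "C", "D"),
                         Z = "C"))
  expect_equal(r$common, "C")
  get <- function(region) r$regions$count[r$regions$region == region]
  expect_equal(get("X&Y&Z"), 1L)   # C
  expect_equal(get("X&Y"), 1L)     # B
  expect_equal(get("X"), 1L)       # A
  expect_equal(get("Y"), 1L)       # D
  expect_equal(get("Z"), 0L)
  # identical sets: everything in the full intersection
  ident <- overlap_sets(list(a = c("x", "y"), b = c("x", "y"),
                             c = c("x", "y")))
  expect_equal(ident$regions$count[ident$regions$region == "a&b&c"], 2L)
  expect_equal(sum(ident$regions$count), 2L)
  # disjoint sets: zero in every multi-set region
  dis <- overlap_sets(list(a = "p", b = "q"))
  expect_equal(dis$regions$count[dis$regions$region == "a&b"], 0L)
  expect_error(overlap_sets(list(a = "x")), "2-4")
  expect_error(overlap_sets(list("x", "y")), "named")
})

test_that("PCA trajectory is deterministic in sign and ordered by variance", {
  set.seed(12)
  m <- matrix(rpois(50 * 6, 60), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  m[1:20, 4:6] <- m[1:20, 4:6] * 6  # planted group separation
  pc <- pca_trajectory(m, n_top_variable = 30)
  expect_true(all(diff(pc$var_explained) < 1e-12))
  # PC1 separates the planted groups with margin
  pc1 <- pc$coordinates$PC1
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) || min(pc1[1:3]) > max(pc1[4:6]))
  # duplicated sample lands on identical coordinates
  m2 <- cbind(m, s7 = m[, 6])
  pc2 <- pca_trajectory(m2, n_top_variable = 30)
  expect_equal(unlist(pc2$coordinates[7, -1]), unlist(pc2$coordinates[6, -1]),
               tolerance = 1e-9)
  # permutation invariance to gene order
  perm <- sample(nrow(m))
  pc3 <- pca_trajectory(m[perm, ], n_top_variable = 30)
  expect_equal(pc3$coordinates$PC1, pc$coordinates$PC1, tolerance = 1e-9)
  expect_error(pca_trajectory(m[, 1:2]), ">= 3 samples")
})

test_that("fuzzy c-means respects membership, objective and tie semantics", {
  set.seed(2)
  x <- standardize_profiles(matrix(rnorm(40 * 4), 40, 4,
                                   dimnames = list(paste0("g", 1:40), NULL)))
  m <- fuzzy_cmeans(x, 3, seed = 4)
  expect_equal(unname(rowSums(m$membership)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(diff(m$objective_trace) <= 1e-9))
  expect_true(m$converged)
  # same seed, same model
  m2 <- fuzzy_cmeans(x, 3, seed = 4)
  expect_identical(m$membership, m2$membership)
  # c = 1: trivial model, centroid is the column mean
  m1 <- fuzzy_cmeans(x, 1, seed = 1)
  expect_equal(unname(m1$membership[, 1]), rep(1, 40))
  expect_equal(unname(m1$centroids[1, ]), unname(colMeans(x)))
  expect_error(fuzzy_cmeans(x, 41, seed = 1), "more clusters")
  expect_error(fuzzy_cmeans(rbind(x, z = rep(0, 4)), 2, seed = 1),
               "zero-variance")
})

test_that("well-separated planted patterns are recovered exactly", {
  sim <- simulate_timecourse_counts(list(up = c(1, 2, 4), down = c(4, 2, 1)),
                                    genes_per_pattern = 50, seed = 1)
  cm <- filter_low_expression(sim$counts)
  norm <- median_of_ratios_normalize(cm$counts)$normalized
  y <- log2(norm + 1)
  key <- interaction(cm$meta$condition, cm$meta$timepoint_h, drop = TRUE)
  prof <- standardize_profiles(vapply(levels(key), function(k)
    rowMeans(y[, key == k, drop = FALSE]), numeric(nrow(y))))
  model <- fuzzy_cmeans(prof, 2, seed = 1)
  truth <- sim$truth$pattern_id[match(rownames(prof), sim$truth$gene)]
  expect_equal(adjusted_rand_index(model$hard_labels, truth), 1.0)
})

test_that("small-problem objective matches a multi-restart oracle and e1071", {
  set.seed(6)
  centres <- rbind(c(-1.2, 0, 1.2), c(1.2, 0, -1.2), c(-0.5, 1.3, -0.8))
  x <- centres[rep(1:3, each = 9), ] + matrix(rnorm(81, sd = 0.1), 27, 3)
  rownames(x) <- paste0("g", 1:27)
  x <- standardize_profiles(x)
  fit <- fuzzy_cmeans(x, 3, seed = 1)
  best <- min(vapply(1:20, function(s)
    fuzzy_cmeans(x, 3, seed = s)$objective, numeric(1)))
  expect_lt(abs(fit$objective - best), 1e-6)
  skip_if_not_installed("e1071")
  # independent implementation: recompute the fuzzy objective sum(u^m d^2)
  # from e1071's fitted model and compare optima
  set.seed(2)
  cmref <- e1071::cmeans(x, 3, m = 2, iter.max = 500)
  d2 <- t(apply(x, 1, function(r) colSums((t(cmref$centers) - r)^2)))
  ref <- sum(cmref$membership^2 * d2)
  expect_equal(fit$objective, ref, tolerance = 1e-4)
})

test_that("agreement metric matches mclust's adjusted Rand index", {
  skip_if_not_installed("mclust")
  set.seed(8)
  a <- sample(1:4, 60, replace = TRUE)
  b <- sample(1:3, 60, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, a), 1)
})
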