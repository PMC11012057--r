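# Screening cascade: quality/element filters, coelution grouping, ANOVA,
# PCA, PLS-DA + VIP, ranking, hierarchical clustering.

make_group_table <- function(X, groups) {
  # X: samples x features of log10 areas; build a feature_table around it
  n <- ncol(X)
  feats <- data.frame(id = sprintf("F%03d", seq_len(n)),
                      mz = seq(200, by = 10, length.out = n),
                      rt = seq(5, by = 0.5, length.out = n),
                      formula = rep("C10H12O4", n), stringsAsFactors = FALSE)
  samples <- sprintf("S%02d", seq_len(nrow(X)))
  areas <- t(10^X) - 1
  colnames(areas) <- samples
  ratings <- matrix(9, n, nrow(X), dimnames = list(NULL, samples))
  manifest <- data.frame(sample = samples, group = as.character(groups),
                         stringsAsFactors = FALSE)
  feature_table(feats, areas, ratings, manifest)
}

test_that("quality filter applies inclusive rating and intensity thresholds", {
  areas <- matrix(c(2e5, 2e5, 1e5, 1.5e5, 3e6, 1e6), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, c("A1", "B1")))
  ratings <- matrix(c(6.0, 4.0, 5.9, 5.9, 5.0, 6.0), 3, 2, byrow = TRUE,
                    dimnames = list(NULL, c("A1", "B1")))
  ft <- toy_table(3, areas = areas, ratings = ratings)
  kept <- filter_quality(ft)
  # F1: one rating at 6.0 and max area exactly 2e5 -> kept (inclusive)
  # F2: all ratings 5.9 -> removed; F3: rating 6.0 present, area fine -> kept
  expect_identical(kept$features$id, c("F1", "F3"))
})

test_that("quality filter pass counts agree with generator bookkeeping", {
  study <- generate_study(sim_config(seed = 1, n_null_features = 480,
                                     n_marker_features = 20,
                                     samples_per_group = 4,
                                     adduct_satellite_rate = 0,
                                     isf_satellite_rate = 0,
                                     rating_low_rate = 0.3))
  kept <- filter_quality(study$features)
  expect_false(any(study$truth$low_rated %in% kept$features$id))
  # every feature removed on rating is in the generator's low-rated list;
  # any extra removals must be on intensity alone
  removed <- setdiff(study$features$features$id, kept$features$id)
  on_rating <- removed[apply(study$features$ratings[
    match(removed, study$features$features$id), , drop = FALSE], 1, max) < 6]
  expect_true(all(on_rating %in% study$truth$low_rated))
})

test_that("element filter keeps CHNO formulas and drops the rest", {
  ft <- toy_table(4, formula = c("C27H50N2O4", "C10H12SO4", NA, "C6H6"))
  kept <- filter_elements(ft)
  expect_identical(kept$features$id, c("F1", "F4"))
  cfg <- cascade_config(require_formula = FALSE)
  expect_identical(filter_elements(ft, cfg)$features$id, c("F1", "F3", "F4"))
})

test_that("coelution grouping merges within 5 ppm and 0.1 min only", {
  areas <- matrix(c(5e6, 5e6, 2e6, 2e6, 1e6, 1e6), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, c("A1", "B1")))
  ft <- toy_table(3, mz = c(433.11258, 433.11270, 433.11260),
                  rt = c(17.197, 17.200, 20.70), areas = areas)
  g <- group_features(ft)
  expect_equal(nrow(g$features), 2L)   # F1+F2 merge (0.28 ppm, 0.003 min), F3 apart
  expect_identical(g$features$id[1], "F1")  # representative = largest area
  expect_equal(unname(g$areas[1, ]), c(7e6, 7e6))
  mm <- attr(g, "merge_map")
  expect_equal(mm$group_representative[mm$member == "F2"], "F1")
  # same formula, far apart in RT: stays distinct
  ft2 <- toy_table(2, mz = c(519.11322, 519.11310), rt = c(20.884, 24.417))
  expect_equal(nrow(group_features(ft2)$features), 2L)
  # singleton unchanged
  ft1 <- toy_table(1)
  expect_equal(nrow(group_features(ft1)$features), 1L)
})

test_that("ANOVA screen flags degenerate features and detects planted shifts", {
  set.seed(101)
  g <- rep(paste0("G", 1:7), each = 10)
  X <- matrix(rnorm(70 * 5, 6, 0.2), 70, 5)
  X[, 3] <- rnorm(70, 6, 0.2); X[g == "G2", 3] <- rnorm(10, 6 + 10 * 0.2, 0.2)
  X[, 5] <- 6                       # constant feature
  ft <- make_group_table(X, g)
  rec <- anova_screen(ft)
  expect_true(rec$degenerate[5])
  expect_equal(rec$adjusted_p[5], 1)
  expect_false(rec$passed_anova[5])
  expect_lt(rec$adjusted_p[3], 1e-4)
  expect_true(all(rec$adjusted_p >= rec$anova_p))
  tk <- attr(rec, "tukey")[["F003"]]
  expect_true(any(grepl("G2", names(tk)) & tk < 0.01))
})

test_that("null features reject at roughly the nominal rate", {
  set.seed(7)
  g <- rep(paste0("G", 1:7), each = 10)
  X <- matrix(rnorm(70 * 200, 6, 0.2), 70, 200)
  rec <- anova_screen(make_group_table(X, g), tukey = FALSE)
  expect_equal(mean(rec$anova_p < 0.05), 0.05, tolerance = 0.031 / 0.05)
})

test_that("PCA matches an independent eigen-decomposition oracle", {
  set.seed(3)
  X <- matrix(rnorm(80), 10, 8)
  fit <- pca(X, n_components = 5)
  ev <- eigen(stats::cov(sweep(X, 2, colMeans(X))), symmetric = TRUE)
  # eigenvalues of the covariance relate to squared singular values / (n-1)
  d2 <- apply(fit$scores, 2, function(s) sum(s^2)) / (nrow(X) - 1)
  expect_equal(d2, ev$values[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    expect_equal(abs(sum(fit$loadings[, k] * ev$vectors[, k])), 1, tolerance = 1e-8)
  }
  # rank-1 matrix: first component carries all variance
  R <- outer(1:6, c(1, 2, 3))
  f1 <- pca(R, 2)
  expect_equal(f1$explained_variance[1], 1, tolerance = 1e-12)
  # orthogonal scores
  ct <- crossprod(fit$scores)
  expect_lt(max(abs(ct[upper.tri(ct)])), 1e-8)
  expect_error(pca(matrix(numeric(), 0, 0)), "empty")
})

test_that("PLS-DA weights find a perfectly separating variable", {
  set.seed(8)
  g <- rep(c("A", "B"), each = 10)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 1] <- ifelse(g == "A", 5, -5) + rnorm(20, 0, 0.01)
  fit <- plsda(X, g, n_components = 2)
  expect_equal(which.max(abs(fit$W[, 1])), 1L)
  # scores orthogonal
  ct <- crossprod(fit$scores)
  expect_lt(max(abs(ct[upper.tri(ct)])), 1e-8)
  # weight vectors unit norm
  expect_equal(unname(colSums(fit$W^2)), rep(1, fit$n_components), tolerance = 1e-12)
  expect_identical(predict(fit, X)$class, g)
})

test_that("full-rank PLS reconstructs X within numerical tolerance", {
  set.seed(9)
  X <- matrix(rnorm(8 * 4), 8, 4)
  colnames(X) <- paste0("V", 1:4)
  g <- rep(c("A", "B"), each = 4)
  fit <- plsda(X, g, n_components = 4)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  Xhat <- fit$scores %*% t(fit$P)
  expect_equal(Xhat, unname(Xs), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("VIP obeys its algebraic identities and finds planted markers", {
  set.seed(11)
  g <- rep(paste0("G", 1:4), each = 6)
  X <- matrix(rnorm(24 * 40, 6, 0.3), 24, 40)
  X[, 17] <- X[, 17] + ifelse(g == "G3", 2, 0)   # planted single marker
  fit <- plsda(X, g, n_components = 3)
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  expect_equal(which.max(v), 17L, ignore_attr = TRUE)
  # single-variable model: VIP forced to 1
  X1 <- matrix(rnorm(24, 0, 1), 24, 1)
  X1[, 1] <- ifelse(g == "G1", 3, 0) + rnorm(24, 0, 0.1)
  expect_equal(unname(vip(plsda(X1, g, n_components = 1))), 1, tolerance = 1e-10)
})

test_that("VIP agrees with the mixOmics implementation", {
  set.seed(12)
  g <- factor(rep(c("A", "B"), each = 8))
  X <- matrix(rnorm(16 * 12, 0, 1), 16, 12)
  X[, 2] <- X[, 2] + ifelse(g == "A", 1.5, 0)
  colnames(X) <- paste0("V", 1:12)
  fit <- plsda(X, g, n_components = 2)
  mo <- mixOmics::plsda(X, g, ncomp = 2)
  vm <- mixOmics::vip(mo)[, 2]
  expect_gt(stats::cor(vip(fit), vm), 0.999)
  expect_equal(unname(which.max(vip(fit))), unname(which.max(vm)))
})

test_that("marker ranking is deterministic and order invariant", {
  rec <- data.frame(id = c("b", "a", "c", "d", "e"),
                    adjusted_p = c(1e-6, 1e-6, 1e-8, 0.5, 1e-7),
                    vip = c(3, 4, 2.5, 9, 1.0),
                    passed_anova = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  cfg <- cascade_config(top_n = 3)
  top <- select_markers(rec, cfg)
  expect_identical(top$id, c("c", "a", "b"))   # p asc, tie by VIP desc, then id
  expect_identical(top$rank, 1:3)
  perm <- select_markers(rec[sample(5), ], cfg)
  expect_identical(perm$id, top$id)
  expect_warning(out <- select_markers(rec[rec$vip > 100, ], cfg), "candidate")
  expect_equal(nrow(out), 0L)
})

test_that("hierarchical clustering recovers planted structure deterministically", {
  set.seed(5)
  # two abundance-pattern clusters (rows are autoscaled, so the planted
  # structure must live in the across-sample profile, not the row mean)
  p1 <- c(rep(6, 5), rep(3, 5)); p2 <- rev(p1)
  X <- rbind(t(replicate(5, p1 + rnorm(10, 0, 0.3))),
             t(replicate(5, p2 + rnorm(10, 0, 0.3))))
  rownames(X) <- paste0("M", 1:10)
  hc <- hcluster(X)
  expect_false(is.unsorted(hc$tree$height))     # Ward heights non-decreasing
  split2 <- stats::cutree(hc$tree, 2)
  expect_equal(length(unique(split2[1:5])), 1L)
  expect_equal(length(unique(split2[6:10])), 1L)
  expect_false(split2[1] == split2[6])
  tr <- ape::read.tree(text = hc$newick)
  expect_setequal(tr$tip.label, rownames(X))
  # identical rows merge at height zero
  Z <- rbind(a = c(1, 2, 3, 8), b = c(1, 2, 3, 8), c = c(9, 1, 2, 4))
  hz <- hcluster(Z)
  expect_equal(hz$tree$height[1], 0, tolerance = 1e-12)
  # single row: trivial tree
  expect_null(hcluster(Z[1, , drop = FALSE])$tree)
})

test_that("tightening any cascade threshold nests the surviving set", {
  study <- generate_study(sim_config(seed = 23, n_null_features = 120,
                                     n_marker_features = 10,
                                     samples_per_group = 5))
  ft <- study$features
  loose <- cascade_config(rating_threshold = 5, min_intensity = 1e5,
                          anova_alpha = 1e-2, vip_threshold = 1.0)
  strict <- cascade_config(rating_threshold = 7, min_intensity = 5e5,
                           anova_alpha = 1e-5, vip_threshold = 2.5)
  expect_true(all(filter_quality(ft, strict)$features$id %in%
                    filter_quality(ft, loose)$features$id))
  sl <- suppressWarnings(screen_markers(ft, loose))
  ss <- suppressWarnings(screen_markers(ft, strict))
  expect_true(all(ss$records$id[ss$records$passed_anova] %in%
                    sl$records$id[sl$records$passed_anova]))
  expect_true(all(ss$records$id[ss$records$passed_vip] %in%
                    sl$records$id[sl$records$passed_vip]))
  expect_true(all(diff(sl$funnel) <= 0))
})
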