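# Marker-screening cascade: peak-quality and intensity filters, element
# filters, coelution grouping, one-way ANOVA with Tukey post-hoc and BH
# adjustment, PCA, NIPALS PLS-DA with VIP, ranked top-N selection, and
# hierarchical clustering of the selected markers.

#' Cascade configuration
#'
#' Defaults follow common high-resolution LC-MS practice for herbal feature
#' tables: peak rating >= 6 in at least one file, minimum peak intensity
#' 2e5, CHNO-only formulas, BH-adjusted ANOVA alpha 1e-4, VIP >= 2, top 25
#' markers, 5 ppm / 0.1 min coelution grouping, 3 PLS-DA components.
#'
#' @param rating_threshold Minimum of the per-feature maximum peak rating.
#' @param min_intensity Minimum of the per-feature maximum area.
#' @param allowed_elements Elements a predicted formula may contain.
#' @param require_formula Drop features without a predicted formula.
#' @param anova_alpha Threshold on the BH-adjusted ANOVA p-value.
#' @param vip_threshold Minimum PLS-DA VIP.
#' @param top_n Number of ranked markers to retain.
#' @param group_mz_ppm,group_rt_min Coelution grouping tolerances.
#' @param n_components Number of PLS-DA components.
#' @param p_adjust Either \code{"BH"} (Benjamini-Hochberg across features,
#'   the default) or \code{"tukey"} (minimum Tukey family-wise pairwise p).
#' @return A list of class \code{"cascade_config"}.
#' @export
cascade_config <- function(rating_threshold = 6,
                           min_intensity = 2e5,
                           allowed_elements = c("C", "H", "N", "O"),
                           require_formula = TRUE,
                           anova_alpha = 1e-4,
                           vip_threshold = 2.0,
                           top_n = 25,
                           group_mz_ppm = 5,
                           group_rt_min = 0.1,
                           n_components = 3,
                           p_adjust = c("BH", "tukey")) {
  stopifnot(rating_threshold > 0, min_intensity > 0, anova_alpha > 0,
            vip_threshold >= 0, top_n >= 1, group_mz_ppm > 0,
            group_rt_min > 0, n_components >= 1)
  structure(list(rating_threshold = rating_threshold,
                 min_intensity = min_intensity,
                 allowed_elements = allowed_elements,
                 require_formula = require_formula,
                 anova_alpha = anova_alpha,
                 vip_threshold = vip_threshold,
                 top_n = top_n,
                 group_mz_ppm = group_mz_ppm,
                 group_rt_min = group_rt_min,
                 n_components = n_components,
                 p_adjust = match.arg(p_adjust)),
            class = "cascade_config")
}

#' Peak-quality filter
#'
#' Keeps a feature iff its maximum peak rating over samples is at least
#' \code{rating_threshold} (i.e. rated well in at least one file) and its
#' maximum area is at least \code{min_intensity}.  Thresholds are
#' inclusive; feature order is preserved.
#'
#' @param ft A \code{\link{feature_table}}.
#' @param cfg A \code{\link{cascade_config}}.
#' @return Filtered \code{feature_table}.
#' @export
filter_quality <- function(ft, cfg = cascade_config()) {
  max_rating <- apply(ft$ratings, 1L, max, na.rm = TRUE)
  max_area <- apply(ft$areas, 1L, max, na.rm = TRUE)
  keep <- max_rating >= cfg$rating_threshold & max_area >= cfg$min_intensity
  subset_features(ft, keep)
}

#' Element filter
#'
#' Keeps a feature iff a predicted formula is present and its element set
#' is a subset of \code{allowed_elements} (features with rare heteroatoms
#' or without a predicted formula are excluded).
#'
#' @inheritParams filter_quality
#' @return Filtered \code{feature_table}.
#' @export
filter_elements <- function(ft, cfg = cascade_config()) {
  keep <- vapply(ft$features$formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(!cfg$require_formula)
    els <- tryCatch(formula_elements(f), error = function(e) NULL)
    !is.null(els) && all(els %in% cfg$allowed_elements)
  }, logical(1L), USE.NAMES = FALSE)
  subset_features(ft, keep)
}

#' Coelution grouping of redundant features
#'
#' Features within \code{group_mz_ppm} (of the larger m/z) and
#' \code{group_rt_min} of an already-seen feature are merged into it.
#' Features are visited in descending maximum-area order, so each group's
#' representative is its highest-area member; merged areas are summed per
#' sample and ratings take the per-sample maximum.  The member-to-group map
#' is kept in the \code{"merge_map"} attribute for audit.
#'
#' @inheritParams filter_quality
#' @return Grouped \code{feature_table} with a \code{"merge_map"} attribute.
#' @export
group_features <- function(ft, cfg = cascade_config()) {
  n <- nrow(ft$features)
  if (n == 0L) return(ft)
  ord <- order(-apply(ft$areas, 1L, max, na.rm = TRUE))
  rep_idx <- integer(0)           # indices of representatives, in visit order
  assign_to <- integer(n)         # feature index -> representative index
  for (i in ord) {
    mzd <- abs(ft$features$mz[i] - ft$features$mz[rep_idx])
    tol <- pmax(ft$features$mz[i], ft$features$mz[rep_idx]) * cfg$group_mz_ppm * 1e-6
    rtd <- abs(ft$features$rt[i] - ft$features$rt[rep_idx])
    hit <- which(mzd <= tol & rtd <= cfg$group_rt_min)
    if (length(hit)) {
      assign_to[i] <- rep_idx[hit[1L]]
    } else {
      rep_idx <- c(rep_idx, i)
      assign_to[i] <- i
    }
  }
  keep <- sort(rep_idx)
  areas <- ft$areas[keep, , drop = FALSE]
  ratings <- ft$ratings[keep, , drop = FALSE]
  for (j in seq_along(keep)) {
    members <- which(assign_to == keep[j] & seq_len(n) != keep[j])
    for (i in members) {
      areas[j, ] <- areas[j, ] + ft$areas[i, ]
      ratings[j, ] <- pmax(ratings[j, ], ft$ratings[i, ])
    }
  }
  out <- structure(list(features = ft$features[keep, , drop = FALSE],
                        areas = areas, ratings = ratings,
                        manifest = ft$manifest),
                   class = "feature_table")
  attr(out, "merge_map") <- data.frame(
    member = ft$features$id,
    group_representative = ft$features$id[assign_to],
    stringsAsFactors = FALSE)
  out
}

log_area <- function(areas) log10(areas + 1)

#' Per-feature one-way ANOVA with Tukey post-hoc
#'
#' Peak areas are log10(x+1)-transformed, then each feature is tested with
#' a one-way ANOVA F-test across groups (\code{stats::aov}).  P-values are
#' adjusted across features by Benjamini-Hochberg (\code{stats::p.adjust});
#' Tukey HSD pairwise adjusted p-values are stored per feature.  A feature
#' that is constant within and between groups gets p = 1 and a
#' \code{degenerate} flag.  When \code{cfg$p_adjust == "tukey"} the cascade
#' cut uses the minimum Tukey pairwise p instead of the BH-adjusted p.
#'
#' @param ft A \code{\link{feature_table}} with at least 2 groups of at
#'   least 2 samples each.
#' @param cfg A \code{\link{cascade_config}}.
#' @param tukey Compute Tukey HSD tables (default TRUE; disable for speed
#'   in large simulations).
#' @return data.frame with columns \code{id}, \code{anova_p},
#'   \code{adjusted_p}, \code{degenerate}, \code{passed_anova}, and a
#'   \code{"tukey"} attribute (list of pairwise adjusted-p vectors).
#' @export
anova_screen <- function(ft, cfg = cascade_config(), tukey = TRUE) {
  g <- sample_groups(ft)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups with >= 2 samples each")
  }
  Y <- log_area(ft$areas)
  n <- nrow(Y)
  p_raw <- numeric(n)
  degenerate <- logical(n)
  tk <- vector("list", n)
  for (i in seq_len(n)) {
    y <- Y[i, ]
    if (stats::var(y) < .Machine$double.eps) {
      p_raw[i] <- 1
      degenerate[i] <- TRUE
      next
    }
    fit <- stats::aov(y ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    p_raw[i] <- if (is.na(p)) 1 else p
    if (tukey) {
      hsd <- stats::TukeyHSD(fit)$g
      tk[[i]] <- stats::setNames(hsd[, "p adj"], rownames(hsd))
    }
  }
  adj <- stats::p.adjust(p_raw, method = "BH")
  if (cfg$p_adjust == "tukey") {
    if (!tukey) stop("tukey adjustment requested but tukey = FALSE")
    adj <- vapply(seq_len(n), function(i) {
      if (degenerate[i] || is.null(tk[[i]])) 1 else min(tk[[i]])
    }, numeric(1L))
    adj <- pmax(adj, p_raw)
  }
  out <- data.frame(id = ft$features$id,
                    anova_p = p_raw,
                    adjusted_p = adj,
                    degenerate = degenerate,
                    passed_anova = adj < cfg$anova_alpha,
                    stringsAsFactors = FALSE)
  attr(out, "tukey") <- stats::setNames(tk, ft$features$id)
  out
}

#' Principal component analysis by singular value decomposition
#'
#' Columns are mean-centered; scores are U times the singular values.
#'
#' @param X Numeric samples-by-features matrix.
#' @param n_components Number of components (default
#'   \code{min(dim(X)) - 1}).
#' @return List with \code{scores}, \code{loadings},
#'   \code{explained_variance} (fractions of total variance) and
#'   \code{center}.
#' @export
pca <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  if (!length(X)) stop("empty matrix")
  if (is.null(n_components)) n_components <- max(1L, min(dim(X)) - 1L)
  stopifnot(n_components <= min(dim(X)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  total <- sum(sv$d^2)
  list(scores = scores, loadings = sv$v,
       explained_variance = if (total > 0) d^2 / total else rep(0, n_components),
       center = ctr)
}

#' Fit a PLS-DA model (NIPALS PLS2)
#'
#' X is autoscaled (centered, unit variance; zero-variance columns dropped
#' with a warning) and Y is the centered one-hot group indicator matrix.
#' Components are extracted by the NIPALS algorithm with deflation of both
#' X and Y, which makes the score vectors mutually orthogonal.  The fit is
#' deterministic given the input row/column order.
#'
#' @param X Numeric samples-by-features matrix (rows = samples).
#' @param groups Group labels (factor or character), one per row of X.
#' @param n_components Number of latent components (default 3).
#' @param scale Either \code{"auto"} (unit variance, the default) or
#'   \code{"pareto"} (square-root of the standard deviation).
#' @param max_iter,tol NIPALS iteration controls.
#' @return An object of class \code{"plsda"} with weights \code{W}, scores
#'   \code{T}, X-loadings \code{P}, Y-loadings \code{Q}, per-component
#'   explained Y sum of squares \code{ssy}, scaling vectors, and group
#'   levels.
#' @seealso \code{\link{vip}}, \code{\link{predict.plsda}}
#' @export
plsda <- function(X, groups, n_components = 3, scale = c("auto", "pareto"),
                  max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  groups <- factor(groups)
  scale <- match.arg(scale)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  stopifnot(nrow(X) == length(groups), n_components >= 1)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > .Machine$double.eps
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance column(s) before scaling", sum(!keep)))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  ctr <- colMeans(X)
  scl <- if (scale == "auto") sds else sqrt(sds)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Ymat <- stats::model.matrix(~ groups - 1)
  colnames(Ymat) <- levels(groups)
  yctr <- colMeans(Ymat)
  Ys <- sweep(Ymat, 2L, yctr)
  n <- nrow(Xs); p <- ncol(Xs)
  a_max <- min(n_components, n - 1L, p)
  W <- matrix(0, p, a_max); Tm <- matrix(0, n, a_max)
  P <- matrix(0, p, a_max); Q <- matrix(0, ncol(Ys), a_max)
  ssy <- numeric(a_max)
  Xd <- Xs; Yd <- Ys
  a <- 0L
  for (comp in seq_len(a_max)) {
    u <- Yd[, which.max(apply(Yd, 2L, stats::var))]
    if (sum(u^2) < tol || sum(Xd^2) < tol) break
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), tol) < tol) break
      t_old <- tt
    }
    pl <- crossprod(Xd, tt) / sum(tt^2)
    a <- comp
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pl; Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)     # = sum((t q')^2), Y-SS explained
    Xd <- Xd - tt %*% t(pl)
    Yd <- Yd - tt %*% t(q)
  }
  if (a == 0L) stop("no PLS component could be extracted")
  idx <- seq_len(a)
  structure(list(W = W[, idx, drop = FALSE], scores = Tm[, idx, drop = FALSE],
                 P = P[, idx, drop = FALSE], Q = Q[, idx, drop = FALSE],
                 ssy = ssy[idx], n_components = a,
                 center = ctr, scale = scl, y_center = yctr,
                 levels = levels(groups), variables = colnames(X),
                 groups = groups),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d components, %d variables, %d samples, %d classes\n",
              x$n_components, nrow(x$W), nrow(x$scores), length(x$levels)))
  cat("Y-SS explained per component:", signif(x$ssy / sum(x$ssy), 3), "\n")
  invisible(x)
}

#' Regression coefficients of a PLS-DA model
#'
#' @param object A \code{\link{plsda}} fit.
#' @param ... Ignored.
#' @return Matrix of coefficients (variables x classes) on the scaled scale.
#' @export
coef.plsda <- function(object, ...) {
  Wstar <- object$W %*% solve(crossprod(object$P, object$W))
  B <- Wstar %*% t(object$Q)
  rownames(B) <- object$variables
  colnames(B) <- object$levels
  B
}

#' Predict group membership from a PLS-DA model
#'
#' @param object A \code{\link{plsda}} fit.
#' @param newdata Samples-by-features matrix with the model's variables.
#' @param ... Ignored.
#' @return List with \code{y} (predicted indicator values) and
#'   \code{class} (argmax class labels).
#' @export
predict.plsda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X <- X[, object$variables, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  Yhat <- Xs %*% coef.plsda(object)
  Yhat <- sweep(Yhat, 2L, object$y_center, "+")
  list(y = Yhat, class = object$levels[max.col(Yhat)])
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with \eqn{p} the number of variables and \eqn{SSY_a} the Y sum of
#' squares explained by component \eqn{a}.  The mean of squared VIPs is
#' always 1.
#'
#' @param model A fitted \code{\link{plsda}} model.
#' @return Named numeric vector of VIP scores, one per variable.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"), model$n_components >= 1)
  W <- model$W
  p <- nrow(W)
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.vector(wn^2 %*% model$ssy) / sum(model$ssy))
  stats::setNames(v, model$variables)
}

#' Rank and select the top-N markers
#'
#' Candidates must pass the ANOVA cut and reach the VIP threshold; they are
#' ranked by ascending adjusted p, ties broken by descending VIP then
#' ascending feature id, and the top \code{top_n} retained.  The ranking is
#' invariant to input row order.
#'
#' @param records data.frame from \code{\link{anova_screen}} with a
#'   \code{vip} column added.
#' @param cfg A \code{\link{cascade_config}}.
#' @return data.frame of the selected markers with a \code{rank} column.
#' @export
select_markers <- function(records, cfg = cascade_config()) {
  stopifnot(all(c("id", "adjusted_p", "vip", "passed_anova") %in% names(records)))
  cand <- records[records$passed_anova & records$vip >= cfg$vip_threshold, , drop = FALSE]
  if (nrow(cand) < cfg$top_n) {
    warning(sprintf("only %d candidate(s) for top_n = %d", nrow(cand), cfg$top_n))
  }
  ord <- order(cand$adjusted_p, -cand$vip, cand$id)
  top <- utils::head(cand[ord, , drop = FALSE], cfg$top_n)
  top$rank <- seq_len(nrow(top))
  rownames(top) <- NULL
  top
}

#' Hierarchical clustering of marker features
#'
#' Rows (features) are autoscaled across samples, then clustered with Ward
#' linkage (\code{"ward.D2"}) on Euclidean distances.  The result is the
#' standard \code{hclust} object plus a deterministic leaf order and a
#' Newick export.
#'
#' @param X Numeric features-by-samples matrix (rows are clustered).
#' @param newick_path Optional path; when given the tree is written in
#'   Newick format via \pkg{ape}.
#' @return List with \code{tree} (an \code{hclust}), \code{leaf_order}
#'   (row labels in dendrogram order), and \code{newick} (string).
#' @export
hcluster <- function(X, newick_path = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    return(list(tree = NULL, leaf_order = rownames(X), newick = NULL))
  }
  sds <- apply(X, 1L, stats::sd)
  sds[sds < .Machine$double.eps] <- 1
  Z <- sweep(sweep(X, 1L, rowMeans(X)), 1L, sds, "/")
  tree <- stats::hclust(stats::dist(Z), method = "ward.D2")
  phy <- ape::as.phylo(tree)
  nwk <- ape::write.tree(phy)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  list(tree = tree, leaf_order = tree$labels[tree$order], newick = nwk)
}

#' Run the full marker-screening cascade
#'
#' Applies, in order: the peak-quality filter, the element filter, per-
#' feature ANOVA with BH adjustment, PLS-DA VIP scoring, and ranked top-N
#' selection, then clusters the selected markers.  Stage survivor counts
#' are recorded as a six-number funnel (input, quality, elements, ANOVA,
#' VIP, top-N).
#'
#' @param ft A \code{\link{feature_table}}.
#' @param cfg A \code{\link{cascade_config}}.
#' @param tukey Compute Tukey HSD tables in the ANOVA stage.
#' @return An object of class \code{"marker_screen"}: \code{records}
#'   (per-feature statistics with stage flags), \code{markers} (ranked
#'   top-N), \code{funnel}, the fitted \code{plsda} model, the marker
#'   \code{hclust} result, and the post-filter \code{feature_table}.
#' @export
screen_markers <- function(ft, cfg = cascade_config(), tukey = TRUE) {
  n0 <- nrow(ft$features)
  ft_q <- filter_quality(ft, cfg)
  ft_e <- filter_elements(ft_q, cfg)
  if (nrow(ft_e$features) < 2L) stop("fewer than 2 features survive the filters")
  rec <- anova_screen(ft_e, cfg, tukey = tukey)
  X <- t(log_area(ft_e$areas))          # samples x features
  colnames(X) <- ft_e$features$id
  model <- plsda(X, sample_groups(ft_e), n_components = cfg$n_components)
  v <- vip(model)
  rec$vip <- as.numeric(v[rec$id])
  rec$vip[is.na(rec$vip)] <- 0          # zero-variance columns dropped in plsda
  rec$passed_vip <- rec$passed_anova & rec$vip >= cfg$vip_threshold
  top <- select_markers(rec, cfg)
  rec$in_top_n <- rec$id %in% top$id
  funnel <- c(input = n0,
              quality = nrow(ft_q$features),
              elements = nrow(ft_e$features),
              anova = sum(rec$passed_anova),
              vip = sum(rec$passed_vip),
              top_n = nrow(top))
  hc <- if (nrow(top) >= 2L) {
    hcluster(log_area(ft_e$areas)[match(top$id, ft_e$features$id), , drop = FALSE])
  } else NULL
  structure(list(records = rec, markers = top, funnel = funnel,
                 model = model, hclust = hc, table = ft_e, config = cfg),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, ...) {
  cat("Marker-screening cascade\n")
  cat(sprintf("  funnel: %s\n", paste(sprintf("%s=%d", names(x$funnel), x$funnel),
                                      collapse = " -> ")))
  cat(sprintf("  top markers: %d (VIP >= %.1f, adjusted p < %g)\n",
              nrow(x$markers), x$config$vip_threshold, x$config$anova_alpha))
  invisible(x)
}

#' @export
summary.marker_screen <- function(object, ...) {
  print(object)
  cat("\nTop markers:\n")
  print(utils::head(object$markers[, c("id", "adjusted_p", "vip", "rank")], 25))
  invisible(object)
}
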