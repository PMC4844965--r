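#' Pairwise Pearson similarity matrix
#'
#' Correlates the feature vectors of every image pair. Rows must be in
#' view-major order: all identities at the first view, then all at the
#' second, and so on; `block` is the number of identities per view block.
#'
#' @param features Numeric matrix, one row per image.
#' @param block Identities per view block.
#' @return A symmetric correlation matrix of class `similarity_matrix`
#'   with attributes `block` and `n_views`.
#' @export
similarity_matrix <- function(features, block) {
  n <- nrow(features)
  if (n %% block != 0)
    stop("number of rows is not a multiple of the block size")
  sds <- apply(features, 1, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) feature vector for image(s): ",
         paste(which(sds == 0), collapse = ", "))
  m <- stats::cor(t(features))
  structure(m, block = block, n_views = n / block,
            class = c("similarity_matrix", "matrix"))
}

# index masks for the two ratio statistics
sim_masks <- function(m) {
  n <- nrow(m)
  block <- attr(m, "block")
  idx <- (seq_len(n) - 1) %/% block     # view index per row
  pos <- (seq_len(n) - 1) %% block      # identity index per row
  same_view <- outer(idx, idx, "==")
  same_id <- outer(pos, pos, "==")
  diagm <- diag(n) == 1
  list(same_view = same_view, same_id = same_id, diag = diagm)
}

#' View selectivity index (VSI)
#'
#' Mean correlation inside the identity-count-sized square blocks around
#' the main diagonal (same view, different identity) divided by the mean
#' over the rest of the matrix; the main diagonal is excluded from both.
#'
#' @param m A [similarity_matrix()].
#' @return A single number; 1 means no view structure.
#' @export
vsi <- function(m) {
  mk <- sim_masks(m)
  num <- mean(m[mk$same_view & !mk$diag])
  den <- mean(m[!mk$same_view & !mk$diag])
  if (den == 0) stop("zero denominator in VSI")
  num / den
}

#' View-invariant identity selectivity index (VISI)
#'
#' Mean correlation along the off-centre diagonals at row-column lags
#' that are nonzero multiples of the block size (same identity, different
#' view under view-major ordering) divided by the mean over all other
#' off-diagonal entries.
#'
#' @param m A [similarity_matrix()].
#' @return A single number; 1 means no identity structure.
#' @export
visi <- function(m) {
  mk <- sim_masks(m)
  num <- mean(m[mk$same_id & !mk$diag])
  den <- mean(m[!mk$same_id & !mk$diag])
  if (den == 0) stop("zero denominator in VISI")
  num / den
}

#' Degree of invariance (DoI)
#'
#' For each reference view v, the between-identity correlations at v form
#' a threshold sample. For every view v', the within-identity
#' correlations \{corr(f(id, v), f(id, v'))\} are compared against the
#' threshold with a one-sided rank-sum test; DoI(v) counts the views
#' passing at `alpha` (v' = v is trivially invariant and counts, so DoI
#' is in \[1, 37\]). With `threshold = "max"` the within sample is
#' instead tested (one-sided signed rank) against the maximum
#' between-identity correlation at v.
#'
#' @param features Feature matrix in view-major order.
#' @param ids,views Provenance vectors (one entry per row of
#'   `features`).
#' @param alpha Significance level per comparison.
#' @param threshold `"mean"` compares against the between-identity
#'   sample (rank-sum); `"max"` against its maximum (signed rank).
#' @return A list with `doi` (named count per reference view), the mean
#'   `tuning` curve matrix (reference view x probe view), and the
#'   significance `mask`.
#' @export
doi <- function(features, ids, views, alpha = 0.02,
                threshold = c("mean", "max")) {
  threshold <- match.arg(threshold)
  uids <- unique(ids)
  uv <- sort(unique(views))
  if (length(uids) < 3) stop("DoI needs at least 3 identities")
  nv <- length(uv)
  # features indexed [identity, view]
  fmat <- lapply(uv, function(v) {
    rows <- features[views == v, , drop = FALSE]
    rows[match(uids, ids[views == v]), , drop = FALSE]
  })
  tuning <- matrix(NA_real_, nv, nv, dimnames = list(uv, uv))
  mask <- matrix(FALSE, nv, nv, dimnames = list(uv, uv))
  for (a in seq_len(nv)) {
    fa <- fmat[[a]]
    cm <- suppressWarnings(stats::cor(t(fa)))
    between <- cm[upper.tri(cm)]
    for (b in seq_len(nv)) {
      fb <- fmat[[b]]
      within <- vapply(seq_along(uids), function(i)
        suppressWarnings(stats::cor(fa[i, ], fb[i, ])), numeric(1))
      tuning[a, b] <- mean(within)
      p <- if (threshold == "mean") {
        suppressWarnings(stats::wilcox.test(within, between,
                                            alternative = "greater",
                                            exact = FALSE))$p.value
      } else {
        suppressWarnings(stats::wilcox.test(within - max(between),
                                            alternative = "greater",
                                            exact = FALSE))$p.value
      }
      mask[a, b] <- is.finite(p) && p < alpha
    }
    mask[a, a] <- TRUE   # a view is trivially invariant to itself
  }
  list(doi = rowSums(mask), tuning = tuning, mask = mask)
}

#' Discriminability score across in-plane rotations
#'
#' For every rotation, all pairwise Euclidean distances between identity
#' feature vectors are computed; distances are z-scored against the
#' pooled distance set over all rotations and runs, then averaged per
#' rotation. Positivity per rotation is tested one-sided across runs
#' (signed rank) with Benjamini-Hochberg correction.
#'
#' @param runs A list (one element per run) of lists (one element per
#'   rotation, named by rotation angle) of feature matrices with one row
#'   per identity.
#' @param fdr_alpha FDR level.
#' @return A tibble with rotation, score, p, p_adj and significance.
#' @export
discriminability_score <- function(runs, fdr_alpha = 0.05) {
  rots <- names(runs[[1]])
  per_run <- lapply(runs, function(run) {
    lapply(run, function(f) {
      if (nrow(f) < 2) stop("discriminability needs >= 2 identities")
      as.vector(stats::dist(f))
    })
  })
  pooled <- unlist(per_run)
  mu <- mean(pooled); sdv <- stats::sd(pooled)
  if (sdv == 0) sdv <- 1   # all distances equal: z-scores all zero
  zmeans <- sapply(rots, function(r)
    vapply(per_run, function(run) mean((run[[r]] - mu) / sdv),
           numeric(1)))
  zmeans <- matrix(zmeans, nrow = length(runs))
  score <- colMeans(zmeans)
  p <- apply(zmeans, 2, function(z) {
    if (length(z) < 2 || stats::sd(z) == 0) return(NA_real_)
    suppressWarnings(stats::wilcox.test(z, alternative = "greater",
                                        exact = FALSE))$p.value
  })
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(rotation = as.numeric(rots), score = score, p = p,
                 p_adj = p_adj,
                 significant = !is.na(p_adj) & p_adj < fdr_alpha)
}

#' Composite-face hit rate curves
#'
#' Similarity of two composites with the same top half is `exp(-d)` of
#' their Euclidean feature distance; a pair counts as a hit at threshold
#' t when `exp(-d) > t`. Returns the hit-rate curve per condition over
#' the threshold grid, plus a per-threshold rank-sum comparison of the
#' hit indicators between conditions.
#'
#' @param aligned,misaligned Feature matrices for the two conditions,
#'   one row per composite image.
#' @param top Integer or character vector marking the top-half identity
#'   of each row (pairs are formed within the same top).
#' @param thresholds Threshold grid in \[0, 1\].
#' @return A list with `curves` (tibble: threshold, condition, hit_rate,
#'   p) and the per-condition pair distance vectors.
#' @export
composite_hit_rate <- function(aligned, misaligned, top,
                               thresholds = seq(0, 0.95, by = 0.05)) {
  pair_dists <- function(f) {
    ut <- unique(top)
    unlist(lapply(ut, function(tt) {
      rows <- which(top == tt)
      if (length(rows) < 2) return(numeric(0))
      as.vector(stats::dist(f[rows, , drop = FALSE]))
    }))
  }
  da <- pair_dists(aligned)
  dm <- pair_dists(misaligned)
  if (length(da) == 0 || length(dm) == 0)
    stop("no same-top composite pairs found")
  sa <- exp(-da); sm <- exp(-dm)
  rows <- lapply(thresholds, function(t) {
    ha <- as.numeric(sa > t); hm <- as.numeric(sm > t)
    p <- if (stats::sd(c(ha, hm)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(hm, ha,
                                          alternative = "greater",
                                          exact = FALSE))$p.value
    data.frame(threshold = t, aligned = mean(ha), misaligned = mean(hm),
               p = p)
  })
  list(curves = tibble::as_tibble(do.call(rbind, rows)),
       dist_aligned = da, dist_misaligned = dm)
}

#' Cross-view identification accuracy
#'
#' Trains a linear multiclass SVM on the identity labels at the training
#' views and reports accuracy at the test views.
#'
#' @param features Feature matrix.
#' @param ids,views Provenance vectors.
#' @param train_views,test_views Yaw values for training and testing.
#' @param cost SVM regularisation constant.
#' @return Test accuracy (fraction).
#' @export
cross_view_identification <- function(features, ids, views, train_views,
                                      test_views, cost = 1) {
  if (length(train_views) == 0 || length(test_views) == 0)
    stop("train and test view sets must be nonempty")
  tr <- views %in% train_views
  te <- views %in% test_views
  if (!all(unique(ids[te]) %in% unique(ids[tr])))
    stop("a test identity is absent from training")
  svm_accuracy(features[tr, , drop = FALSE], ids[tr],
               features[te, , drop = FALSE], ids[te], cost = cost)
}

#' Full train-view by test-view accuracy matrix
#'
#' @inheritParams cross_view_identification
#' @return A 37 x 37 matrix of accuracies (rows: training view).
#' @export
cross_view_matrix <- function(features, ids, views, cost = 1) {
  uv <- sort(unique(views))
  out <- matrix(NA_real_, length(uv), length(uv),
                dimnames = list(uv, uv))
  for (a in seq_along(uv)) {
    tr <- views == uv[a]
    keep <- apply(features[tr, , drop = FALSE], 2,
                  function(v) stats::var(v) > 0)
    if (!any(keep)) { out[a, ] <- 1 / length(unique(ids)); next }
    fit <- e1071::svm(features[tr, keep, drop = FALSE], factor(ids[tr]),
                      kernel = "linear", cost = cost, scale = FALSE)
    for (b in seq_along(uv)) {
      te <- views == uv[b]
      pred <- stats::predict(fit, features[te, keep, drop = FALSE])
      out[a, b] <- mean(as.character(pred) == ids[te])
    }
  }
  out
}

#' Inversion contrast
#'
#' Per view: mean pairwise between-identity Euclidean distance for the
#' upright and the inverted feature sets, normalised jointly by the
#' maximum over both conditions, with a one-sided rank-sum test per view
#' (upright > inverted); plus VISI computed separately on the two
#' similarity matrices.
#'
#' @param upright,inverted Feature matrices over the same identities and
#'   views (view-major order).
#' @param ids,views Provenance vectors, shared by both sets.
#' @return A list with `per_view` (tibble: view, upright, inverted,
#'   normalised distances, p) and `visi` (named pair).
#' @export
inversion_contrast <- function(upright, inverted, ids, views) {
  if (!all(dim(upright) == dim(inverted)))
    stop("upright and inverted feature grids do not match")
  uv <- sort(unique(views))
  n_id <- length(unique(ids))
  rows <- lapply(uv, function(v) {
    du <- as.vector(stats::dist(upright[views == v, , drop = FALSE]))
    di <- as.vector(stats::dist(inverted[views == v, , drop = FALSE]))
    p <- if (stats::sd(c(du, di)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(du, di,
                                          alternative = "greater",
                                          exact = FALSE))$p.value
    data.frame(view = v, upright = mean(du), inverted = mean(di), p = p)
  })
  per_view <- tibble::as_tibble(do.call(rbind, rows))
  mx <- max(c(per_view$upright, per_view$inverted))
  if (mx > 0) {
    per_view$upright_norm <- per_view$upright / mx
    per_view$inverted_norm <- per_view$inverted / mx
  } else {
    per_view$upright_norm <- per_view$inverted_norm <- 0
  }
  vp <- c(upright = visi(similarity_matrix(upright, block = n_id)),
          inverted = visi(similarity_matrix(inverted, block = n_id)))
  list(per_view = per_view, visi = vp)
}

#' Classical 2-D MDS embedding of a similarity matrix
#'
#' @param m A [similarity_matrix()].
#' @return An n x 2 matrix of coordinates (embedding of 1 - r).
#' @export
mds_embed <- function(m) {
  stats::cmdscale(stats::as.dist(1 - unclass(m)), k = 2)
}
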