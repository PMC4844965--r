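test_that("similarity matrices match the two-loop oracle", {
  withr::with_seed(21, {
    f <- matrix(rnorm(6 * 9), 6, 9)
    sm <- similarity_matrix(f, block = 2)
    expect_equal(unclass(sm), oracle_similarity(f), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(diag(sm), rep(1, 6))
    # duplicated feature rows give off-diagonal 1
    f2 <- rbind(f, f[1, ])
    sm2 <- similarity_matrix(f2, block = 7)
    expect_equal(sm2[1, 7], 1)
    # constant rows are rejected by name
    f3 <- f; f3[4, ] <- 2
    expect_error(similarity_matrix(f3, block = 2), "image\\(s\\): 4")
  })
})

test_that("VSI and VISI agree with hand-built matrices and oracles", {
  # hand-built: within-view blocks 0.8, everything else 0.2
  block <- 3; nv <- 4; n <- block * nv
  m <- matrix(0.2, n, n)
  for (v in 0:(nv - 1)) {
    idx <- v * block + 1:block
    m[idx, idx] <- 0.8
  }
  diag(m) <- 1
  sm <- structure(m, block = block, n_views = nv,
                  class = c("similarity_matrix", "matrix"))
  expect_equal(vsi(sm), 4)
  # same-identity lag entries 0.9, rest 0.1
  m2 <- matrix(0.1, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j && (i - 1) %% block == (j - 1) %% block) m2[i, j] <- 0.9
  diag(m2) <- 1
  sm2 <- structure(m2, block = block, n_views = nv,
                   class = c("similarity_matrix", "matrix"))
  expect_equal(visi(sm2), 9)
  # flat off-diagonal: both indices are exactly 1
  m3 <- matrix(0.4, n, n); diag(m3) <- 1
  sm3 <- structure(m3, block = block, n_views = nv,
                   class = c("similarity_matrix", "matrix"))
  expect_equal(vsi(sm3), 1)
  expect_equal(visi(sm3), 1)
  # random symmetric case against the double-loop oracle
  withr::with_seed(22, {
    f <- matrix(rnorm(12 * 7), 12, 7)
    smr <- similarity_matrix(f, block = 3)
    expect_equal(vsi(smr), oracle_vsi(unclass(smr), 3), tolerance = 1e-12)
    expect_equal(visi(smr), oracle_visi(unclass(smr), 3),
                 tolerance = 1e-12)
  })
})

test_that("VSI and VISI are invariant to common linear rescaling", {
  withr::with_seed(23, {
    f <- matrix(rnorm(12 * 8), 12, 8)
    a <- similarity_matrix(f, block = 3)
    b <- similarity_matrix(f * 3.7 + 0.4, block = 3)
    expect_equal(vsi(a), vsi(b), tolerance = 1e-10)
    expect_equal(visi(a), visi(b), tolerance = 1e-10)
  })
})

test_that("degree of invariance counts views passing the rank-sum test", {
  nv <- 6; n_id <- 10
  views <- rep(1:nv, each = n_id)
  ids <- rep(letters[1:n_id], nv)
  # constant per identity across views: perfectly invariant, DoI = nv
  withr::with_seed(24, {
    base <- matrix(rnorm(n_id * 8), n_id, 8)
    f_const <- base[rep(1:n_id, nv), ]
    d <- doi(f_const, ids, views, alpha = 0.02)
    expect_equal(unname(d$doi), rep(nv, nv))
    expect_true(all(diag(d$mask)))          # v' = v always counts
    expect_equal(unname(diag(d$tuning)), rep(1, nv))
    # independent features per (id, view): DoI collapses toward the
    # false-positive floor of 1 (the self view)
    f_rand <- matrix(rnorm(n_id * nv * 8), n_id * nv, 8)
    dr <- doi(f_rand, ids, views, alpha = 0.02)
    expect_lt(mean(dr$doi), 2)
    expect_error(doi(f_rand[ids %in% c("a", "b")],
                     ids[ids %in% c("a", "b")],
                     views[ids %in% c("a", "b")]), "3 identities")
  })
  # permuting identity labels destroys invariance at the alpha level
  withr::with_seed(25, {
    sig <- matrix(rnorm(n_id * 6), n_id, 6)
    f_inv <- sig[rep(1:n_id, nv), ] +
      0.3 * matrix(rnorm(n_id * nv * 6), n_id * nv, 6)
    d0 <- doi(f_inv, ids, views, alpha = 0.02)
    expect_gt(mean(d0$doi), 4)
    perm_doi <- replicate(20, {
      pids <- ids
      for (v in 1:nv) pids[views == v] <- sample(ids[views == v])
      mean(doi(f_inv, pids, views, alpha = 0.02)$doi)
    })
    # permuted labels leave the self view plus alpha-level false hits
    expect_lt(mean(perm_doi), 1 + 0.02 * nv * 3 + 0.5)
  })
})

test_that("both DoI threshold conventions are available", {
  nv <- 4; n_id <- 8
  views <- rep(1:nv, each = n_id)
  ids <- rep(letters[1:n_id], nv)
  withr::with_seed(26, {
    f <- matrix(rnorm(n_id * nv * 5), n_id * nv, 5)
    d_mean <- doi(f, ids, views, threshold = "mean")
    d_max <- doi(f, ids, views, threshold = "max")
    # the max threshold is stricter: never more passing views
    expect_true(all(d_max$doi <= d_mean$doi))
  })
})

test_that("discriminability scores match a hand computation", {
  # two runs, two rotations, three identities, 1-D features
  runs <- list(
    list(`0` = matrix(c(0, 1, 3)), `90` = matrix(c(0, 0.1, 0.2))),
    list(`0` = matrix(c(0, 2, 5)), `90` = matrix(c(0, 0.1, 0.3))))
  # pooled distances and their z-scores, written out by hand
  d_all <- c(1, 3, 2, 0.1, 0.2, 0.1, 2, 5, 3, 0.1, 0.3, 0.2)
  mu <- mean(d_all); sdv <- sd(d_all)
  z0 <- c(mean((c(1, 3, 2) - mu) / sdv), mean((c(2, 5, 3) - mu) / sdv))
  z90 <- c(mean((c(0.1, 0.2, 0.1) - mu) / sdv),
           mean((c(0.1, 0.3, 0.2) - mu) / sdv))
  res <- discriminability_score(runs)
  expect_equal(res$score, c(mean(z0), mean(z90)), tolerance = 1e-12)
  # identical features: all distances zero, no rotation significant
  flat <- list(list(`0` = matrix(c(1, 1, 1)), `90` = matrix(c(1, 1, 1))),
               list(`0` = matrix(c(1, 1, 1)), `90` = matrix(c(1, 1, 1))))
  rf <- discriminability_score(flat)
  expect_equal(rf$score, c(0, 0))
  expect_false(any(rf$significant))
  # scaling all distances leaves the z-scored profile unchanged
  runs_scaled <- lapply(runs, function(r) lapply(r, function(f) f * 10))
  expect_equal(discriminability_score(runs_scaled)$score, res$score,
               tolerance = 1e-12)
  expect_error(discriminability_score(list(list(`0` = matrix(1)))),
               ">= 2 identities")
})

test_that("composite hit rates evaluate exp(-d) against the threshold", {
  # four same-top pairs with distances 0.1, 0.5, 1, 2
  f <- matrix(c(0, 0.1, 0, 0.5, 0, 1, 0, 2), ncol = 1)
  top <- c(1, 1, 2, 2, 3, 3, 4, 4)
  hr <- composite_hit_rate(f, f, top, thresholds = c(0, 0.5))
  expect_equal(hr$curves$aligned[hr$curves$threshold == 0], 1)
  expect_equal(hr$curves$aligned[hr$curves$threshold == 0.5], 2 / 4)
  expect_equal(sort(hr$dist_aligned), c(0.1, 0.5, 1, 2))
  # identical features in a pair count as hits for every t < 1
  fid <- matrix(0, 4, 2); top2 <- c(1, 1, 2, 2)
  hr2 <- composite_hit_rate(fid, fid, top2, thresholds = c(0, 0.5, 0.99))
  expect_equal(hr2$curves$aligned, c(1, 1, 1))
  expect_error(composite_hit_rate(f[1, , drop = FALSE],
                                  f[1, , drop = FALSE], top = 1),
               "no same-top")
})

test_that("cross-view identification hits its oracle extremes", {
  n_id <- 6
  withr::with_seed(27, {
    sig <- matrix(rnorm(n_id * 8, sd = 3), n_id, 8)
    views <- rep(c(0, 30), each = n_id)
    ids <- rep(letters[1:n_id], 2)
    f <- sig[rep(1:n_id, 2), ] + 0.01 * matrix(rnorm(n_id * 2 * 8),
                                               n_id * 2, 8)
    expect_equal(cross_view_identification(f, ids, views, 0, 0), 1)
    expect_equal(cross_view_identification(f, ids, views, 0, 30), 1)
    accs <- replicate(10, {
      sh <- ids
      for (v in c(0, 30)) sh[views == v] <- sample(ids[views == v])
      cross_view_identification(f, sh, views, 0, 30)
    })
    expect_lt(mean(accs), 0.5)
    expect_error(cross_view_identification(f, ids, views,
                                           numeric(0), 30), "nonempty")
    expect_error(cross_view_identification(
      f, c(ids[-1], "zz"), views, 0, 30), "absent")
  })
})

test_that("inversion contrasts match a double-loop oracle", {
  n_id <- 3; nv <- 2
  withr::with_seed(28, {
    up <- matrix(rnorm(n_id * nv * 5), n_id * nv, 5)
    ids <- rep(letters[1:n_id], nv)
    views <- rep(c(0, 45), each = n_id)
    # inverted == upright: zero contrast everywhere
    ic0 <- inversion_contrast(up, up, ids, views)
    expect_equal(ic0$per_view$upright, ic0$per_view$inverted)
    expect_equal(unname(ic0$visi["upright"]), unname(ic0$visi["inverted"]))
    # halved features: inverted distances exactly half
    ic <- inversion_contrast(up, up * 0.5, ids, views)
    expect_equal(ic$per_view$inverted, ic$per_view$upright / 2)
    # per-view means equal the explicit loop
    for (k in 1:nv) {
      v <- c(0, 45)[k]
      rows <- which(views == v)
      dd <- c()
      for (i in rows) for (j in rows)
        if (i < j) dd <- c(dd, sqrt(sum((up[i, ] - up[j, ])^2)))
      expect_equal(ic$per_view$upright[k], mean(dd), tolerance = 1e-12)
    }
    expect_error(inversion_contrast(up, up[1:3, ], ids, views),
                 "do not match")
  })
})

test_that("MDS embeds a similarity matrix into two dimensions", {
  withr::with_seed(29, {
    f <- matrix(rnorm(8 * 6), 8, 6)
    em <- mds_embed(similarity_matrix(f, block = 2))
    expect_equal(dim(em), c(8, 2))
  })
})
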