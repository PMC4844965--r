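test_that("VSL responses follow the Gaussian-plus-trace recursion", {
  pop <- vsl_population(dim = 4)
  c2 <- c(0.2, 0.5, 0.9, 0.4)
  gr <- vsl_grow(pop, c2)
  expect_equal(gr$new_unit, 1)
  pop <- gr$population
  # center == input, zero trace: activation exactly 1
  r1 <- vsl_respond(pop, c2, update_trace = TRUE)
  expect_equal(r1$activation, 1)
  # second presentation: 1 + alpha * 1 clamps back to 1; trace stays 1
  r2 <- vsl_respond(r1$population, c2, update_trace = TRUE)
  expect_equal(r2$activation, 1)
  expect_equal(r2$population$trace, 1)
  # far stimulus: analytic activation below the vigilance threshold
  far <- c2 + 1            # distance 2 in 4 dims
  rf <- vsl_respond(r2$population, far)
  expect_equal(rf$activation, exp(-4 / 0.5) + 0.3 * 1)
  g_inst <- exp(-sum((far - c2)^2) / (2 * 0.5^2))
  expect_lt(g_inst, 0.9)
  gr2 <- vsl_grow(r2$population, far)
  expect_equal(gr2$new_unit, 2)
  expect_equal(gr2$population$centers[2, ], far)
  # re-presenting a stored center never grows (response 1 >= any rho < 1)
  gr3 <- vsl_grow(gr2$population, c2)
  expect_true(is.na(gr3$new_unit))
  # empty population responds with an empty vector, not an error
  expect_length(vsl_respond(vsl_population(4), c2)$activation, 0)
})

test_that("vigilance growth matches a sequential-scan oracle on a sweep", {
  id <- sample_identity(41, "A")
  sm <- small_model()
  imgs <- lapply(yaw_grid(), function(v) render_face(id, v))
  c2s <- extract_c2(imgs, sm$model$dict, sm$model$bank)
  pop <- vsl_population(ncol(c2s), rho = 0.9)
  for (i in seq_len(nrow(c2s))) pop <- vsl_grow(pop, c2s[i, ])$population
  # oracle: explicit sequential scan with plain arithmetic
  centers <- list()
  for (i in seq_len(nrow(c2s))) {
    x <- c2s[i, ]
    best <- if (length(centers) == 0) -Inf else
      max(vapply(centers, function(p) exp(-sum((x - p)^2) / 0.5),
                 numeric(1)))
    if (best < 0.9) centers[[length(centers) + 1]] <- x
  }
  expect_equal(nrow(pop$centers), length(centers))
  expect_equal(pop$centers, do.call(rbind, centers))
})

test_that("ISL units max-pool their private VSL inputs with trace mixing", {
  pop <- isl_population(max_coeff = 0.7, trace_coeff = 0.3)
  pop$incoming <- list(c(3, 6))
  pop$trace <- 0
  acts <- c(0, 0, 0.4, 0, 0, 0.9, 0)
  r <- isl_respond(pop, acts)
  expect_equal(r$activation, 0.7 * 0.9)
  # all-zero input with zero traces: activation exactly 0
  pop$trace <- 0
  expect_equal(isl_respond(pop, rep(0, 7))$activation, 0)
  expect_error(isl_respond(pop, c(0.1, 0.2)), "out of range")
})

test_that("pooling more views yields a more view-stable ISL profile", {
  sm <- small_model()
  id <- sample_identity(42, "A")
  imgs <- lapply(yaw_grid(), function(v) render_face(id, v))
  c2s <- extract_c2(imgs, sm$model$dict, sm$model$bank)
  vsl <- vsl_population(ncol(c2s))
  vsl$centers <- c2s[seq(1, 37, by = 4), , drop = FALSE]  # 10 view units
  vsl$trace <- numeric(nrow(vsl$centers))
  isl <- isl_population()
  isl$incoming <- list(seq_len(10), 5L)  # pooled unit vs one-view unit
  isl$trace <- c(0, 0)
  sweep_act <- t(sapply(seq_len(nrow(c2s)), function(i)
    isl_respond(isl, vsl_respond(vsl, c2s[i, ])$activation)$activation))
  expect_lt(var(sweep_act[, 1]), var(sweep_act[, 2]))
})

test_that("new VSL units wire to the trace-winning ISL unit", {
  isl <- isl_population()
  # cold start: fresh ISL unit containing exactly the new VSL unit
  w1 <- wire_to_winner(isl, 1)
  expect_equal(w1$population$incoming, list(1))
  expect_equal(w1$winner, 1)
  # mid-identity: positive trace wins, ties break to the lowest index
  pop <- w1$population
  pop$trace <- 0.4
  w2 <- wire_to_winner(pop, 2)
  expect_equal(w2$winner, 1)
  expect_equal(w2$population$incoming[[1]], c(1, 2))
  # after a blank reset (all traces zero): a NEW ISL unit is created
  pop2 <- w2$population
  pop2$trace <- c(0, 0)
  w3 <- wire_to_winner(pop2, 3)
  expect_equal(w3$winner, 2)
  expect_equal(w3$population$incoming, list(c(1, 2), 3))
  expect_error(wire_to_winner(w3$population, 2), "already wired")
})

test_that("trace reset is idempotent and a blank image reproduces it", {
  sm <- small_model()
  m <- sm$model
  c2 <- extract_c2(list(render_face(sample_identity(43, "A"), 0)),
                   m$dict, m$bank)[1, ]
  vsl <- m$vsl; isl <- m$isl
  # respond with trace updates, then reset
  vr <- vsl_respond(vsl, c2, update_trace = TRUE)
  ir <- isl_respond(isl, vr$activation, update_trace = TRUE)
  rt <- reset_traces(vr$population, ir$population)
  expect_true(all(rt$vsl$trace == 0) && all(rt$isl$trace == 0))
  rt2 <- reset_traces(rt$vsl, rt$isl)
  expect_identical(rt, rt2)
  # fresh response after reset equals a fresh population's response
  expect_identical(vsl_respond(rt$vsl, c2)$activation,
                   vsl_respond(vsl, c2)$activation)
  # end-to-end: a blank gray image yields zero C2, zero activations, and
  # clears the traces exactly like reset_traces
  blank_c2 <- s2_c2(s1_c1(matrix(0.5, 64, 64), m$bank), m$dict)
  expect_true(all(blank_c2 == 0))
  vb <- vsl_respond(vr$population, blank_c2, update_trace = TRUE)
  expect_true(all(vb$activation == 0))
  ib <- isl_respond(ir$population, vb$activation, update_trace = TRUE)
  expect_true(all(ib$activation == 0))
  expect_identical(vb$population$trace, rt$vsl$trace)
  expect_identical(ib$population$trace, rt$isl$trace)
})

test_that("wiring stays disjoint and covers every VSL unit", {
  m <- small_model()$model
  wired <- unlist(m$isl$incoming)
  expect_equal(sort(wired), seq_len(nrow(m$vsl$centers)))
  expect_equal(length(wired), length(unique(wired)))
})

test_that("trained ISL features are identity-tolerant across views", {
  f <- study_test_features()
  ids <- f$provenance$id_label
  cm <- cor(t(f$ISL))
  same <- outer(ids, ids, "==")
  diag(same) <- NA
  expect_gt(mean(cm[which(same)]), mean(cm[which(!same)]))
})

test_that("identities are population-coded over several ISL units", {
  f <- study_test_features()
  ids <- unique(f$provenance$id_label)
  for (id in ids) {
    prof <- colMeans(f$ISL[f$provenance$id_label == id, , drop = FALSE])
    expect_gte(sum(prof > 0.1 * max(prof)), 2)
  }
})

test_that("VSL units are view-tuned with near-unimodal mean curves", {
  f <- study_test_features()
  vs <- f$provenance$yaw_deg
  curves <- apply(f$VSL, 2, function(col) tapply(col, vs, mean))
  # examine a systematic sample of units
  sel <- seq(1, ncol(curves), length.out = 40)
  frac_ok <- mean(sapply(round(sel), function(j) {
    cu <- curves[, j]
    pk <- which.max(cu)
    win <- max(1, pk - 6):min(37, pk + 6)  # +/- 30 degrees
    # monotone decay away from the peak, small tolerance band
    left <- cu[win[win <= pk]]; right <- cu[win[win >= pk]]
    all(diff(left) > -0.02 * max(cu)) && all(diff(right) < 0.02 * max(cu))
  }))
  expect_gt(frac_ok, 0.9)
})
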