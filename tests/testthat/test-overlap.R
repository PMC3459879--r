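test_that("overlap is the absolute correlation cosine", {
  v <- tt_anm$vectors[, 3]
  expect_equal(overlap(v, v), 1.0)
  expect_equal(overlap(v, -v), 1.0)
  expect_equal(overlap(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0)), 0.0)
  expect_equal(overlap(v, tt_anm$vectors[, 4]), 0, tolerance = 1e-9)
  expect_lm_error(overlap(v, v[-1]), "shape_error")
  expect_lm_error(overlap(v, rep(0, length(v))), "degenerate_input_error")
  expect_warning(overlap(2 * v, v), "normalized")
  expect_equal(suppressWarnings(overlap(2 * v, 3 * v)), 1.0)
})

test_that("cumulative overlap accumulates and saturates at 1", {
  modes <- tt_anm
  ref <- modes$vectors[, 5]
  expect_equal(cumulative_overlap(ref, modes, 4L), 0, tolerance = 1e-9)
  expect_equal(cumulative_overlap(ref, modes, 5L), 1, tolerance = 1e-9)
  expect_equal(cumulative_overlap(ref, modes, modes$k), 1, tolerance = 1e-9)
  expect_lm_error(cumulative_overlap(ref, modes, 0L), "index_error")
  expect_lm_error(cumulative_overlap(ref, modes, modes$k + 1L), "index_error")

  # brute-force accumulation oracle on a 12-dimensional toy basis
  set.seed(31)
  Q <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  toy <- list(vectors = Q, values = 12:1, k = 12L)
  class(toy) <- "mode_set"
  r <- rnorm(12); r <- r / sqrt(sum(r^2))
  co_oracle <- numeric(12)
  acc <- 0
  for (j in 1:12) {
    acc <- acc + abs(sum(r * Q[, j]))^2
    co_oracle[j] <- sqrt(acc)
  }
  got <- vapply(1:12, function(J) cumulative_overlap(r, toy, J), numeric(1))
  expect_equal(got, co_oracle, tolerance = 1e-12)
  expect_false(is.unsorted(got))          # monotone non-decreasing
  expect_equal(got[12], 1, tolerance = 1e-12)
})

test_that("Parseval: squared overlaps over a complete basis sum to one", {
  modes <- tt_anm
  set.seed(17)
  # reference orthogonal to the rigid-body space
  rb <- oracle_rigid_basis(tt_fold$model$xyz)
  z <- rnorm(180)
  z <- z - rb %*% crossprod(rb, z)
  z <- z / sqrt(sum(z^2))
  prof <- overlap_profile(z, modes)
  expect_equal(sum(prof$overlap^2), 1, tolerance = 1e-9)
  expect_equal(prof$cumulative[modes$k], 1, tolerance = 1e-9)
})

test_that("segment overlap is orientational and scale-free", {
  modes <- tt_anm
  loop <- tt_fold$loop
  keys <- modes$keys
  v <- modes$vectors[, 2]
  expect_equal(segment_overlap(v, v, loop, keys = keys), 1.0)
  expect_equal(segment_overlap(v, modes, loop, keys = keys, j = 2), 1.0)
  # invariance to global scaling of either argument
  w <- tt_defvec
  expect_equal(segment_overlap(7 * as.numeric(w), v, loop, keys = keys),
               segment_overlap(as.numeric(w), 0.1 * v, loop, keys = keys),
               tolerance = 1e-12)
  # a vector with no amplitude on the loop is degenerate there
  z <- v
  li <- segment_selection("A", loop$start_residue, loop$end_residue)
  idx <- which(keys$chain == "A" & keys$resno >= li$start_residue &
                 keys$resno <= li$end_residue)
  z[as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))] <- 0
  expect_lm_error(segment_overlap(z, v, loop, keys = keys),
                  "degenerate_segment_error")
})

test_that("weighted-average overlap is the declared convex combination", {
  modes <- tt_anm
  loop <- tt_fold$loop
  ref <- tt_defvec

  # endpoint: a single-mode window reduces to the segment overlap
  expect_equal(weighted_average_overlap(ref, modes, loop, mode_window = 3L),
               segment_overlap(ref, modes, loop, keys = modes$keys, j = 3L),
               tolerance = 1e-12)

  # hand-computed oracle over a 5-mode window
  win <- 1:5
  keys <- modes$keys
  idx <- which(keys$chain == loop$chain & keys$resno >= loop$start_residue &
                 keys$resno <= loop$end_residue)
  vi <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  o <- w <- numeric(5)
  for (t in seq_along(win)) {
    j <- win[t]
    a <- ref[vi]; b <- modes$vectors[vi, j]
    o[t] <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    w[t] <- sum(b^2) / modes$values[j]
  }
  expect_equal(weighted_average_overlap(ref, modes, loop, win),
               sum(w * o) / sum(w), tolerance = 1e-12)

  # a reference built parallel to every window mode on the segment gives 1
  par <- numeric(180)
  par[vi] <- modes$vectors[vi, 1]
  expect_equal(weighted_average_overlap(par, modes, loop, mode_window = 1L), 1,
               tolerance = 1e-12)

  # alternative weighting schemes stay in [0, 1]
  for (sch in c("amplitude", "uniform")) {
    val <- weighted_average_overlap(ref, modes, loop, win, weighting = sch)
    expect_gte(val, 0); expect_lte(val, 1)
  }
  expect_lm_error(weighted_average_overlap(ref, modes, loop, 200L), "window_error")
})

test_that("mode-window profiles match per-window recomputation and decay", {
  modes <- tt_anm
  loop <- tt_fold$loop
  ref <- tt_defvec

  prof <- mode_window_profile(ref, modes, loop, p = 10L)
  expect_equal(nrow(prof), modes$k - 9L)
  recompute <- vapply(seq_len(nrow(prof)), function(s)
    weighted_average_overlap(ref, modes, loop, s:(s + 9L)), numeric(1))
  expect_equal(prof$value, recompute, tolerance = 1e-12)

  # planted along mode 1: the softest window dominates the spectrum tail
  expect_equal(which.max(prof$value), 1L)
  expect_gt(prof$value[1], mean(prof$value[-(1:10)]) * 2)

  # k = p: single entry
  small <- list(vectors = modes$vectors[, 1:10], values = modes$values[1:10],
                k = 10L, keys = modes$keys, N = modes$N,
                ref_xyz = modes$ref_xyz)
  class(small) <- "mode_set"
  expect_equal(nrow(mode_window_profile(ref, small, loop, p = 10L)), 1L)
})

test_that("random mode sets are orthonormal, seeded and unbiased", {
  xyz <- tt_fold$model$xyz
  sets <- random_modeset(xyz, tt_anm$values[1:10], count = 2, seed = 99)
  rb <- oracle_rigid_basis(xyz)
  for (rs in sets) {
    G <- crossprod(rs$vectors)
    expect_lt(max(abs(G - diag(10))), 1e-10)
    expect_lt(max(abs(crossprod(rb, rs$vectors))), 1e-10)
    expect_equal(rs$values, tt_anm$values[1:10])
  }
  again <- random_modeset(xyz, tt_anm$values[1:10], count = 2, seed = 99)
  expect_identical(sets[[1]]$vectors, again[[1]]$vectors)
  other <- random_modeset(xyz, tt_anm$values[1:10], count = 1, seed = 100)
  expect_gt(max(abs(sets[[1]]$vectors - other[[1]]$vectors)), 1e-6)

  # E[squared overlap] of a rigid-body-free random unit vector with a fixed
  # unit vector is 1/(3N - 6)
  n <- 20
  fold2 <- make_toy_fold(30, 6, seed = 5)
  xyz2 <- fold2$model$xyz[1:n, ]
  fixed <- rnorm(3 * n)
  rb2 <- oracle_rigid_basis(xyz2)
  fixed <- fixed - rb2 %*% crossprod(rb2, fixed)
  fixed <- fixed / sqrt(sum(fixed^2))
  draws <- random_modeset(xyz2, 1, count = 2000, seed = 1234)
  o2 <- vapply(draws, function(rs) sum(fixed * rs$vectors[, 1])^2, numeric(1))
  d <- 3 * n - 6
  se <- sd(o2) / sqrt(length(o2))
  expect_lt(abs(mean(o2) - 1 / d), 3 * se)

  expect_lm_error(random_modeset(xyz2, -1, count = 1, seed = 1), "parameter_error")
  expect_lm_error(random_modeset(xyz2[1:3, ], rep(1, 5), count = 1, seed = 1),
                  "dimension_error")
})

test_that("random_modeset leaves the caller's RNG state untouched", {
  set.seed(555)
  before <- .Random.seed
  invisible(random_modeset(tt_fold$model$xyz, 1, count = 1, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("enhancement analysis recovers the planted coupling and respects the null", {
  enh <- enhancement_analysis(tt_defvec, tt_anm, tt_fold$loop, p = 10L,
                              n_random = 60, seed = 2024)
  expect_s3_class(enh, "enhancement_analysis")
  expect_gt(enh$enhancement_factor, 2)          # planted coupling recovered
  expect_equal(enh$s, 11L)

  # the difference profile peaks at (or inside) the planted loop
  prof <- enh$profile
  peak <- prof$window_start[which.max(prof$difference)]
  loop_windows <- (tt_fold$loop$start_residue - enh$s + 1):tt_fold$loop$end_residue
  expect_true(peak %in% loop_windows)
  expect_true(all(prof$anm >= 0 & prof$anm <= 1))
  expect_true(all(prof$random >= 0 & prof$random <= 1))

  # null self-consistency: random references are not enhanced on average
  # (a single random reference has a large Monte-Carlo spread, so average
  # the enhancement ratio over 20 of them)
  set.seed(4096)
  rb <- oracle_rigid_basis(tt_fold$model$xyz)
  rand_sets <- random_modeset(tt_fold$model$xyz, tt_anm$values[1:10],
                              count = 100, seed = 77, keys = tt_anm$keys)
  ratios <- vapply(1:20, function(i) {
    z <- rnorm(180); z <- z - rb %*% crossprod(rb, z); z <- z / sqrt(sum(z^2))
    a <- weighted_average_overlap(z, tt_anm, tt_fold$loop, 1:10)
    b <- mean(vapply(rand_sets, function(rs)
      weighted_average_overlap(z, rs, tt_fold$loop, 1:10), numeric(1)))
    a / b
  }, numeric(1))
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 1.5)
})

test_that("the per-mode overlap profile is maximal at the planted mode", {
  prof <- overlap_profile(tt_defvec, tt_anm, "deformation")
  expect_equal(which.max(prof$overlap), tt_truth$driver_mode_index)
  loop_ov <- segment_overlap(tt_pca$vectors[, 1], tt_anm, tt_fold$loop,
                             keys = tt_anm$keys, j = tt_truth$driver_mode_index)
  expect_gt(loop_ov, 0.9)
})
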