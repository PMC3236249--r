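test_that("CRCM entries are absolute Pearson correlations with block structure", {
  # hand-checked correlation: cor((1,2,3), (1,2,4)) = 1.5/(1*sqrt(7/3))
  x <- matrix(c(1, 2, 3), 1, 3)
  y <- matrix(c(1, 2, 4), 1, 3)
  cr <- compute_crcm(list(component_set(x), component_set(y)))
  expect_equal(cr$values[1, 2], 0.98198051, tolerance = 1e-7)

  # identical runs: off-diagonal block has 1 exactly at matching positions
  runs <- noise_runs(1, 3, 50, seed = 1)
  cr2 <- compute_crcm(list(runs[[1]], runs[[1]]))
  blk <- cr2$values[1:3, 4:6]
  expect_equal(diag(blk), rep(1, 3), tolerance = 1e-12)
  expect_true(all(blk[row(blk) != col(blk)] < 1))

  # sign invariance: a component and its negation correlate at 1
  neg <- component_set(-runs[[1]]$maps)
  cr3 <- compute_crcm(list(runs[[1]], neg))
  expect_equal(diag(cr3$values[1:3, 4:6]), rep(1, 3), tolerance = 1e-12)

  # symmetry, range, unit diagonal
  expect_true(isSymmetric(cr3$values))
  expect_true(all(cr3$values >= 0 & cr3$values <= 1))
  expect_equal(diag(cr3$values), rep(1, 6))

  expect_error(compute_crcm(runs[1]), "insufficient runs")
})

test_that("zero-variance components yield 0 CRCM entries everywhere", {
  a <- component_set(rbind(rnorm(40), rep(1, 40)))
  b <- component_set(matrix(rnorm(80), 2, 40))
  cr <- compute_crcm(list(a, b))
  expect_true(all(cr$values[2, ] == 0))
  expect_true(all(cr$values[, 2] == 0))
  expect_true(all(is.finite(cr$values)))
})

test_that("within-run blocks can be omitted and are then flagged", {
  runs <- noise_runs(2, 3, 60, seed = 2)
  cr <- compute_crcm(runs, include_within_run = FALSE)
  expect_false(cr$within_run_available)
  expect_true(all(is.na(cr$values[1:3, 1:3])))
  expect_false(anyNA(cr$values[1:3, 4:6]))
})

test_that("greedy matching reproduces hand-enumerated 2-run assignments", {
  # between-run block [[0.9, 0.1], [0.2, 0.8]]: best assignment in both
  # greedy and exhaustive enumeration is (c1, c1) then (c2, c2)
  v <- diag(4)
  v[1:2, 3:4] <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  v[3:4, 1:2] <- t(v[1:2, 3:4])
  m <- raicar_match(crcm_from_values(v, R = 2, K = 2))
  expect_equal(m[[1]]$members, c(1, 1))
  expect_equal(m[[1]]$r_norm, 0.9)
  expect_equal(m[[2]]$members, c(2, 2))
  expect_equal(m[[2]]$r_norm, 0.8)

  # block [[0.5, 0.9], [0.85, 0.6]]: greedy takes the cross pairs
  v2 <- diag(4)
  v2[1:2, 3:4] <- rbind(c(0.5, 0.9), c(0.85, 0.6))
  v2[3:4, 1:2] <- t(v2[1:2, 3:4])
  m2 <- raicar_match(crcm_from_values(v2, R = 2, K = 2))
  expect_equal(m2[[1]]$members, c(1, 2))
  expect_equal(m2[[1]]$r_norm, 0.9)
  expect_equal(m2[[2]]$members, c(2, 1))
  expect_equal(m2[[2]]$r_norm, 0.85)
})

test_that("identical runs match component-wise with all-ones phi", {
  runs <- noise_runs(1, 4, 80, seed = 3)
  m <- raicar_match(compute_crcm(list(runs[[1]], runs[[1]], runs[[1]])))
  for (mc in m) {
    expect_equal(mc$members, rep(mc$members[1], 3))
    expect_equal(mc$phi, matrix(1, 3, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mc$r_norm, 1, tolerance = 1e-10)
  }
})

test_that("matching rejects degenerate or invalid CRCMs", {
  v <- diag(4)
  v[1, 3] <- NaN
  expect_error(raicar_match(crcm_from_values(v, 2, 2)), "NaN")
  cr <- compute_crcm(noise_runs(2, 2, 30, seed = 4))
  cr$values[1, 3] <- NA
  expect_error(raicar_match(cr), "NA")
})

test_that("matched components always partition the (run, component) pairs", {
  shapes <- withr::with_seed(9, cbind(R = sample(2:5, 20, TRUE),
                                      K = sample(2:6, 20, TRUE)))
  for (i in 1:20) {
    R <- unname(shapes[i, "R"]); K <- unname(shapes[i, "K"])
    m <- raicar_match(random_crcm(R, K, seed = i))
    expect_partition(m, R, K)
  }
})

test_that("matching is invariant to within-run component relabeling", {
  runs <- noise_runs(3, 4, 200, seed = 5)
  m0 <- raicar_match(compute_crcm(runs))
  perm <- c(3, 1, 4, 2)
  runs_p <- runs
  runs_p[[2]] <- component_set(runs[[2]]$maps[perm, ], "perm2")
  m1 <- raicar_match(compute_crcm(runs_p))
  for (k in seq_along(m0)) {
    expect_equal(m0[[k]]$members[-2], m1[[k]]$members[-2])
    # member of run 2 relabeled by the permutation
    expect_equal(m0[[k]]$members[2], perm[m1[[k]]$members[2]])
    expect_equal(m0[[k]]$r_norm, m1[[k]]$r_norm, tolerance = 1e-12)
  }
})

test_that("matched_similarity and normalized_reproducibility follow their definitions", {
  cr <- random_crcm(3, 3, seed = 6)
  m <- raicar_match(cr)
  phi <- matched_similarity(m[[1]], cr)
  expect_equal(diag(phi), rep(1, 3))
  expect_true(isSymmetric(unname(phi)))
  expect_equal(normalized_reproducibility(phi), mean(phi[upper.tri(phi)]))
  expect_error(matched_similarity(c(1, 99, 2), cr), "out of range")

  # hand example: off-diagonals 0.9, 0.8, 0.7 average to 0.8
  phi3 <- diag(3)
  phi3[1, 2] <- phi3[2, 1] <- 0.9
  phi3[1, 3] <- phi3[3, 1] <- 0.8
  phi3[2, 3] <- phi3[3, 2] <- 0.7
  expect_equal(normalized_reproducibility(phi3), 0.8)
  expect_equal(normalized_reproducibility(matrix(1, 4, 4)), 1)
  expect_equal(normalized_reproducibility(diag(2) + 0.42 - 0.42 * diag(2)),
               0.42)
  expect_error(normalized_reproducibility(matrix(1, 1, 1)), "R >= 2")
})

test_that("sign alignment recovers planted polarity flips", {
  base <- noise_runs(1, 3, 100, seed = 7)[[1]]
  maps2 <- base$maps; maps2[2, ] <- -maps2[2, ]
  flipped <- component_set(maps2, "flip")
  runs <- list(base, base, flipped)
  s_same <- sign_align(c(1, 1, 1), runs)
  expect_equal(s_same, c(1L, 1L, 1L))
  s_flip <- sign_align(c(2, 2, 2), runs)
  expect_equal(s_flip[1:2], c(1L, 1L))
  expect_equal(s_flip[3], -1L)
})

test_that("sign alignment follows the raw correlation to the reference", {
  withr::with_seed(8, {
    x <- rnorm(200)
    r1 <- component_set(rbind(x + 0.1 * rnorm(200)))
    r2 <- component_set(rbind(x + 0.2 * rnorm(200)))
    r3 <- component_set(rbind(-x + 0.2 * rnorm(200)))
    s <- sign_align(c(1, 1, 1), list(r1, r2, r3))
    expect_equal(s, c(1L, 1L, -1L))
  })
})
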