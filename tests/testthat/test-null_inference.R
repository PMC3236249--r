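test_that("label permutation reorders the CRCM without changing its content", {
  cr <- compute_crcm(noise_runs(3, 3, 100, seed = 11))
  # identity permutation leaves values untouched
  idp <- permute_run_labels(cr, perm = seq_len(9))
  expect_equal(idp$values, cr$values)
  # fixed seed reproduces the draw
  p1 <- permute_run_labels(cr, seed = 99)
  p2 <- permute_run_labels(cr, seed = 99)
  expect_identical(p1$perm, p2$perm)
  expect_equal(p1$values, p2$values)
  # the multiset of entries is preserved under any permutation
  expect_equal(sort(as.numeric(p1$values)), sort(as.numeric(cr$values)))
  # pseudo-run structure is consecutive blocks; original identities kept
  expect_equal(p1$run_of_index, rep(1:3, each = 3))
  expect_setequal(p1$orig_comp + (p1$orig_run - 1) * 3, 1:9)
})

test_that("permutation null demands stored within-run correlations", {
  cr <- compute_crcm(noise_runs(3, 3, 80, seed = 12),
                     include_within_run = FALSE)
  expect_error(permute_run_labels(cr, seed = 1), "include_within_run = TRUE")
  expect_error(null_pool(cr, 5, seed = 1), "include_within_run = TRUE")
})

test_that("null pool has length n_sims * K, values in [0, 1], reproducible", {
  cr <- compute_crcm(noise_runs(3, 5, 120, seed = 13))
  pool <- null_pool(cr, n_sims = 2, seed = 5)
  expect_length(pool, 10L)
  expect_true(all(pool >= 0 & pool <= 1))
  expect_equal(as.numeric(pool), as.numeric(null_pool(cr, 2, seed = 5)))
  expect_error(null_pool(cr, 0, seed = 1), "n_sims")
})

test_that("null r_norm can reach 1 when duplicated data is split across pseudo-runs", {
  run <- noise_runs(1, 2, 60, seed = 14)[[1]]
  cr <- compute_crcm(list(run, run))
  # split both duplicated pairs across the two pseudo-runs: pseudo-run 1
  # holds (run1 comp1, run2 comp2), pseudo-run 2 holds (run1 comp2,
  # run2 comp1), so each component can match its own duplicate
  perm <- c(1L, 4L, 2L, 3L)
  m <- raicar_match(permute_run_labels(cr, perm = perm))
  r <- vapply(m, `[[`, 0, "r_norm")
  expect_equal(sort(r, decreasing = TRUE)[1:2], c(1, 1), tolerance = 1e-10)
})

test_that("under exchangeability the null pool mean tracks the observed mean", {
  # iid noise: observed and permuted reproducibility are exchangeable
  cr <- compute_crcm(noise_runs(10, 8, 2000, seed = 15))
  obs <- vapply(raicar_match(cr), `[[`, 0, "r_norm")
  pool <- null_pool(cr, n_sims = 40, seed = 16)
  mc_se <- stats::sd(pool) / sqrt(length(pool) / cr$K)  # K values per sim share a permutation
  expect_lt(abs(mean(pool) - mean(obs)), 3 * mc_se + 0.01)
})

test_that("p-values follow the inclusive counting rule", {
  pool <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.65, 0.7, 0.75, 0.79)
  # all ten null values below the observed 0.8
  p <- reproducibility_pvalues(0.8, pool)
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "p_text"), "<0.1")
  # a pool value equal to the observed counts (inclusive comparison)
  expect_equal(as.numeric(reproducibility_pvalues(0.5, pool)), 0.6)
  # direct count: 3 of 10 >= 0.68
  expect_equal(as.numeric(reproducibility_pvalues(0.68, pool)), 0.3)
  # smoothed variant adds the +1 pseudo-count
  expect_equal(as.numeric(reproducibility_pvalues(0.8, pool, smoothed = TRUE)),
               1 / 11)
  expect_error(reproducibility_pvalues(0.5, numeric(0)), "empty")
})

test_that("selection is strict at alpha and supports BH adjustment", {
  p <- c(0.001, 0.04, 0.05, 0.9)
  expect_equal(select_reproducible(p, alpha = 0.05), c(1L, 2L))
  expect_equal(select_reproducible(p, alpha = 1), 1:4)
  expect_length(select_reproducible(rep(0.5, 4), alpha = 0.05), 0L)
  expect_equal(select_reproducible(p, alpha = 0.05, adjust = "BH"),
               which(p.adjust(p, "BH") < 0.05))
})

test_that("two-group matching on duplicated runs preserves structure and r_norm = 1", {
  # with exact duplicates the permutation null itself saturates at 1, so
  # inclusive p-values stay large; the matching structure is still exact
  runs <- noise_runs(1, 3, 150, seed = 17)
  dupA <- list(runs[[1]], runs[[1]], runs[[1]])
  dupB <- list(runs[[1]], runs[[1]], runs[[1]])
  tab <- two_group_reproducibility(dupA, dupB, n_sims = 30, seed = 18)
  expect_equal(tab$r_norm, rep(1, 3), tolerance = 1e-10)
  expect_equal(tab$r_norm_A, rep(1, 3), tolerance = 1e-10)
  expect_equal(tab$r_norm_B, rep(1, 3), tolerance = 1e-10)
  expect_partition(attr(tab, "matches"), R = 6, K = 3)
  expect_error(two_group_reproducibility(dupA[1], dupB, seed = 1),
               "at least 2 runs")
})

test_that("sources planted strongly in both groups are flagged in both", {
  # groups of 6 runs: the structure-preserving null then reassembles a
  # planted 6-member cluster rarely enough for p to clear alpha
  sim <- generate_runs(synthetic_spec(R = 12, K = 4, V = 800, n_planted = 2,
                                      snr = 5, seed = 22))
  tab <- two_group_reproducibility(sim$runs[1:6], sim$runs[7:12],
                                   n_sims = 50, seed = 24)
  both_ranks <- order(tab$r_norm_A + tab$r_norm_B, decreasing = TRUE)[1:2]
  expect_true(all(tab$selected_A[both_ranks]))
  expect_true(all(tab$selected_B[both_ranks]))
  expect_true(all(tab$both[both_ranks]))
})

test_that("a source planted only in group A is flagged in A, not in B", {
  specA <- synthetic_spec(R = 5, K = 4, V = 1000, n_planted = 1, snr = 4,
                          seed = 19)
  simA <- generate_runs(specA)
  runsB <- noise_runs(5, 4, 1000, seed = 20)
  tab <- two_group_reproducibility(simA$runs, runsB, n_sims = 50, seed = 21)
  planted_rank <- which.max(tab$r_norm_A)
  expect_true(tab$selected_A[planted_rank])
  expect_false(tab$selected_B[planted_rank])
})
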