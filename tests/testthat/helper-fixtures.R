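# Small in-code fixtures shared across test files.

# R runs of pure iid Gaussian noise maps.
noise_runs <- function(R, K, V, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(R), function(r) {
      component_set(matrix(rnorm(K * V), K, V), sprintf("noise%02d", r))
    })
  })
}

# Build a crcm object directly from an explicit RK x RK value matrix,
# bypassing compute_crcm — used to exercise matching on hand-made blocks.
crcm_from_values <- function(values, R, K, within = TRUE) {
  structure(list(values = values, R = R, K = K,
                 run_of_index = rep(seq_len(R), each = K),
                 comp_of_index = rep(seq_len(K), R),
                 within_run_available = within,
                 run_ids = paste0("run", seq_len(R))),
            class = "crcm")
}

# A random valid CRCM with distinct between-run entries and unit diagonal.
random_crcm <- function(R, K, seed) {
  n <- R * K
  withr::with_seed(seed, {
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2 + 1)
    v <- v + t(v)
    diag(v) <- 1
    crcm_from_values(v, R, K)
  })
}

expect_partition <- function(matches, R, K) {
  pairs <- do.call(rbind, lapply(matches, function(m) {
    cbind(run = seq_len(R), comp = m$members)
  }))
  expect_equal(nrow(pairs), R * K)
  expect_equal(nrow(unique(as.data.frame(pairs))), R * K)
  for (r in seq_len(R)) {
    expect_setequal(pairs[pairs[, "run"] == r, "comp"], seq_len(K))
  }
}
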