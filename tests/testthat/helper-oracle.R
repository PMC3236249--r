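# Independent re-implementation of the greedy across-run matching, written
# as a literal transcription of the published step list over explicit
# per-run-pair block matrices G[[j]][[k]]. Deliberately coded differently
# from raicar_match (blocks instead of one flat matrix) so the two can
# cross-check each other.
oracle_match <- function(crcm) {
  R <- crcm$R; K <- crcm$K
  idx <- function(r) (r - 1L) * K + seq_len(K)
  # explicit block decomposition; diagonal blocks zeroed (cannot match
  # within a run)
  G <- lapply(seq_len(R), function(j) {
    lapply(seq_len(R), function(k) {
      b <- crcm$values[idx(j), idx(k), drop = FALSE]
      if (j == k) b[] <- 0
      b
    })
  })
  out <- vector("list", K)
  for (cc in seq_len(K)) {
    # step 1: global maximal element over off-diagonal blocks j < k
    best <- c(-1, 0, 0, 0, 0)  # value, j, k, m, n
    for (j in seq_len(R - 1)) for (k in (j + 1):R) {
      b <- G[[j]][[k]]
      mx <- max(b)
      if (mx > best[1]) {
        pos <- which(b == mx, arr.ind = TRUE)
        pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
        best <- c(mx, j, k, pos[1, 1], pos[1, 2])
      }
    }
    if (best[1] < 0) stop("oracle: nothing left to match")
    j <- best[2]; k <- best[3]; m <- best[4]; n <- best[5]
    members <- integer(R); members[j] <- m; members[k] <- n
    # step 2: for every other run q, compare the best match to component m
    # of run j (column search) against the best match to component n of run
    # k (row search); larger correlation wins, ties to the smaller index
    for (q in setdiff(seq_len(R), c(j, k))) {
      col_j <- G[[q]][[j]][, m]   # candidates in run q against (j, m)
      col_k <- G[[q]][[k]][, n]   # candidates in run q against (k, n)
      a_idx <- which.max(col_j); b_idx <- which.max(col_k)
      chosen <- if (a_idx == b_idx) a_idx
      else if (col_j[a_idx] > col_k[b_idx]) a_idx
      else if (col_k[b_idx] > col_j[a_idx]) b_idx
      else min(a_idx, b_idx)
      members[q] <- chosen
      # step 3: remove (q, chosen) from all blocks
      for (r2 in seq_len(R)) {
        G[[q]][[r2]][chosen, ] <- 0
        G[[r2]][[q]][, chosen] <- 0
      }
    }
    # eliminate the seed components too
    for (r2 in seq_len(R)) {
      G[[j]][[r2]][m, ] <- 0; G[[r2]][[j]][, m] <- 0
      G[[k]][[r2]][n, ] <- 0; G[[r2]][[k]][, n] <- 0
    }
    phi <- diag(R)
    for (r1 in seq_len(R - 1)) for (r2 in (r1 + 1):R) {
      v <- crcm$values[(r1 - 1L) * K + members[r1],
                       (r2 - 1L) * K + members[r2]]
      phi[r1, r2] <- v; phi[r2, r1] <- v
    }
    # normalized reproducibility: upper-triangle sum over R(R-1)/2
    out[[cc]] <- list(members = members,
                      r_norm = sum(phi[upper.tri(phi)]) / (R * (R - 1) / 2))
  }
  out
}
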