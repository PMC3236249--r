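#' Cross-realization correlation matrix (CRCM)
#'
#' Computes the RK x RK block matrix of absolute Pearson spatial correlations
#' between every component of every run. Block (j, k) holds the K x K
#' absolute correlations between run j's and run k's maps. Within-run
#' (diagonal-block) correlations are computed and stored by default: the
#' matching step masks them, but the permutation null re-partitions labels
#' into pseudo-runs, where a pseudo-run pair may originate from one original
#' run, so the entries must exist.
#'
#' Zero-variance components have undefined correlations; their entries
#' (including the diagonal) are defined as 0, so they sort to the bottom of
#' the matching instead of desynchronising component indices.
#'
#' @param runs list of \code{\link{component_set}} (or K x V matrices), all
#'   with identical K and V; at least two runs.
#' @param include_within_run logical; populate diagonal blocks (default
#'   \code{TRUE}). With \code{FALSE} they are stored as \code{NA} and the
#'   permutation null is unavailable until recomputation.
#' @return object of class \code{crcm}: list with \code{values} (RK x RK),
#'   \code{R}, \code{K}, \code{run_of_index}, \code{comp_of_index},
#'   \code{within_run_available}, \code{run_ids}.
#' @export
compute_crcm <- function(runs, include_within_run = TRUE) {
  runs <- as_component_runs(runs)
  R <- length(runs)
  if (R < 2L) stop("insufficient runs: at least 2 runs are required, got ", R)
  K <- runs[[1]]$K
  X <- do.call(rbind, lapply(runs, `[[`, "maps"))
  sds <- row_sds(X)
  zero <- sds == 0
  vals <- matrix(0, nrow(X), nrow(X))
  if (any(!zero)) {
    cc <- stats::cor(t(X[!zero, , drop = FALSE]))
    vals[!zero, !zero] <- abs(cc)
  }
  vals[vals > 1] <- 1   # guard against rounding just above 1
  run_of_index <- rep(seq_len(R), each = K)
  if (!include_within_run) {
    same <- outer(run_of_index, run_of_index, "==")
    vals[same] <- NA_real_
  }
  structure(list(values = vals, R = R, K = K,
                 run_of_index = run_of_index,
                 comp_of_index = rep(seq_len(K), R),
                 within_run_available = include_within_run,
                 run_ids = vapply(runs, `[[`, "", "run_id")),
            class = "crcm")
}

#' @export
print.crcm <- function(x, ...) {
  cat("<crcm> ", x$R, " runs x ", x$K, " components (",
      x$R * x$K, " x ", x$R * x$K, ")",
      if (!x$within_run_available) ", within-run blocks not computed" else "",
      "\n", sep = "")
  invisible(x)
}

crcm_flat_index <- function(crcm, run, comp) (run - 1L) * crcm$K + comp

# Validate a crcm-like object before matching.
check_crcm <- function(crcm) {
  if (!inherits(crcm, "crcm")) stop("expected a 'crcm' object")
  v <- crcm$values
  if (any(is.nan(v))) stop("CRCM contains NaN entries")
  between <- outer(crcm$run_of_index, crcm$run_of_index, "!=")
  if (anyNA(v[between])) stop("CRCM contains NA between-run entries")
  if (any(v[between] < 0 | v[between] > 1)) {
    stop("CRCM entries must lie in [0, 1]")
  }
  invisible(crcm)
}

#' Greedy across-run component matching
#'
#' The RAICAR matching procedure: within-run entries are masked (components
#' of one run cannot match each other); then, repeatedly, (1) the global
#' maximal between-run entry seeds a matched pair; (2) for every remaining
#' run the best match to each of the two seed components is found, and if
#' the two candidates disagree the one with the larger correlation to its
#' seed wins (ties: smaller component index); (3) each matched component's
#' row and column are eliminated from further consideration; (4) repeat
#' until K matched components partition all RK (run, component) pairs.
#' Matching operates on a working copy — the input CRCM is never mutated.
#'
#' @param crcm a \code{\link{compute_crcm}} result (possibly permuted by
#'   \code{\link{permute_run_labels}}).
#' @return object of class \code{raicar_matches}: a list of K matched
#'   components ordered by extraction rank, each with \code{rank},
#'   \code{members} (component index per run), \code{members_flat} (flat
#'   CRCM indices), \code{phi} (R x R absolute-correlation matrix among
#'   members) and \code{r_norm}; attributes \code{R}, \code{K}.
#' @export
raicar_match <- function(crcm) {
  check_crcm(crcm)
  R <- crcm$R; K <- crcm$K
  if (R < 2L) stop("insufficient runs for matching")
  W <- crcm$values
  same <- outer(crcm$run_of_index, crcm$run_of_index, "==")
  W[same] <- -Inf
  W[is.na(W)] <- -Inf
  run_cols <- lapply(seq_len(R), function(r) which(crcm$run_of_index == r))

  matched <- vector("list", K)
  for (rank in seq_len(K)) {
    mx <- max(W)
    if (!is.finite(mx)) stop("no between-run entries available for matching")
    cand <- which(W == mx, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    members <- integer(R)
    members[crcm$run_of_index[i]] <- i
    members[crcm$run_of_index[j]] <- j
    for (r in setdiff(seq_len(R), crcm$run_of_index[c(i, j)])) {
      cols <- run_cols[[r]]
      a <- W[i, cols]; b <- W[j, cols]
      ia <- which.max(a); ib <- which.max(b)  # first max = smallest comp index
      pick <- if (cols[ia] == cols[ib]) {
        cols[ia]
      } else if (a[ia] > b[ib]) {
        cols[ia]
      } else if (b[ib] > a[ia]) {
        cols[ib]
      } else {
        min(cols[ia], cols[ib])
      }
      members[r] <- pick
      W[pick, ] <- -Inf
      W[, pick] <- -Inf
    }
    W[members, ] <- -Inf
    W[, members] <- -Inf
    phi <- matched_phi(members, crcm)
    matched[[rank]] <- list(rank = rank,
                            members = crcm$comp_of_index[members],
                            members_flat = members,
                            phi = phi,
                            r_norm = upper_tri_mean(phi))
  }
  structure(matched, class = "raicar_matches", R = R, K = K)
}

#' @export
print.raicar_matches <- function(x, ...) {
  cat("<raicar_matches> ", attr(x, "K"), " matched components across ",
      attr(x, "R"), " runs\n", sep = "")
  r <- vapply(x, `[[`, 0, "r_norm")
  cat("  r_norm by rank:", paste(sprintf("%.3f", r), collapse = " "), "\n")
  invisible(x)
}

# phi from stored CRCM values given flat member indices (one per run).
matched_phi <- function(members_flat, crcm) {
  phi <- crcm$values[members_flat, members_flat, drop = FALSE]
  if (anyNA(phi)) {
    stop("matched members require within-run correlations that were not ",
         "computed; recompute the CRCM with include_within_run = TRUE")
  }
  diag(phi) <- 1
  phi
}

#' Pairwise similarity matrix of one matched component
#'
#' phi[j, k] is the absolute correlation between the members of runs j and
#' k, looked up in the stored CRCM; the diagonal is 1.
#'
#' @param matched one element of a \code{\link{raicar_match}} result (a list
#'   with \code{members_flat}), or an integer vector of flat indices.
#' @param crcm the CRCM the matching was computed from.
#' @return R x R symmetric matrix with unit diagonal.
#' @export
matched_similarity <- function(matched, crcm) {
  members <- if (is.list(matched)) matched$members_flat else as.integer(matched)
  if (any(members < 1L | members > nrow(crcm$values))) {
    stop("member index out of range")
  }
  matched_phi(members, crcm)
}

#' Normalized reproducibility of a matched component
#'
#' The sum of the strict upper triangle of the R x R similarity matrix,
#' divided by its maximum possible value R(R-1)/2 — i.e. the mean
#' off-diagonal absolute correlation among the matched members. Raw
#' (un-thresholded) correlations are averaged; the statistic lies in [0, 1]
#' and equals 1 exactly when all members are perfectly correlated.
#'
#' @param phi R x R symmetric similarity matrix with entries in [0, 1].
#' @return scalar in [0, 1].
#' @export
normalized_reproducibility <- function(phi) {
  phi <- as.matrix(phi)
  if (nrow(phi) < 2L) stop("normalized reproducibility requires R >= 2 runs")
  if (!isSymmetric(unname(phi), tol = 1e-8)) stop("phi must be symmetric")
  if (any(phi < 0 | phi > 1)) stop("phi entries must lie in [0, 1]")
  upper_tri_mean(phi)
}

#' Sign-align the members of a matched component
#'
#' Absolute correlations discard sign, but averaging maps across runs needs
#' consistent polarity. The reference run is the member with the largest
#' summed absolute raw correlation to the other members; every member's sign
#' is the sign of its raw (non-absolute) correlation with the reference
#' (zero correlation maps to +1; the reference itself is +1).
#'
#' @param matched one matched component (list with \code{members}) or an
#'   integer vector giving the member component index per run.
#' @param runs the list of \code{\link{component_set}} the matching was run on.
#' @return integer vector of length R with values in \{-1, +1\}.
#' @export
sign_align <- function(matched, runs) {
  runs <- as_component_runs(runs)
  members <- if (is.list(matched)) matched$members else as.integer(matched)
  R <- length(runs)
  if (length(members) != R) stop("need one member per run")
  M <- vapply(seq_len(R), function(r) {
    if (members[r] < 1L || members[r] > runs[[r]]$K) {
      stop("member index out of range for run '", runs[[r]]$run_id, "'")
    }
    runs[[r]]$maps[members[r], ]
  }, numeric(runs[[1]]$V))
  cc <- suppressWarnings(stats::cor(M))
  cc[!is.finite(cc)] <- 0   # zero-variance members
  ref <- which.max(rowSums(abs(cc)))
  s <- sign(cc[ref, ])
  s[s == 0] <- 1
  s[ref] <- 1
  as.integer(s)
}
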