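#' Randomly re-partition component labels into pseudo-runs
#'
#' The "no reproducibility" null states that any component of any run could
#' equally have come from any other run. It is simulated by drawing one
#' uniform permutation of the RK flat component labels and assigning
#' consecutive blocks of K permuted labels to pseudo-runs 1..R. Permuting
#' the stored CRCM's rows and columns is mathematically identical to
#' recomputing correlations on reshuffled maps, and orders of magnitude
#' faster — which is why within-run correlations must have been computed: a
#' permuted pseudo-run pair may originate from a single original run.
#'
#' @param crcm a \code{\link{compute_crcm}} result with
#'   \code{within_run_available = TRUE}.
#' @param seed integer seed for the permutation draw (ignored when
#'   \code{perm} is given).
#' @param perm optional explicit permutation of 1..RK.
#' @return a \code{crcm} whose rows/columns are reordered by the permutation
#'   and whose index maps describe the pseudo-run structure; original
#'   (run, component) identities are kept in \code{orig_run}/\code{orig_comp}.
#' @export
permute_run_labels <- function(crcm, seed = NULL, perm = NULL) {
  if (!inherits(crcm, "crcm")) stop("expected a 'crcm' object")
  if (!crcm$within_run_available) {
    stop("permutation null requires within-run correlations: recompute the ",
         "CRCM with include_within_run = TRUE (a permuted pair may ",
         "originate from one original run)")
  }
  n <- crcm$R * crcm$K
  if (is.null(perm)) {
    perm <- with_seed(seed, sample.int(n))
  }
  if (!identical(sort(as.integer(perm)), seq_len(n))) {
    stop("perm must be a permutation of 1..", n)
  }
  out <- crcm
  out$values <- crcm$values[perm, perm, drop = FALSE]
  out$orig_run <- crcm$run_of_index[perm]
  out$orig_comp <- crcm$comp_of_index[perm]
  out$perm <- as.integer(perm)
  # pseudo-run structure: consecutive blocks of the permuted label sequence
  out$run_of_index <- rep(seq_len(crcm$R), each = crcm$K)
  out$comp_of_index <- rep(seq_len(crcm$K), crcm$R)
  out
}

#' Pooled null distribution of normalized reproducibility
#'
#' Repeats label permutation + matching \code{n_sims} times and pools all K
#' null reproducibility values per permutation into one vector of length
#' \code{n_sims * K}. Fully reproducible given (seed, n_sims): per-simulation
#' seeds are derived from the master seed.
#'
#' @param crcm CRCM with within-run correlations.
#' @param n_sims number of independent permutations (default 100).
#' @param seed master seed.
#' @return numeric vector of length \code{n_sims * K}, with attribute
#'   \code{n_sims}.
#' @export
null_pool <- function(crcm, n_sims = 100, seed = NULL) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  seeds <- derive_seeds(seed, n_sims)
  pool <- vapply(seq_len(n_sims), function(s) {
    m <- raicar_match(permute_run_labels(crcm, seed = seeds[s]))
    vapply(m, `[[`, 0, "r_norm")
  }, numeric(crcm$K))
  pool <- as.numeric(pool)
  attr(pool, "n_sims") <- as.integer(n_sims)
  pool
}

#' Permutation p-values for observed reproducibility
#'
#' p_c is the fraction of pooled null values greater than or equal to the
#' observed reproducibility of matched component c (inclusive comparison).
#' An observed value exceeding every null value yields p = 0; such results
#' are reported in text as "< 1/pool-length". A smoothed (+1 pseudo-count)
#' variant is available behind \code{smoothed}.
#'
#' @param observed length-K vector of observed r_norm values.
#' @param null_pool pooled null vector from \code{\link{null_pool}}.
#' @param smoothed logical; use (count + 1)/(pool + 1) instead of the plain
#'   count rule (default \code{FALSE}).
#' @return numeric vector of p-values with attribute \code{p_text}.
#' @export
reproducibility_pvalues <- function(observed, null_pool, smoothed = FALSE) {
  if (length(null_pool) == 0L) stop("null pool is empty")
  n <- length(null_pool)
  p <- vapply(observed, function(o) sum(null_pool >= o), 0) / n
  if (smoothed) p <- (p * n + 1) / (n + 1)
  attr(p, "p_text") <- ifelse(p == 0, sprintf("<%g", 1 / n),
                              formatC(p, format = "g", digits = 6))
  p
}

#' Select significantly reproducible components
#'
#' Components with p-value strictly below \code{alpha} are selected. The
#' cutoff is fixed and objective (default 0.05); optional Benjamini-Hochberg
#' adjustment is off by default — the raw cutoff is the reference behaviour.
#'
#' @param p_values numeric vector of p-values (or a \code{raicarn} fit).
#' @param alpha significance cutoff in (0, 1].
#' @param adjust "none" (default) or "BH".
#' @return integer vector of selected component ranks.
#' @export
select_reproducible <- function(p_values, alpha = 0.05, adjust = c("none", "BH")) {
  if (inherits(p_values, "raicarn")) p_values <- p_values$p_values
  adjust <- match.arg(adjust)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  p <- if (adjust == "BH") stats::p.adjust(p_values, "BH") else p_values
  which(p < alpha)
}

#' Two-group reproducibility comparison
#'
#' Components are matched across the pooled runs of groups A and B; each
#' matched component then receives a reproducibility score and permutation
#' p-value restricted to each group's own members (with the null built from
#' that group's own CRCM). Components significant in both groups at
#' \code{alpha} are flagged as candidates for between-group comparison.
#'
#' @param runsA,runsB lists of \code{\link{component_set}} (>= 2 runs each,
#'   identical V across all runs).
#' @param n_sims permutations per group null (default 100).
#' @param alpha significance cutoff (default 0.05).
#' @param seed master seed (split into per-group substreams).
#' @return data.frame with one row per matched component: rank, pooled
#'   r_norm, per-group r_norm and p-values, per-group selection flags and
#'   \code{both}; the matches object is attached as attribute
#'   \code{matches}.
#' @export
two_group_reproducibility <- function(runsA, runsB, n_sims = 100,
                                      alpha = 0.05, seed = NULL) {
  runsA <- as_component_runs(runsA)
  runsB <- as_component_runs(runsB)
  if (length(runsA) < 2L || length(runsB) < 2L) {
    stop("each group needs at least 2 runs")
  }
  pooled <- as_component_runs(c(runsA, runsB))
  RA <- length(runsA)
  crcm_all <- compute_crcm(pooled)
  matches <- raicar_match(crcm_all)
  seeds <- derive_seeds(seed, 2L)
  poolA <- null_pool(compute_crcm(runsA), n_sims, seeds[1])
  poolB <- null_pool(compute_crcm(runsB), n_sims, seeds[2])
  idxA <- seq_len(RA)
  idxB <- RA + seq_along(runsB)
  rA <- vapply(matches, function(m) upper_tri_mean(m$phi[idxA, idxA]), 0)
  rB <- vapply(matches, function(m) upper_tri_mean(m$phi[idxB, idxB]), 0)
  pA <- reproducibility_pvalues(rA, poolA)
  pB <- reproducibility_pvalues(rB, poolB)
  out <- data.frame(rank = seq_along(matches),
                    r_norm = vapply(matches, `[[`, 0, "r_norm"),
                    r_norm_A = rA, p_value_A = as.numeric(pA),
                    r_norm_B = rB, p_value_B = as.numeric(pB))
  out$selected_A <- out$p_value_A < alpha
  out$selected_B <- out$p_value_B < alpha
  out$both <- out$selected_A & out$selected_B
  attr(out, "matches") <- matches
  out
}
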