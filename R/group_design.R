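#' Probability that a fixed subject pair co-occurs in one random group
#'
#' For d subjects drawn uniformly without replacement from N, the
#' probability that two given subjects both appear is
#' C(N-2, d-2) / C(N, d) = d(d-1) / (N(N-1)). Computed on the log scale for
#' stability; both forms agree exactly over the practical range.
#'
#' @param N total number of subjects (>= 2).
#' @param d subjects per group, 2 <= d <= N.
#' @return probability in (0, 1].
#' @export
pair_cooccurrence <- function(N, d) {
  if (d < 2 || d > N) stop("require 2 <= d <= N (got d=", d, ", N=", N, ")")
  exp(lchoose(N - 2, d - 2) - lchoose(N, d))
}

#' Expected pair co-occurrences over G independent group draws
#'
#' @param N total subjects.
#' @param d subjects per group.
#' @param G number of independent group draws (>= 1).
#' @return expected count G * pair_cooccurrence(N, d).
#' @export
expected_cooccurrence <- function(N, d, G) {
  if (G < 1) stop("G must be >= 1")
  G * pair_cooccurrence(N, d)
}

#' Plan the per-group subject count for subsampled group ICA
#'
#' Running group ICA on G random d-subsets of N subjects requires the
#' subsets to be diverse: if any fixed pair of subjects co-occurs too often,
#' the runs are not close to independent realisations. The diversity
#' constant beta bounds the pair co-occurrence probability, and d is chosen
#' as the largest integer in [2, N] with d(d-1) <= beta * N(N-1). G should
#' be as large as the computational budget allows; beyond roughly 50 runs
#' results change little, so 50 is the default.
#'
#' @param N total subjects (>= 2).
#' @param beta diversity constant in (0, 1]; default 0.05.
#' @param G number of group draws the plan is evaluated for; default 50.
#' @return object of class \code{group_plan}: list(N, d, G, beta, p_pair,
#'   n_expected).
#' @export
plan_group_size <- function(N, beta = 0.05, G = 50) {
  if (N < 2) stop("N must be >= 2")
  if (!(beta > 0 && beta <= 1)) stop("beta must lie in (0, 1]")
  if (2 * 1 > beta * N * (N - 1)) {
    stop("no feasible group size: even d=2 violates the diversity bound; ",
         "the minimum beta admitting d=2 is ",
         format(2 / (N * (N - 1)), digits = 6))
  }
  d_cand <- 2:N
  d <- max(d_cand[d_cand * (d_cand - 1) <= beta * N * (N - 1)])
  p <- pair_cooccurrence(N, d)
  structure(list(N = as.integer(N), d = as.integer(d), G = as.integer(G),
                 beta = beta, p_pair = p, n_expected = G * p),
            class = "group_plan")
}

#' @export
print.group_plan <- function(x, ...) {
  cat("<group_plan> N=", x$N, " subjects, d=", x$d, " per group, G=", x$G,
      " groups (beta=", format(x$beta), ")\n",
      "  pair co-occurrence p=", format(x$p_pair, digits = 5),
      ", expected co-occurrences over G draws: ",
      format(x$n_expected, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Draw random subject groups
#'
#' G independent uniform d-subsets of 1..N — without replacement within a
#' group, independently across groups (a pair may co-occur in several
#' groups; the diversity constraint controls the expectation, not the
#' realisation). Deterministic under \code{seed}.
#'
#' @param N total subjects.
#' @param d subjects per group (2 <= d <= N).
#' @param G number of groups.
#' @param seed integer seed.
#' @return integer matrix G x d; each row a sorted group of distinct subjects.
#' @export
draw_groups <- function(N, d, G, seed = NULL) {
  if (d < 2 || d > N) stop("require 2 <= d <= N (got d=", d, ", N=", N, ")")
  if (G < 1) stop("G must be >= 1")
  with_seed(seed, {
    t(vapply(seq_len(G), function(g) sort(sample.int(N, d)), integer(d)))
  })
}
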