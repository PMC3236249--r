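#' Specify a synthetic multi-run component experiment
#'
#' Describes R independent decompositions that share n_planted source maps.
#' Each run receives every planted map with an independent random sign flip
#' and a random component permutation, plus additive iid Gaussian noise at
#' the stated signal-to-noise ratio; the remaining K - n_planted components
#' are run-specific iid noise maps. This emulates the run-to-run variability
#' of repeated ICA fits — sign/permutation ambiguity plus estimation noise —
#' with known ground truth. Planted sources are sparse maps: a small
#' fraction of active voxels with Gamma-distributed positive amplitudes, so
#' group-average maps have the genuine positive non-Gaussian tails the
#' mixture model is designed to detect.
#'
#' @param R number of runs.
#' @param K components per run.
#' @param V voxels (optionally \code{grid}, a 3D dim vector with
#'   \code{prod(grid) >= V}, for volume output).
#' @param n_planted number of shared sources, 0 <= n_planted <= K.
#' @param snr ratio of planted-map standard deviation to additive noise
#'   standard deviation; \code{Inf} means noise-free copies.
#' @param active_frac fraction of active voxels per source (default 0.05).
#' @param amp_shape,amp_scale Gamma amplitude distribution of active voxels
#'   (default shape 4, scale 1).
#' @param seed integer master seed.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(R = 10, K = 8, V = 2000, n_planted = 4, snr = 1,
                           active_frac = 0.05, amp_shape = 4, amp_scale = 1,
                           grid = NULL, seed = 1) {
  if (n_planted < 0 || n_planted > K) stop("require 0 <= n_planted <= K")
  if (snr < 0) stop("snr must be >= 0")
  if (R < 2) stop("R must be >= 2")
  if (V < 2) stop("V must be >= 2")
  if (!(active_frac > 0 && active_frac < 1)) stop("active_frac must be in (0,1)")
  structure(list(R = as.integer(R), K = as.integer(K), V = as.integer(V),
                 n_planted = as.integer(n_planted), snr = snr,
                 active_frac = active_frac, amp_shape = amp_shape,
                 amp_scale = amp_scale, grid = grid, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Planted source maps drawn from a substream that depends only on the seed
# and the source dimensions — never on R — so the same seed yields the same
# sources regardless of run count.
planted_sources <- function(spec) {
  if (spec$n_planted == 0L) {
    return(matrix(0, 0, spec$V))
  }
  seeds <- derive_seeds(spec$seed, 2L)
  with_seed(seeds[1], {
    n_active <- max(1L, round(spec$active_frac * spec$V))
    t(vapply(seq_len(spec$n_planted), function(s) {
      m <- numeric(spec$V)
      act <- sample.int(spec$V, n_active)
      m[act] <- stats::rgamma(n_active, shape = spec$amp_shape,
                              scale = spec$amp_scale)
      m / stats::sd(m)   # unit sd so snr has its stated meaning
    }, numeric(spec$V)))
  })
}

#' Generate synthetic component runs with known ground truth
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{runs} (list of R \code{\link{component_set}})
#'   and \code{truth} — a data.frame mapping each planted source to its
#'   (run, component, sign) assignment.
#' @export
generate_runs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- planted_sources(spec)
  seeds <- derive_seeds(spec$seed, 2L)
  noise_sd <- if (is.infinite(spec$snr)) 0 else if (spec$snr == 0) Inf else 1 / spec$snr
  with_seed(seeds[2], {
    truth <- NULL
    runs <- lapply(seq_len(spec$R), function(r) {
      maps <- matrix(stats::rnorm(spec$K * spec$V), spec$K, spec$V)
      if (spec$n_planted > 0L) {
        slots <- sample.int(spec$K, spec$n_planted)
        signs <- sample(c(-1L, 1L), spec$n_planted, replace = TRUE)
        for (s in seq_len(spec$n_planted)) {
          sig <- signs[s] * S[s, ]
          noise <- if (noise_sd == 0) 0 else if (is.infinite(noise_sd)) {
            stats::rnorm(spec$V) * 1e6   # snr = 0: signal drowned
          } else {
            stats::rnorm(spec$V, sd = noise_sd)
          }
          maps[slots[s], ] <- sig + noise
        }
        truth <<- rbind(truth, data.frame(source = seq_len(spec$n_planted),
                                          run = r, component = slots,
                                          sign = signs))
      }
      component_set(maps, sprintf("sim%02d", r))
    })
    list(runs = runs, truth = truth)
  })
}

#' Generate per-subject time-series with shared spatial sources
#'
#' Builds subject data matrices as (random time-courses) x (planted source
#' maps) + Gaussian noise, the linear mixing model the temporal
#' concatenation group-ICA harness expects.
#'
#' @param spec a \code{\link{synthetic_spec}} (\code{R} is read as the
#'   number of subjects; \code{n_planted} as the number of sources).
#' @param T_len timepoints per subject; must exceed \code{spec$K}.
#' @return list of R matrices, each T_len x V.
#' @export
generate_group_timeseries <- function(spec, T_len) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (T_len <= spec$K) stop("need T > K timepoints (got T=", T_len,
                            ", K=", spec$K, ")")
  if (spec$n_planted < 1L) stop("need at least one planted source")
  S <- planted_sources(spec)
  seeds <- derive_seeds(spec$seed, 2L)
  noise_sd <- if (is.infinite(spec$snr)) 0 else 1 / spec$snr
  with_seed(seeds[2], {
    lapply(seq_len(spec$R), function(i) {
      A <- matrix(stats::rnorm(T_len * spec$n_planted), T_len, spec$n_planted)
      Y <- A %*% S
      if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd),
                                        nrow(Y), ncol(Y))
      Y
    })
  })
}

#' Temporal-concatenation group ICA harness
#'
#' Plumbing for one group-ICA run: demeans each subject's voxel
#' time-courses, reduces each subject to its top K temporal principal
#' components (per-subject covariance by default; \code{reducer = "pooled"}
#' reduces the concatenated data directly), temporally concatenates the
#' reduced data, whitens to K dimensions, and delegates the unmixing to a
#' caller-supplied ICA backend. The unmixing algorithm itself is
#' interchangeable; \code{\link{fastica_backend}} is the bundled default and
#' \code{function(X, K) X} (identity) returns the whitened principal
#' component maps.
#'
#' @param datasets list of T_i x V subject matrices (identical V).
#' @param K number of components to extract (< total reduced rows).
#' @param reducer "subject" (default) or "pooled".
#' @param ica_backend function(X, K) taking the K x V whitened data and
#'   returning K x V unmixed spatial maps.
#' @param run_id identifier for the returned \code{component_set}.
#' @return a \code{\link{component_set}} of K spatial maps.
#' @export
group_ica_harness <- function(datasets, K, reducer = c("subject", "pooled"),
                              ica_backend = fastica_backend,
                              run_id = "group") {
  reducer <- match.arg(reducer)
  V <- unique(vapply(datasets, ncol, 0L))
  if (length(V) != 1L) stop("all subjects must share the same voxel count V")
  demeaned <- lapply(datasets, function(Y) sweep(Y, 2, colMeans(Y)))
  reduce_top <- function(Y, k) {
    k <- min(k, nrow(Y) - 1L, ncol(Y))
    sv <- svd(Y, nu = k, nv = 0)
    t(sv$u[, seq_len(k), drop = FALSE]) %*% Y
  }
  stacked <- if (reducer == "subject") {
    do.call(rbind, lapply(demeaned, reduce_top, k = K))
  } else {
    do.call(rbind, demeaned)
  }
  if (K > nrow(stacked)) {
    stop("K=", K, " must not exceed the ", nrow(stacked),
         " concatenated (reduced) rows")
  }
  sv <- svd(stacked, nu = 0, nv = K)
  Xw <- t(sv$v[, seq_len(K), drop = FALSE]) * sqrt(V)  # unit-variance rows
  maps <- tryCatch(ica_backend(Xw, K), error = function(e) {
    stop("ICA backend failed during group run '", run_id, "': ",
         conditionMessage(e))
  })
  maps <- as.matrix(maps)
  if (!all(dim(maps) == c(K, V))) {
    stop("ICA backend must return a ", K, " x ", V, " matrix")
  }
  component_set(maps, run_id)
}

#' Symmetric fixed-point ICA backend
#'
#' A compact reference unmixing backend for
#' \code{\link{group_ica_harness}}: symmetric FastICA on whitened data with
#' the tanh contrast, symmetric decorrelation, and a deterministic seeded
#' initialisation. Any function with the same (X, K) -> K x V signature may
#' be substituted.
#'
#' @param X K x V whitened data (rows uncorrelated, unit variance).
#' @param K number of components.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the unmixing update.
#' @param seed seed for the random orthogonal initialisation.
#' @return K x V matrix of unmixed spatial maps.
#' @export
fastica_backend <- function(X, K, max_iter = 200, tol = 1e-8, seed = 1) {
  V <- ncol(X)
  W <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), K) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    S <- W %*% X
    G <- tanh(S)
    gprime <- rowMeans(1 - G^2)
    W_new <- (G %*% t(X)) / V - diag(gprime, K) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  W %*% X
}
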