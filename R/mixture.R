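#' Voxelwise rank-based transformation to normality
#'
#' Per voxel (column), the R values across runs are replaced by
#' standard-normal quantiles of their mid-ranks, qnorm((rank - 0.5) / R),
#' with ties sharing averaged ranks. The result is invariant to any strictly
#' monotone transform of a column, has per-column mean approximately 0, and
#' makes the subsequent one-sample t-test's Gaussian assumption hold by
#' construction under exchangeability. Constant columns map to all zeros and
#' are flagged in attribute \code{constant_columns}.
#'
#' With \code{margin = "map"} the same mid-rank transform is instead applied
#' to each row across its V voxels — Gaussianising every spatial map's
#' intensity distribution while preserving its spatial ordering. This is the
#' variant the group-average pipeline uses: transforming within voxel
#' columns equalises every voxel's value multiset, which annihilates the
#' group mean, whereas the per-map transform keeps between-voxel contrast
#' and only tames heavy-tailed map intensities.
#'
#' @param stacked_maps R x V matrix of sign-aligned maps (runs as rows).
#' @param margin "voxel" (default): transform each column across runs;
#'   "map": transform each row across voxels.
#' @return R x V matrix of Gaussianised values.
#' @export
rank_gauss_transform <- function(stacked_maps, margin = c("voxel", "map")) {
  margin <- match.arg(margin)
  x <- as.matrix(stacked_maps)
  R <- nrow(x)
  if (R < 2L) stop("rank-based Gaussianisation requires R >= 2 rows")
  rg <- function(v) {
    stats::qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
  }
  if (margin == "voxel") {
    const <- apply(x, 2, function(col) max(col) == min(col))
    out <- apply(x, 2, rg)
    out[, const] <- 0
    attr(out, "constant_columns") <- which(const)
  } else {
    const <- apply(x, 1, function(row) max(row) == min(row))
    out <- t(apply(x, 1, rg))
    out[const, ] <- 0
    attr(out, "constant_rows") <- which(const)
  }
  out
}

#' Voxelwise one-sample group-average t map
#'
#' Ordinary least squares with a single group-average design reduces to the
#' one-sample t statistic per voxel: mean / (sd / sqrt(R)), on R - 1 degrees
#' of freedom. Zero-variance voxels get t = 0 and are flagged in attribute
#' \code{zero_variance}; the dof is recorded in attribute \code{dof}.
#'
#' @param aligned_maps R x V matrix; rows should be sign-aligned (see
#'   \code{\link{sign_align}}) and Gaussianised (see
#'   \code{\link{rank_gauss_transform}}) first.
#' @return length-V numeric vector of t values.
#' @export
group_average_tstat <- function(aligned_maps) {
  x <- as.matrix(aligned_maps)
  R <- nrow(x)
  if (R < 2L) stop("group t map requires R >= 2 rows")
  mu <- colMeans(x)
  sd <- sqrt(colSums((x - rep(mu, each = R))^2) / (R - 1))
  zv <- sd == 0
  t <- numeric(ncol(x))
  t[!zv] <- mu[!zv] / (sd[!zv] / sqrt(R))
  attr(t, "zero_variance") <- which(zv)
  attr(t, "dof") <- R - 1L
  t
}

# Weighted maximum-likelihood Gamma fit (shape, scale) by Newton iteration
# on log(k) - digamma(k) = s, started from the standard closed-form
# approximation. Returns NULL when the weighted sample is degenerate.
weighted_gamma_mle <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0 || length(x) == 0L) return(NULL)
  mw <- sum(w * x) / sw
  s <- log(mw) - sum(w * log(x)) / sw
  if (!is.finite(s) || s <= 1e-12) return(NULL)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:25) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  c(shape = k, scale = mw / k)
}

tgg_density_matrix <- function(x, fr, nu, gp, gm) {
  d_t <- stats::dt(x, df = nu)
  d_p <- ifelse(x > 0, stats::dgamma(x, shape = gp[1], scale = gp[2]), 0)
  d_m <- ifelse(x < 0, stats::dgamma(-x, shape = gm[1], scale = gm[2]), 0)
  cbind(t = fr[1] * d_t, plus = fr[2] * d_p, minus = fr[3] * d_m)
}

#' Fit a Student-t / Gamma+ / Gamma- mixture to a statistic map
#'
#' Three-class EM fit of
#' pi_t t_nu(x) + pi_plus Gamma(x; k+, theta+) 1\{x > 0\} +
#' pi_minus Gamma(-x; k-, theta-) 1\{x < 0\}:
#' a central Student-t null plus positive and negative Gamma tails carrying
#' the non-Gaussian structure. If the input is a pure t map (no interesting
#' structure) the Gamma class fractions are driven towards 0, so the null is
#' accounted for automatically; a class whose fraction hits the floor
#' (1e-6) is reported as degenerate.
#'
#' Initialisation: values below the 2.5\% sample quantile seed Gamma-, above
#' the 97.5\% quantile seed Gamma+, the middle seeds the t class, with
#' method-of-moments Gamma starts. Convergence when the mean log-likelihood
#' improves by less than \code{tol} (default 1e-6), at most \code{max_iter}
#' iterations. The Gammas sit on the half-lines with no location shift.
#'
#' @param values numeric vector of statistic values (>= 10; >= 100
#'   recommended for a stable fit).
#' @param dof Student-t degrees of freedom: a positive number (typically
#'   R - 1 from the t map) or \code{"estimate"} to fit nu by inner
#'   profile optimisation.
#' @param tol convergence tolerance on mean log-likelihood change.
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class \code{tgg_mixture}: \code{fractions} (pi_t,
#'   pi_plus, pi_minus), \code{t_dof}, \code{gamma_plus},
#'   \code{gamma_minus} (shape, scale), \code{loglik_trace},
#'   \code{posteriors} (n x 3, columns t/plus/minus), \code{degenerate},
#'   \code{converged}, \code{n_iter}.
#' @export
fit_tgg_mixture <- function(values, dof = "estimate", tol = 1e-6,
                            max_iter = 500) {
  x <- as.numeric(values)
  if (!all(is.finite(x))) stop("mixture input must be finite")
  n <- length(x)
  if (n < 10L) stop("need at least 10 values to fit the mixture")
  if (n < 100L) warning("fewer than 100 values: mixture fit may be unstable")
  estimate_dof <- identical(dof, "estimate")
  nu <- if (estimate_dof) 10 else {
    if (!(is.numeric(dof) && dof > 0)) stop("dof must be positive or 'estimate'")
    as.numeric(dof)
  }

  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  lo <- x < q[1] & x < 0
  hi <- x > q[2] & x > 0
  mom_gamma <- function(v, fallback = c(shape = 2, scale = 1)) {
    if (length(v) < 2L || stats::var(v) == 0) return(fallback)
    m <- mean(v); s2 <- stats::var(v)
    c(shape = m^2 / s2, scale = s2 / m)
  }
  gp <- mom_gamma(x[hi])
  gm <- mom_gamma(-x[lo])
  fr <- c(t = max(mean(!lo & !hi), 1e-3),
          plus = max(mean(hi), 1e-3),
          minus = max(mean(lo), 1e-3))
  fr <- fr / sum(fr)

  floor_frac <- 1e-6
  degenerate <- c(plus = FALSE, minus = FALSE)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    num <- tgg_density_matrix(x, fr, nu, gp, gm)
    den <- rowSums(num)
    den[den <= 0] <- .Machine$double.xmin
    ll <- sum(log(den))
    ll_trace <- c(ll_trace, ll)
    resp <- num / den
    if (is.finite(ll_prev) && (ll - ll_prev) / n < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    fr_new <- colMeans(resp)
    fr_new <- pmax(fr_new, floor_frac)
    fr <- fr_new / sum(fr_new)
    degenerate <- c(plus = unname(fr[2]) <= floor_frac * 2,
                    minus = unname(fr[3]) <= floor_frac * 2)
    pos <- x > 0
    if (!degenerate["plus"]) {
      g <- weighted_gamma_mle(x[pos], resp[pos, "plus"])
      if (!is.null(g)) gp <- g
    }
    neg <- x < 0
    if (!degenerate["minus"]) {
      g <- weighted_gamma_mle(-x[neg], resp[neg, "minus"])
      if (!is.null(g)) gm <- g
    }
    if (estimate_dof) {
      wt <- resp[, "t"]
      nu <- exp(stats::optimize(function(lnu) {
        -sum(wt * stats::dt(x, df = exp(lnu), log = TRUE))
      }, c(log(0.5), log(500)))$minimum)
    }
  }
  names(fr) <- c("pi_t", "pi_plus", "pi_minus")
  structure(list(fractions = fr, t_dof = nu,
                 gamma_plus = gp, gamma_minus = gm,
                 loglik_trace = ll_trace,
                 posteriors = resp,
                 degenerate = degenerate,
                 converged = converged,
                 n_iter = length(ll_trace)),
            class = "tgg_mixture")
}

#' @export
print.tgg_mixture <- function(x, ...) {
  f <- x$fractions
  cat("<tgg_mixture> fractions: t=", sprintf("%.4f", f[1]),
      " gamma+=", sprintf("%.4f", f[2]),
      " gamma-=", sprintf("%.4f", f[3]),
      "  (t dof ", sprintf("%.2f", x$t_dof), ")\n", sep = "")
  cat("  gamma+: shape=", sprintf("%.3f", x$gamma_plus[1]),
      " scale=", sprintf("%.3f", x$gamma_plus[2]),
      if (x$degenerate["plus"]) " [degenerate]" else "", "\n", sep = "")
  cat("  gamma-: shape=", sprintf("%.3f", x$gamma_minus[1]),
      " scale=", sprintf("%.3f", x$gamma_minus[2]),
      if (x$degenerate["minus"]) " [degenerate]" else "", "\n", sep = "")
  cat("  log-likelihood ", sprintf("%.2f", utils::tail(x$loglik_trace, 1)),
      " after ", x$n_iter, " EM iterations",
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Posterior class probabilities under a fitted mixture
#'
#' @param fit a \code{\link{fit_tgg_mixture}} result.
#' @param values values to evaluate; defaults to the fitted posteriors.
#' @return n x 3 matrix with columns t, plus, minus summing to 1 per row.
#' @export
tgg_posterior <- function(fit, values = NULL) {
  if (is.null(values)) return(fit$posteriors)
  num <- tgg_density_matrix(as.numeric(values), fit$fractions, fit$t_dof,
                            fit$gamma_plus, fit$gamma_minus)
  den <- rowSums(num)
  den[den <= 0] <- .Machine$double.xmin
  num / den
}

#' Classify voxels by mixture posterior
#'
#' A voxel is labelled \code{positive} when its Gamma+ posterior exceeds
#' \code{tau}, \code{negative} when its Gamma- posterior exceeds \code{tau},
#' and \code{null} otherwise (should both exceed tau, which is possible only
#' for tau < 0.5, the larger posterior wins). The default tau = 0.5 is the
#' maximum-a-posteriori display rule.
#'
#' @param fit fitted \code{tgg_mixture}.
#' @param values values to classify; defaults to the fitting data.
#' @param tau posterior threshold in (0, 1).
#' @return factor of labels with levels negative, null, positive.
#' @export
classify_voxels <- function(fit, values = NULL, tau = 0.5) {
  if (!(tau > 0 && tau < 1)) stop("tau must lie in (0, 1)")
  post <- tgg_posterior(fit, values)
  lab <- rep("null", nrow(post))
  pos <- post[, "plus"] > tau
  neg <- post[, "minus"] > tau
  both <- pos & neg
  lab[pos & !both] <- "positive"
  lab[neg & !both] <- "negative"
  lab[both] <- ifelse(post[both, "plus"] >= post[both, "minus"],
                      "positive", "negative")
  factor(lab, levels = c("negative", "null", "positive"))
}
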