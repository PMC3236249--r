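#' Reproducibility analysis of spatial components across runs
#'
#' The central fit: builds the cross-realization correlation matrix over all
#' runs, greedily matches components across runs, computes each matched
#' component's normalized reproducibility, simulates the "no
#' reproducibility" permutation null by re-partitioning component labels
#' into pseudo-runs, and assigns permutation p-values. Components with
#' p < alpha are flagged as significantly reproducible. The whole fit is a
#' pure function of (runs, n_sims, seed).
#'
#' @param runs list of \code{\link{component_set}} or K x V matrices
#'   (>= 2 runs, identical K and V).
#' @param n_sims number of null permutations; the null pool has
#'   \code{n_sims * K} values, so the smallest resolvable p is
#'   1/(n_sims * K). Default 100.
#' @param alpha significance cutoff on the permutation p-value (default 0.05).
#' @param seed master seed for the permutation null (required for a
#'   reproducible fit).
#' @param adjust p-value adjustment passed to
#'   \code{\link{select_reproducible}} ("none" or "BH").
#' @return object of class \code{raicarn}: matches, r_norm, null_pool,
#'   p_values, selected ranks, per-run member indices and signs, and the
#'   stored CRCM.
#' @examples
#' sim <- generate_runs(synthetic_spec(R = 6, K = 4, V = 500,
#'                                     n_planted = 2, snr = 2, seed = 7))
#' fit <- raicarn(sim$runs, n_sims = 50, seed = 42)
#' summary(fit)
#' @export
raicarn <- function(runs, n_sims = 100, alpha = 0.05, seed = NULL,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  runs <- as_component_runs(runs)
  crcm <- compute_crcm(runs, include_within_run = TRUE)
  matches <- raicar_match(crcm)
  r_norm <- vapply(matches, `[[`, 0, "r_norm")
  pool <- null_pool(crcm, n_sims = n_sims, seed = seed)
  p <- reproducibility_pvalues(r_norm, pool)
  signs <- t(vapply(matches, sign_align, integer(length(runs)), runs = runs))
  members <- t(vapply(matches, `[[`, integer(length(runs)), "members"))
  structure(list(matches = matches, crcm = crcm,
                 r_norm = r_norm, null_pool = pool,
                 p_values = as.numeric(p), p_text = attr(p, "p_text"),
                 selected = select_reproducible(as.numeric(p), alpha, adjust),
                 members = members, signs = signs,
                 alpha = alpha, n_sims = n_sims, seed = seed,
                 R = crcm$R, K = crcm$K, V = runs[[1]]$V,
                 run_ids = crcm$run_ids, runs = runs,
                 call = match.call()),
            class = "raicarn")
}

#' @export
print.raicarn <- function(x, ...) {
  cat("Reproducibility analysis of ", x$K, " components across ", x$R,
      " runs (V = ", x$V, " voxels)\n", sep = "")
  cat("Permutation null: ", x$n_sims, " label re-partitions (pool ",
      length(x$null_pool), "), seed ", x$seed %||% "<none>", "\n", sep = "")
  cat(length(x$selected), " of ", x$K,
      " components significantly reproducible at alpha = ", x$alpha,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.raicarn <- function(object, ...) {
  tab <- data.frame(rank = seq_len(object$K),
                    r_norm = object$r_norm,
                    p_value = object$p_values,
                    p_text = object$p_text,
                    selected = seq_len(object$K) %in% object$selected)
  structure(list(table = tab, alpha = object$alpha, R = object$R,
                 K = object$K, n_sims = object$n_sims,
                 pool_size = length(object$null_pool)),
            class = "summary.raicarn")
}

#' @export
print.summary.raicarn <- function(x, ...) {
  cat("Matched components (", x$K, ") across ", x$R, " runs; null pool ",
      x$pool_size, "; alpha = ", x$alpha, "\n\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.raicarn <- function(object, ...) {
  stats::setNames(object$r_norm, paste0("rank", seq_len(object$K)))
}

#' Null pool and observed reproducibility of a fit
#'
#' @param x a \code{raicarn} fit.
#' @param ... passed to \code{hist}.
#' @export
plot.raicarn <- function(x, ...) {
  graphics::hist(x$null_pool, breaks = 40, freq = FALSE,
                 main = "Normalized reproducibility vs permutation null",
                 xlab = "normalized reproducibility", col = "grey85",
                 border = "grey60", xlim = c(0, 1), ...)
  sel <- seq_len(x$K) %in% x$selected
  graphics::points(x$r_norm, rep(0, x$K), pch = ifelse(sel, 19, 1),
                   col = ifelse(sel, "firebrick", "grey30"), cex = 1.2)
  graphics::legend("topright", pch = c(19, 1),
                   col = c("firebrick", "grey30"),
                   legend = c(sprintf("selected (p < %g)", x$alpha),
                              "not selected"), bty = "n")
  invisible(x)
}

#' Report table of a fit
#'
#' One row per matched component: rank, r_norm, p-value (numeric and text
#' form), selection flag, then the member component index and sign per run.
#'
#' @param fit a \code{raicarn} fit.
#' @return data.frame.
#' @export
raicarn_report <- function(fit) {
  stopifnot(inherits(fit, "raicarn"))
  tab <- data.frame(rank = seq_len(fit$K),
                    r_norm = fit$r_norm,
                    p_value = fit$p_values,
                    p_text = fit$p_text,
                    selected = seq_len(fit$K) %in% fit$selected)
  mem <- as.data.frame(fit$members)
  names(mem) <- paste0("member.", fit$run_ids)
  sg <- as.data.frame(fit$signs)
  names(sg) <- paste0("sign.", fit$run_ids)
  cbind(tab, mem, sg)
}

#' Group-average t maps of reproducible components
#'
#' For each requested rank: sign-aligns the member maps across runs,
#' Gaussianises each map's intensity distribution by the rank-based
#' transform (\code{margin = "map"}; see \code{\link{rank_gauss_transform}}
#' for why the per-voxel variant cannot feed a group mean), and computes the
#' one-sample group-average t map (dof R - 1).
#'
#' @param fit a \code{raicarn} fit.
#' @param ranks which matched components; defaults to the selected ones.
#' @return matrix length(ranks) x V of t values, rownames "rank<i>",
#'   attribute \code{dof}.
#' @export
reproducible_tmaps <- function(fit, ranks = fit$selected) {
  stopifnot(inherits(fit, "raicarn"))
  if (length(ranks) == 0L) stop("no components requested")
  out <- t(vapply(ranks, function(rk) {
    aligned <- t(vapply(seq_len(fit$R), function(r) {
      fit$signs[rk, r] * fit$runs[[r]]$maps[fit$members[rk, r], ]
    }, numeric(fit$V)))
    group_average_tstat(rank_gauss_transform(aligned, margin = "map"))
  }, numeric(fit$V)))
  rownames(out) <- paste0("rank", ranks)
  attr(out, "dof") <- fit$R - 1L
  out
}

# ---- end-to-end pipeline with file outputs ---------------------------------

# Parse a flat key = value config file into a named list (comments with #).
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("cannot parse config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

default_run_config <- function() {
  list(n_sims = 100, alpha = 0.05, tau = 0.5, mixture_dof = "default",
       n_planted = 4, snr = 1, R = 10, K = 8, V = 2000, seed = NULL,
       write_volumes = FALSE)
}

#' Run a full reproducibility analysis end to end
#'
#' Orchestrates load (or synthesis) -> CRCM -> matching -> permutation null
#' -> p-values -> selection -> sign alignment -> Gaussianisation -> group t
#' maps -> mixture fit -> voxel labels, and writes a report TSV, per-rank
#' t-map/label outputs and a JSON manifest into \code{out_dir}. Identical
#' config and seed produce byte-identical report files. Any stage error
#' aborts with the stage name; partial outputs are removed.
#'
#' @param config named list or path to a flat key = value config file.
#'   Recognised keys: \code{inputs} (comma-separated run paths),
#'   \code{mask}, \code{n_sims}, \code{seed} (required), \code{alpha},
#'   \code{tau}, \code{mixture_dof} ("default" = R - 1, "estimate", or a
#'   number), \code{write_volumes}; without \code{inputs} a synthetic
#'   experiment is generated from \code{R}, \code{K}, \code{V},
#'   \code{n_planted}, \code{snr}.
#' @param out_dir output directory (created if needed).
#' @return the \code{raicarn} fit, invisibly, with the report attached as
#'   attribute \code{report}.
#' @export
run_raicarn <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$seed)) stop("config error: a master seed is required")
  stage <- "configure"
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    seeds <- derive_seeds(cfg$seed, 2L)  # substreams: synthetic, null
    stage <- "load"
    if (!is.null(cfg$inputs)) {
      paths <- trimws(strsplit(cfg$inputs, ",")[[1]])
      if (any(is_nifti_path(paths)) && is.null(cfg$mask)) {
        stop("volume inputs require a mask")
      }
      runs <- load_component_runs(paths, mask = cfg$mask)
      truth <- NULL
    } else {
      sim <- generate_runs(synthetic_spec(R = cfg$R, K = cfg$K, V = cfg$V,
                                          n_planted = cfg$n_planted,
                                          snr = cfg$snr, seed = seeds[1]))
      runs <- sim$runs
      truth <- sim$truth
    }
    stage <- "fit"
    fit <- raicarn(runs, n_sims = cfg$n_sims, alpha = cfg$alpha,
                   seed = seeds[2])
    stage <- "report"
    report <- raicarn_report(fit)
    report_path <- file.path(out_dir, "report.tsv")
    written <- c(written, report_path)
    write_report_tsv(report, report_path)
    stage <- "postprocess"
    mix_summ <- list()
    if (length(fit$selected)) {
      tmaps <- reproducible_tmaps(fit)
      dof <- if (identical(cfg$mixture_dof, "default")) {
        attr(tmaps, "dof")
      } else if (identical(cfg$mixture_dof, "estimate")) {
        "estimate"
      } else {
        as.numeric(cfg$mixture_dof)
      }
      tmap_path <- file.path(out_dir, "tmaps.tsv")
      written <- c(written, tmap_path)
      write_report_tsv(as.data.frame(tmaps), tmap_path, col_names = FALSE)
      for (i in seq_len(nrow(tmaps))) {
        mx <- fit_tgg_mixture(tmaps[i, ], dof = dof)
        lab <- classify_voxels(mx, tmaps[i, ], tau = cfg$tau)
        lab_path <- file.path(out_dir,
                              sprintf("labels_%s.tsv", rownames(tmaps)[i]))
        written <- c(written, lab_path)
        writeLines(paste(as.integer(lab) - 2L, collapse = "\t"), lab_path)
        mix_summ[[rownames(tmaps)[i]]] <- list(
          fractions = as.list(mx$fractions),
          t_dof = mx$t_dof,
          gamma_plus = as.list(mx$gamma_plus),
          gamma_minus = as.list(mx$gamma_minus),
          loglik = utils::tail(mx$loglik_trace, 1),
          converged = mx$converged)
        if (isTRUE(cfg$write_volumes) && !is.null(fit$runs[[1]]$voxel_index)) {
          vol_path <- file.path(out_dir,
                                sprintf("tmap_%s.nii.gz", rownames(tmaps)[i]))
          written <- c(written, vol_path)
          write_component_volume(tmaps[i, ], fit$runs[[1]]$voxel_index,
                                 fit$runs[[1]]$grid, vol_path)
        }
      }
    }
    stage <- "manifest"
    manifest <- list(config = cfg,
                     seed_substreams = list(synthetic = seeds[1],
                                            null = seeds[2]),
                     n_runs = fit$R, K = fit$K, V = fit$V,
                     selected = fit$selected,
                     mixture = mix_summ,
                     file_hashes = as.list(tools::md5sum(
                       written[file.exists(written)])))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    if (!is.null(truth)) {
      write_report_tsv(truth, file.path(out_dir, "ground_truth.tsv"))
    }
    attr(fit, "report") <- report
    invisible(fit)
  }, error = on_fail)
}

# Deterministic TSV writer: fixed number formatting so identical fits give
# byte-identical files.
write_report_tsv <- function(df, path, col_names = TRUE) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col_names)
  invisible(path)
}
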