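#' Construct a set of spatial component maps for one run
#'
#' A \code{component_set} holds the K spatial maps of one decomposition run
#' (one ICA fit, one PCA fit, ...) as a K x V matrix over the V in-mask
#' voxels, together with the voxel-to-grid mapping needed to write results
#' back out as volumes. Components whose map has zero variance are retained
#' but flagged; downstream their correlations are defined as 0, so component
#' indices stay synchronised across runs.
#'
#' @param maps numeric matrix, K components x V voxels; all entries finite.
#' @param run_id character scalar identifying the run.
#' @param voxel_index optional integer matrix (V x 3) of grid coordinates for
#'   each column, in the fixed flattening order (see
#'   \code{\link{mask_voxel_index}}); \code{NULL} for plain matrix input.
#' @param grid optional integer vector giving the 3D grid dimensions.
#' @return an object of class \code{component_set} with fields \code{maps},
#'   \code{run_id}, \code{K}, \code{V}, \code{voxel_index}, \code{grid} and
#'   \code{zero_variance} (logical, length K).
#' @export
component_set <- function(maps, run_id = "run", voxel_index = NULL, grid = NULL) {
  maps <- as.matrix(maps)
  storage.mode(maps) <- "double"
  if (!all(is.finite(maps))) {
    stop("component maps must be finite: run '", run_id,
         "' contains NA/NaN/Inf values")
  }
  if (nrow(maps) < 1L || ncol(maps) < 2L) {
    stop("component maps must have at least 1 component and 2 voxels")
  }
  if (!is.null(voxel_index)) {
    voxel_index <- as.matrix(voxel_index)
    if (nrow(voxel_index) != ncol(maps)) {
      stop("voxel_index has ", nrow(voxel_index), " rows but maps have ",
           ncol(maps), " voxels")
    }
  }
  zv <- row_sds(maps) == 0
  structure(list(maps = maps, run_id = as.character(run_id),
                 K = nrow(maps), V = ncol(maps),
                 voxel_index = voxel_index, grid = grid,
                 zero_variance = zv),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> run '", x$run_id, "': ", x$K, " components x ",
      x$V, " voxels", sep = "")
  if (!is.null(x$grid)) cat(" (grid ", paste(x$grid, collapse = "x"), ")", sep = "")
  if (any(x$zero_variance)) {
    cat("\n  zero-variance components:",
        paste(which(x$zero_variance), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.component_set <- function(x, ...) x$maps

#' Fixed voxel flattening order for a mask
#'
#' Maps the in-mask voxels of a 3D grid to matrix columns 1..V. The order is
#' row-major over grid coordinates (first axis slowest, last axis fastest),
#' restricted to the mask. It depends only on (mask, grid), never on data
#' values, so reports can index voxels consistently across the package.
#'
#' @param mask logical (or 0/1 numeric) 3D array.
#' @return integer matrix V x n_dims of grid coordinates, with an attribute
#'   \code{linear} giving the corresponding linear indices into the array.
#' @export
mask_voxel_index <- function(mask) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask selects 0 voxels (empty mask)")
  coords <- which(mask, arr.ind = TRUE)
  ord <- do.call(order, lapply(seq_len(ncol(coords)), function(j) coords[, j]))
  coords <- coords[ord, , drop = FALSE]
  d <- dim(mask)
  mult <- c(1, cumprod(d[-length(d)]))
  lin <- as.integer((coords - 1) %*% mult + 1)
  attr(coords, "linear") <- lin
  coords
}

is_nifti_path <- function(path) {
  grepl("\\.nii(\\.gz)?$|\\.hdr$", path, ignore.case = TRUE)
}

#' Load spatial component maps from volume or matrix files
#'
#' Reads one file per run — either a 4D NIfTI volume (one 3D volume per
#' component) or a tab-delimited matrix (components as rows) — and flattens
#' each into a \code{\link{component_set}}. All runs entering one analysis
#' must share the same number of components K and in-mask voxel count V; a
#' single common mask is applied to every volume.
#'
#' @param paths character vector of file paths, one per run.
#' @param mask optional path to a 3D NIfTI mask, or a logical/0-1 array.
#'   Required grid match with every volume; ignored for matrix input.
#' @param run_ids optional run identifiers (defaults to file base names).
#' @return list of \code{component_set}, one per run.
#' @export
load_component_runs <- function(paths, mask = NULL, run_ids = NULL) {
  if (length(paths) < 1L) stop("no input runs given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("cannot read input file(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(run_ids)) {
    run_ids <- sub("\\.nii(\\.gz)?$|\\.tsv$|\\.txt$", "",
                   basename(paths), ignore.case = TRUE)
  }
  mask_arr <- NULL
  if (!is.null(mask)) {
    mask_arr <- if (is.character(mask)) {
      as.array(RNifti::readNifti(mask))
    } else {
      mask
    }
    mask_arr <- array(as.logical(mask_arr != 0), dim = dim(mask_arr))
  }

  runs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (is_nifti_path(p)) {
      vol <- as.array(RNifti::readNifti(p))
      if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
      if (length(dim(vol)) != 4L) {
        stop("expected a 3D or 4D volume in '", p, "', got ",
             length(dim(vol)), " dimensions")
      }
      grid <- dim(vol)[1:3]
      m <- mask_arr %||% array(TRUE, dim = grid)
      if (!identical(dim(m), as.integer(grid)) &&
          !identical(as.integer(dim(m)), as.integer(grid))) {
        stop("dimensional mismatch: mask grid (",
             paste(dim(m), collapse = "x"), ") does not match volume '",
             p, "' (", paste(grid, collapse = "x"), ")")
      }
      vi <- mask_voxel_index(m)
      lin <- attr(vi, "linear")
      K <- dim(vol)[4]
      nvox <- prod(grid)
      maps <- matrix(0, K, length(lin))
      for (k in seq_len(K)) {
        maps[k, ] <- vol[(k - 1L) * nvox + lin]
      }
      runs[[i]] <- component_set(maps, run_ids[i], voxel_index = vi, grid = grid)
    } else {
      maps <- read_tsv_matrix(p)
      runs[[i]] <- component_set(maps, run_ids[i])
    }
  }
  K0 <- runs[[1]]$K; V0 <- runs[[1]]$V
  for (i in seq_along(runs)) {
    if (runs[[i]]$V != V0 || runs[[i]]$K != K0) {
      stop("dimensional mismatch: run '", runs[[i]]$run_id, "' has K=",
           runs[[i]]$K, ", V=", runs[[i]]$V, " but run '", runs[[1]]$run_id,
           "' has K=", K0, ", V=", V0)
    }
  }
  runs
}

#' Write values over in-mask voxels back to a NIfTI volume
#'
#' Inverse of the flattening performed by \code{\link{load_component_runs}}:
#' each row of \code{values} becomes one 3D volume with out-of-mask voxels
#' set to 0. Volumes are written in double precision so that a write/load
#' round trip recovers the values exactly.
#'
#' @param values numeric vector of length V or matrix with V columns.
#' @param voxel_index V x 3 coordinate matrix from \code{\link{mask_voxel_index}}.
#' @param grid_shape integer 3D grid dimensions.
#' @param path output file path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_component_volume <- function(values, voxel_index, grid_shape, path) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  if (ncol(values) != nrow(voxel_index)) {
    stop("dimensional mismatch: ", ncol(values), " values per row but ",
         nrow(voxel_index), " in-mask voxels")
  }
  mult <- c(1, cumprod(grid_shape[-length(grid_shape)]))
  lin <- as.integer((as.matrix(voxel_index) - 1) %*% mult + 1)
  K <- nrow(values)
  nvox <- prod(grid_shape)
  vol <- array(0, dim = c(grid_shape, K))
  for (k in seq_len(K)) {
    vol[(k - 1L) * nvox + lin] <- values[k, ]
  }
  if (K == 1L) dim(vol) <- grid_shape
  RNifti::writeNifti(RNifti::asNifti(vol), path, datatype = "double")
  invisible(path)
}

#' Write a component set to a tab-delimited matrix file
#'
#' Components as rows, voxels as columns, no header — the diff-friendly
#' matrix dialect accepted back by \code{\link{load_component_runs}}.
#'
#' @param x a \code{component_set}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_component_tsv <- function(x, path) {
  stopifnot(inherits(x, "component_set"))
  write_tsv_matrix(x$maps, path)
}

# Coerce a list of matrices / component_sets into component_sets with a
# shared V, erroring on mismatch. Internal normalisation for entry points.
as_component_runs <- function(runs) {
  if (inherits(runs, "component_set")) runs <- list(runs)
  runs <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (inherits(r, "component_set")) r else component_set(r, paste0("run", i))
  })
  V <- vapply(runs, `[[`, 0L, "V")
  K <- vapply(runs, `[[`, 0L, "K")
  if (length(unique(V)) != 1L || length(unique(K)) != 1L) {
    bad <- which(V != V[1] | K != K[1])[1]
    stop("dimensional mismatch: run '", runs[[bad]]$run_id,
         "' has K=", K[bad], ", V=", V[bad],
         " but run '", runs[[1]]$run_id, "' has K=", K[1], ", V=", V[1])
  }
  runs
}
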