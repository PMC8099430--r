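#' Pairwise RMSD between two models
#'
#' Root-mean-square deviation over selected particle centers, in the fixed
#' receptor frame (no superposition).
#'
#' @param a,b n x 3 coordinate matrices over the same particle set.
#' @param selection optional integer particle indices (default: all).
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(a, b, selection = NULL) {
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  if (nrow(a) != nrow(b)) stop("selection cardinality mismatch")
  sqrt(mean(rowSums((a - b)^2)))
}

## full M x M RMSD matrix over an ensemble's models
rmsd_matrix <- function(models, selection = NULL) {
  X <- do.call(rbind, lapply(models, function(m) {
    if (!is.null(selection)) m <- m[selection, , drop = FALSE]
    as.numeric(m)
  }))
  S <- ncol(X) / 3
  sq <- rowSums(X * X)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  sqrt(d2 / S)
}

#' Cluster ensemble models by structural similarity
#'
#' Deterministic greedy centroid clustering: the model with the largest
#' neighborhood (models within `rmsd_threshold`) seeds cluster 1, its
#' members are removed, and the procedure repeats.  Ties break toward the
#' lowest model index.
#'
#' @param ensemble an `xlwalk_ensemble`.
#' @param rmsd_threshold cluster radius in Angstrom, or `"auto"` to cluster
#'   at the estimated sampling precision (the median RMSD between models
#'   drawn from different runs), the usual protocol for coarse-grained
#'   integrative ensembles.
#' @param selection particle indices used for the RMSD (default: all
#'   mobile particles).
#' @return an object of class `xlwalk_clustering`: `labels` (per model),
#'   `sizes`, `occupancy` (fractions summing to 1), `centroid` (seed model
#'   index per cluster), `rmsd_threshold`.
#' @export
cluster_models <- function(ensemble, rmsd_threshold = "auto",
                           selection = NULL) {
  if (!length(ensemble$models)) stop("ensemble has no models")
  if (is.null(selection))
    selection <- which(ensemble$system$particles$mobile)
  D <- rmsd_matrix(ensemble$models, selection)
  M <- nrow(D)
  if (identical(rmsd_threshold, "auto")) {
    run <- ensemble$provenance$run
    cross <- outer(run, run, "!=")
    rmsd_threshold <- if (any(cross)) stats::median(D[cross])
                      else stats::median(D[upper.tri(D)])
  }
  nb <- D <= rmsd_threshold
  labels <- rep(NA_integer_, M)
  centroid <- integer(0)
  cl <- 0
  remaining <- seq_len(M)
  while (length(remaining)) {
    counts <- rowSums(nb[remaining, remaining, drop = FALSE])
    seed <- remaining[which.max(counts)]
    cl <- cl + 1
    members <- remaining[nb[seed, remaining]]
    labels[members] <- cl
    centroid[cl] <- seed
    remaining <- setdiff(remaining, members)
  }
  sizes <- as.integer(table(factor(labels, levels = seq_len(cl))))
  structure(list(labels = labels, sizes = sizes,
                 occupancy = sizes / M, centroid = centroid,
                 rmsd_threshold = rmsd_threshold, selection = selection),
            class = "xlwalk_clustering")
}

#' @export
print.xlwalk_clustering <- function(x, ...) {
  cat("xlwalk clustering:", length(x$sizes), "cluster(s) at threshold",
      x$rmsd_threshold, "A\n")
  for (k in seq_along(x$sizes))
    cat(sprintf("  cluster %d: %d models (occupancy %.3f), centroid model %d\n",
                k, x$sizes[k], x$occupancy[k], x$centroid[k]))
  invisible(x)
}

#' Extract the models of one cluster as an ensemble
#'
#' @param ensemble the clustered `xlwalk_ensemble`.
#' @param clustering an [cluster_models()] result.
#' @param cluster cluster label (default 1, the most occupied).
#' @return an `xlwalk_ensemble` restricted to that cluster.
#' @export
cluster_ensemble <- function(ensemble, clustering, cluster = 1) {
  subset_ensemble(ensemble, which(clustering$labels == cluster))
}

## --- density grids ------------------------------------------------------

new_density <- function(origin, voxel, dim, values = NULL) {
  if (is.null(values)) values <- array(0, dim)
  structure(list(origin = as.numeric(origin), voxel = as.numeric(voxel),
                 dim = as.integer(dim), values = values),
            class = "xlwalk_density")
}

#' @export
print.xlwalk_density <- function(x, ...) {
  cat(sprintf("xlwalk density grid: %d x %d x %d voxels @ %.3g A, origin (%s)\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel,
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

## voxel centers sit at origin + (i - 0.5) * voxel
grid_geometry_for <- function(points, margin, voxel, pad_voxels = 2) {
  lo <- apply(points, 2, min) - margin - pad_voxels * voxel
  hi <- apply(points, 2, max) + margin + pad_voxels * voxel
  dim <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  list(origin = lo, voxel = voxel, dim = dim)
}

## add solid spheres (weight per covered voxel) into a grid
accumulate_spheres <- function(grid, centers, radii, weight = 1) {
  v <- grid$voxel
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]
    r <- radii[k]
    lo <- pmax(1L, as.integer(ceiling((ctr - r - grid$origin) / v + 0.5)))
    hi <- pmin(grid$dim, as.integer(floor((ctr + r - grid$origin) / v + 0.5)))
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    cx <- grid$origin[1] + (ii - 0.5) * v - ctr[1]
    cy <- grid$origin[2] + (jj - 0.5) * v - ctr[2]
    cz <- grid$origin[3] + (kk - 0.5) * v - ctr[3]
    d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    inside <- d2 <= r * r
    grid$values[ii, jj, kk] <- grid$values[ii, jj, kk, drop = FALSE] +
      weight * inside
  }
  grid
}

#' Localization probability density of a component over an ensemble
#'
#' Rasterizes each selected particle of each model as a solid sphere of its
#' radius; voxel counts accumulate across models (raw occupancy counts are
#' stored; divide by the number of models for a probability).
#'
#' @param ensemble an `xlwalk_ensemble`.
#' @param selection integer particle indices of the component (default:
#'   all mobile particles).
#' @param voxel voxel edge in Angstrom (default 3).
#' @param geometry optional precomputed grid geometry (origin/voxel/dim
#'   list), e.g. to put two ensembles on a common grid.
#' @return an `xlwalk_density` with attribute `n_models`.
#' @export
localization_density <- function(ensemble, selection = NULL, voxel = 3,
                                 geometry = NULL) {
  if (!length(ensemble$models)) stop("ensemble has no models")
  if (voxel <= 0) stop("voxel must be > 0")
  if (is.null(selection))
    selection <- which(ensemble$system$particles$mobile)
  if (!length(selection)) stop("empty component selection")
  radii <- ensemble$system$particles$radius[selection]
  if (is.null(geometry)) {
    all_pts <- do.call(rbind, lapply(ensemble$models, function(m)
      m[selection, , drop = FALSE]))
    geometry <- grid_geometry_for(all_pts, max(radii), voxel)
  }
  grid <- new_density(geometry$origin, geometry$voxel, geometry$dim)
  for (m in ensemble$models)
    grid <- accumulate_spheres(grid, m[selection, , drop = FALSE], radii)
  attr(grid, "n_models") <- length(ensemble$models)
  grid
}

#' Contour level relative to the grid maximum
#'
#' @param grid an `xlwalk_density`.
#' @param fraction fraction of the maximum voxel value (default 0.025,
#'   i.e. 2.5 percent of max).
#' @return the contour level (same units as the grid values).
#' @export
contour_level <- function(grid, fraction = 0.025) {
  mx <- max(grid$values)
  if (mx <= 0) stop("all-zero grid has no contour level")
  if (fraction == 0) warning("contour fraction 0 gives a degenerate level")
  fraction * mx
}

## nearest-voxel value lookup; points outside the grid read as 0
grid_value_at <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  idx <- round(sweep(points, 2, grid$origin) / grid$voxel + 0.5)
  out <- numeric(nrow(points))
  ok <- idx[, 1] >= 1 & idx[, 1] <= grid$dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= grid$dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= grid$dim[3]
  if (any(ok))
    out[ok] <- grid$values[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  out
}

#' Rasterize a structure as a sum of Gaussians
#'
#' Each atom/bead contributes an isotropic 3D Gaussian with
#' `sigma = resolution / 2.355` (FWHM = resolution), normalized so that
#' each atom integrates to 1 over space; values are per cubic Angstrom.
#'
#' @param coords n x 3 coordinate matrix (or a bio3d `pdb` object).
#' @param resolution nominal resolution in Angstrom (FWHM of the Gaussian).
#' @param voxel voxel edge in Angstrom (default 1).
#' @param geometry optional grid geometry to rasterize onto.
#' @return an `xlwalk_density`.
#' @export
rasterize_structure <- function(coords, resolution, voxel = 1,
                                geometry = NULL) {
  if (inherits(coords, "pdb"))
    coords <- cbind(coords$atom$x, coords$atom$y, coords$atom$z)
  sigma <- resolution / 2.355
  cutoff <- 4 * sigma
  if (is.null(geometry))
    geometry <- grid_geometry_for(coords, cutoff, voxel)
  grid <- new_density(geometry$origin, geometry$voxel, geometry$dim)
  amp <- (2 * pi * sigma^2)^(-1.5)
  v <- grid$voxel
  for (k in seq_len(nrow(coords))) {
    ctr <- coords[k, ]
    lo <- pmax(1L, as.integer(ceiling((ctr - cutoff - grid$origin) / v + 0.5)))
    hi <- pmin(grid$dim,
               as.integer(floor((ctr + cutoff - grid$origin) / v + 0.5)))
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    cx <- grid$origin[1] + (ii - 0.5) * v - ctr[1]
    cy <- grid$origin[2] + (jj - 0.5) * v - ctr[2]
    cz <- grid$origin[3] + (kk - 0.5) * v - ctr[3]
    d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    grid$values[ii, jj, kk] <- grid$values[ii, jj, kk, drop = FALSE] +
      amp * exp(-d2 / (2 * sigma^2))
  }
  grid
}

## trilinear resampling of src values at the voxel centers of a geometry
resample_grid <- function(src, geometry) {
  out <- new_density(geometry$origin, geometry$voxel, geometry$dim)
  ii <- seq_len(out$dim[1]); jj <- seq_len(out$dim[2]); kk <- seq_len(out$dim[3])
  px <- out$origin[1] + (ii - 0.5) * out$voxel
  py <- out$origin[2] + (jj - 0.5) * out$voxel
  pz <- out$origin[3] + (kk - 0.5) * out$voxel
  ## fractional source indices (voxel-center convention)
  fx <- (px - src$origin[1]) / src$voxel - 0.5 + 1
  fy <- (py - src$origin[2]) / src$voxel - 0.5 + 1
  fz <- (pz - src$origin[3]) / src$voxel - 0.5 + 1
  val_at <- function(i, j, k) {
    ok <- i >= 1 & i <= src$dim[1] & j >= 1 & j <= src$dim[2] &
      k >= 1 & k <= src$dim[3]
    v <- numeric(length(i))
    if (any(ok)) v[ok] <- src$values[cbind(i[ok], j[ok], k[ok])]
    v
  }
  g <- expand.grid(x = fx, y = fy, z = fz)
  i0 <- floor(g$x); j0 <- floor(g$y); k0 <- floor(g$z)
  dx <- g$x - i0; dy <- g$y - j0; dz <- g$z - k0
  acc <- numeric(nrow(g))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wgt <- (if (di) dx else 1 - dx) * (if (dj) dy else 1 - dy) *
      (if (dk) dz else 1 - dz)
    acc <- acc + wgt * val_at(i0 + di, j0 + dj, k0 + dk)
  }
  out$values <- array(acc, out$dim)
  out
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) && abs(a$voxel - b$voxel) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Model-minus-experimental difference map
#'
#' Scales the model grid by the least-squares amplitude fit to the
#' experimental grid, then subtracts voxelwise:
#' `diff = experimental - alpha * model` with
#' `alpha = <exp, model> / <model, model>`.
#'
#' @param grid_experimental,grid_model `xlwalk_density` grids.
#' @param resample if `TRUE`, trilinearly resample the model grid onto the
#'   experimental geometry first; otherwise the geometries must match.
#' @return the difference `xlwalk_density` (attribute `scale` holds alpha).
#' @export
difference_map <- function(grid_experimental, grid_model, resample = FALSE) {
  if (!same_geometry(grid_experimental, grid_model)) {
    if (!resample)
      stop("grid geometries differ; pass resample = TRUE to interpolate")
    grid_model <- resample_grid(grid_model, grid_experimental)
  }
  mm <- sum(grid_model$values^2)
  if (mm == 0) stop("model grid is all zero")
  alpha <- sum(grid_experimental$values * grid_model$values) / mm
  out <- grid_experimental
  out$values <- grid_experimental$values - alpha * grid_model$values
  attr(out, "scale") <- alpha
  out
}

#' Sampling convergence check between two ensembles
#'
#' Builds the localization densities of both ensembles on a common grid and
#' returns the Pearson correlation over voxels where either density is
#' positive.
#'
#' @param ensembleA,ensembleB `xlwalk_ensemble` objects over the same
#'   topology.
#' @param selection particle indices of the component (default: mobile
#'   particles).
#' @param voxel voxel edge in Angstrom.
#' @return correlation in `[-1, 1]`.
#' @export
convergence_check <- function(ensembleA, ensembleB, selection = NULL,
                              voxel = 3) {
  if (is.null(selection))
    selection <- which(ensembleA$system$particles$mobile)
  radii <- ensembleA$system$particles$radius[selection]
  pts <- rbind(
    do.call(rbind, lapply(ensembleA$models, function(m)
      m[selection, , drop = FALSE])),
    do.call(rbind, lapply(ensembleB$models, function(m)
      m[selection, , drop = FALSE])))
  geom <- grid_geometry_for(pts, max(radii), voxel)
  ga <- localization_density(ensembleA, selection, voxel, geometry = geom)
  gb <- localization_density(ensembleB, selection, voxel, geometry = geom)
  keep <- ga$values > 0 | gb$values > 0
  if (!any(keep)) stop("empty overlap between the two densities")
  stats::cor(as.numeric(ga$values[keep]), as.numeric(gb$values[keep]))
}

## --- MRC (mode 2, float32) IO ------------------------------------------

#' Write a density grid as an MRC file
#'
#' MRC2014 mode-2 (float32) with correct cell, axis-order and origin
#' metadata.  Values are written with the x index fastest.
#'
#' @param grid an `xlwalk_density`.
#' @param path output file path.
#' @param normalize divide values by the number of models (attribute
#'   `n_models`) to store per-model probabilities instead of raw counts.
#' @return the path, invisibly.
#' @export
write_mrc <- function(grid, path, normalize = FALSE) {
  vals <- grid$values
  if (normalize) {
    n <- attr(grid, "n_models")
    if (is.null(n)) stop("grid has no n_models attribute to normalize by")
    vals <- vals / n
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(grid$dim)                      # nx ny nz
  wi(2)                             # mode 2 = float32
  wi(c(0, 0, 0))                    # nxstart nystart nzstart
  wi(grid$dim)                      # mx my mz
  wf(grid$dim * grid$voxel)         # cella
  wf(c(90, 90, 90))                 # cellb
  wi(c(1, 2, 3))                    # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1)                             # ispg
  wi(0)                             # nsymbt
  wi(rep(0, 25))                    # extra (words 26-49, incl. extTyp/nversion)
  wf(grid$origin)                   # origin x y z (words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(as.numeric(vals)))   # rms
  wi(0)                             # nlabl
  writeBin(raw(800), con)           # labels
  wf(as.numeric(vals))
  invisible(path)
}

#' Read an MRC density file
#'
#' Supports the mode-2 (float32) maps written by [write_mrc()] with axis
#' order x, y, z.
#'
#' @param path MRC file path.
#' @return an `xlwalk_density`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dim <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC maps are supported")
  ri(3)                 # nxstart
  m <- ri(3)            # mx my mz
  cella <- rf(3)
  rf(3)                 # cellb
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3))) stop("only x,y,z axis order is supported")
  rf(3)                 # dmin dmax dmean
  ri(2)                 # ispg nsymbt
  ri(25)                # extra
  origin <- rf(3)
  seek(con, 1024)
  vals <- rf(prod(dim))
  voxel <- cella[1] / m[1]
  new_density(origin, voxel, dim, array(vals, dim))
}
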