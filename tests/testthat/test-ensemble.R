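# quick synthetic ensemble around given center configurations
blob_ensemble <- function(centers, counts, jitter = 0.5, seed = 1) {
  set.seed(seed)
  n <- nrow(centers[[1]])
  sys <- manual_system(list(X = list(centers[[1]])))
  models <- list()
  runs <- integer(0)
  for (b in seq_along(centers)) {
    for (k in seq_len(counts[b])) {
      models[[length(models) + 1]] <-
        centers[[b]] + matrix(rnorm(n * 3, 0, jitter), n, 3)
      runs <- c(runs, b)
    }
  }
  ord <- sample(length(models))   # interleave blob membership
  structure(list(models = models[ord], system = sys,
                 provenance = data.frame(model = seq_along(models),
                                         run = rep(1, length(models)),
                                         seed = seed,
                                         snapshot = seq_along(models))),
            class = "xlwalk_ensemble")
}

test_that("pairwise RMSD matches definition and brute force", {
  a <- random_chain(9, 2)
  expect_equal(pairwise_rmsd(a, a), 0)
  b <- a
  b[5, ] <- b[5, ] + c(3, 0, 0)   # one of nine displaced by 3 A
  expect_equal(pairwise_rmsd(a, b), 1)
  set.seed(3)
  for (k in 1:20) {
    x <- matrix(rnorm(30), 10, 3)
    y <- matrix(rnorm(30), 10, 3)
    sel <- sample(10, sample(3:10, 1))
    expect_equal(pairwise_rmsd(x, y, sel), bf_rmsd(x, y, sel),
                 tolerance = 1e-12)
  }
  expect_error(pairwise_rmsd(a, a[1:3, ]), "mismatch")
})

test_that("greedy clustering recovers constructed occupancies", {
  base <- random_chain(12, 5)
  ens1 <- blob_ensemble(list(base), counts = 20)
  cl1 <- cluster_models(ens1, rmsd_threshold = 5, selection = 1:12)
  expect_equal(length(cl1$sizes), 1)
  expect_equal(cl1$occupancy, 1)

  far <- base + 100
  ens2 <- blob_ensemble(list(base, far), counts = c(70, 30), seed = 4)
  cl2 <- cluster_models(ens2, rmsd_threshold = 5, selection = 1:12)
  expect_equal(length(cl2$sizes), 2)
  expect_equal(cl2$occupancy, c(0.7, 0.3))
  expect_equal(sum(cl2$occupancy), 1)

  cl3 <- cluster_models(ens2, rmsd_threshold = Inf, selection = 1:12)
  expect_equal(length(cl3$sizes), 1)

  # auto mode estimates a threshold at the within-blob scale, far below
  # the between-blob separation, so the blobs stay separate clusters
  cl4 <- cluster_models(ens2, rmsd_threshold = "auto", selection = 1:12)
  expect_lt(cl4$rmsd_threshold, 50)
  expect_gte(length(cl4$sizes), 2)
  expect_equal(sum(cl4$occupancy), 1)
})

test_that("localization density puts mass where the beads are", {
  sys <- manual_system(list(X = list(matrix(c(5, 5, 5), 1, 3))))
  ens <- structure(list(models = list(sys$coords), system = sys,
                        provenance = data.frame(model = 1, run = 1, seed = 1,
                                                snapshot = 1)),
                   class = "xlwalk_ensemble")
  d <- localization_density(ens, selection = 1, voxel = 3)
  expect_equal(xlwalk:::grid_value_at(d, matrix(c(5, 5, 5), 1, 3)),
               max(d$values))
  expect_true(all(d$values >= 0))

  # mirror-symmetric pair of configurations -> two equal maxima
  sys2 <- manual_system(list(X = list(matrix(c(20, 0, 0), 1, 3))))
  ens2 <- structure(list(models = list(matrix(c(20, 0, 0), 1, 3),
                                       matrix(c(-20, 0, 0), 1, 3)),
                         system = sys2,
                         provenance = data.frame(model = 1:2, run = 1,
                                                 seed = 1, snapshot = 1:2)),
                    class = "xlwalk_ensemble")
  d2 <- localization_density(ens2, selection = 1, voxel = 2)
  va <- xlwalk:::grid_value_at(d2, matrix(c(20, 0, 0), 1, 3))
  vb <- xlwalk:::grid_value_at(d2, matrix(c(-20, 0, 0), 1, 3))
  expect_equal(va, vb)
  expect_equal(va, max(d2$values))

  # occupancy volume approximates model count x sphere volumes
  set.seed(6)
  pts <- matrix(rnorm(15, 0, 8), 5, 3)
  sys3 <- manual_system(list(X = list(pts)))
  models <- lapply(1:4, function(k) pts + matrix(rnorm(15, 0, 6), 5, 3))
  ens3 <- structure(list(models = models, system = sys3,
                         provenance = data.frame(model = 1:4, run = 1,
                                                 seed = 1, snapshot = 1:4)),
                    class = "xlwalk_ensemble")
  d3 <- localization_density(ens3, selection = 1:5, voxel = 1)
  vol <- sum(d3$values) * d3$voxel^3
  want <- 4 * 5 * 4 / 3 * pi * bead_radius(1)^3
  expect_lt(abs(vol - want) / want, 0.05)

  expect_error(localization_density(ens3, selection = integer(0)), "empty")
})

test_that("density is invariant to model order", {
  set.seed(8)
  pts <- matrix(rnorm(9, 0, 5), 3, 3)
  sys <- manual_system(list(X = list(pts)))
  models <- lapply(1:6, function(k) pts + matrix(rnorm(9), 3, 3))
  mk <- function(mods) structure(
    list(models = mods, system = sys,
         provenance = data.frame(model = seq_along(mods), run = 1, seed = 1,
                                 snapshot = seq_along(mods))),
    class = "xlwalk_ensemble")
  geom <- list(origin = c(-20, -20, -20), voxel = 2, dim = c(20L, 20L, 20L))
  d1 <- localization_density(mk(models), 1:3, geometry = geom)
  d2 <- localization_density(mk(rev(models)), 1:3, geometry = geom)
  expect_equal(d1$values, d2$values)
})

test_that("contour level is a fraction of the maximum", {
  g <- xlwalk:::new_density(c(0, 0, 0), 1, c(2, 2, 2))
  g$values[1, 1, 1] <- 100
  expect_equal(contour_level(g, 0.025), 2.5)
  expect_equal(contour_level(g, 1), 100)
  expect_warning(lv <- contour_level(g, 0), "degenerate")
  expect_equal(lv, 0)
  g$values[] <- 0
  expect_error(contour_level(g), "all-zero")
})

test_that("Gaussian rasterization integrates to one per atom", {
  one <- matrix(c(0, 0, 0), 1, 3)
  g <- rasterize_structure(one, resolution = 5, voxel = 1)
  expect_equal(sum(g$values) * g$voxel^3, 1, tolerance = 0.02)
  expect_equal(xlwalk:::grid_value_at(g, one), max(g$values))
  two <- rbind(one, c(40, 0, 0))
  g2 <- rasterize_structure(two, resolution = 5, voxel = 1)
  expect_equal(sum(g2$values) * g2$voxel^3, 2, tolerance = 0.04)
  g3 <- rasterize_structure(two, resolution = 5, voxel = 2)
  expect_equal(sum(g3$values) * g3$voxel^3,
               sum(g2$values) * g2$voxel^3, tolerance = 0.05)
})

test_that("difference maps subtract after least-squares amplitude fit", {
  set.seed(10)
  base <- matrix(rnorm(60, 0, 6), 20, 3)
  geom <- list(origin = c(-30, -30, -30), voxel = 2, dim = c(30L, 30L, 30L))
  gm <- rasterize_structure(base, resolution = 6, voxel = 2, geometry = geom)
  d0 <- difference_map(gm, gm)
  expect_lt(max(abs(d0$values)), 1e-6 * max(gm$values))
  # a blob present only in the "experimental" map is recovered
  blob_center <- c(20, 20, 20)
  gx <- rasterize_structure(rbind(base, blob_center), resolution = 6,
                            voxel = 2, geometry = geom)
  dd <- difference_map(gx, gm)
  peak <- which(dd$values == max(dd$values), arr.ind = TRUE)[1, ]
  peak_xyz <- dd$origin + (peak - 0.5) * dd$voxel
  expect_lt(sqrt(sum((peak_xyz - blob_center)^2)), 2 * dd$voxel)
  # scaling the model leaves the fitted difference unchanged
  gm2 <- gm; gm2$values <- 2 * gm$values
  dd2 <- difference_map(gx, gm2)
  expect_equal(dd2$values, dd$values, tolerance = 1e-9)
  # geometry mismatch needs explicit resampling
  gshift <- gm; gshift$origin <- gm$origin + 1
  expect_error(difference_map(gx, gshift), "geometr")
  dd3 <- difference_map(gx, gshift, resample = TRUE)
  expect_equal(dim(dd3$values), dim(gx$values))
})

test_that("convergence correlation is 1 for identical and <= 0 for disjoint", {
  set.seed(12)
  pts <- matrix(rnorm(9, 0, 4), 3, 3)
  sys <- manual_system(list(X = list(pts)))
  mk <- function(shift) structure(
    list(models = lapply(1:5, function(k) pts + shift +
                           matrix(rnorm(9, 0, 0.5), 3, 3)),
         system = sys,
         provenance = data.frame(model = 1:5, run = 1, seed = 1,
                                 snapshot = 1:5)),
    class = "xlwalk_ensemble")
  a <- mk(0)
  expect_equal(convergence_check(a, a, selection = 1:3), 1)
  b <- mk(60)
  expect_lte(convergence_check(a, b, selection = 1:3), 0)
})

test_that("MRC files round-trip values and grid metadata", {
  set.seed(14)
  g <- xlwalk:::new_density(c(-7.5, 3.25, 12), 1.5, c(6L, 5L, 4L))
  g$values[] <- as.numeric(sample(0:50, 120, replace = TRUE))  # float32-exact
  f <- tempfile(fileext = ".mrc")
  write_mrc(g, f)
  back <- read_mrc(f)
  expect_identical(back$dim, g$dim)
  expect_equal(back$values, g$values)       # integers survive float32
  expect_equal(back$voxel, g$voxel, tolerance = 1e-6)
  expect_equal(back$origin, g$origin, tolerance = 1e-5)
  # second write of the re-read grid is byte-identical (stable quantization)
  f2 <- tempfile(fileext = ".mrc")
  write_mrc(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
  # normalization writes per-model probabilities
  attr(g, "n_models") <- 10
  write_mrc(g, f, normalize = TRUE)
  expect_equal(read_mrc(f)$values, g$values / 10, tolerance = 1e-7)
})
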