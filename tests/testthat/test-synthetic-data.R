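test_that("toy receptors carry the generating screw geometry", {
  spec <- toy_spec()
  rec <- make_toy_receptor(spec, seed = 3)
  per <- spec$atoms_per_subunit
  s1 <- rec$coords[rec$subunit == 1, ]
  s2 <- rec$coords[rec$subunit == 2, ]
  fit <- superpose(s2, s1)          # transform placing subunit 1 onto 2
  expect_lt(fit$rmsd, 1e-9)
  sp <- screw_parameters(fit$transform)
  expect_equal(sp$twist, spec$twist, tolerance = 1e-6)
  expect_equal(sp$rise, spec$rise, tolerance = 1e-6)
  expect_equal(abs(sp$axis[3]), 1, tolerance = 1e-9)

  solo <- make_toy_receptor(toy_spec(n_subunits = 1), seed = 3)
  expect_null(solo$transform)
  # determinism
  rec2 <- make_toy_receptor(spec, seed = 3)
  expect_identical(rec2$coords, rec$coords)
  expect_false(identical(make_toy_receptor(spec, seed = 4)$coords,
                         rec$coords))
})

test_that("ground-truth paths hug the receptor surface at 3.8 A steps", {
  spec <- toy_spec()
  rec <- make_toy_receptor(spec, seed = 5)
  truth <- make_ground_truth_path(rec, seed = 6)
  p <- truth$path
  expect_equal(nrow(p), spec$n_residues)
  steps <- sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2))
  expect_true(all(abs(steps - 3.8) < 0.2))
  mind <- vapply(seq_len(nrow(p)), function(i)
    min(sqrt(rowSums((rec$coords - rep(p[i, ], each = nrow(rec$coords)))^2))),
    0)
  expect_true(all(mind <= 10 + 1e-9))
  expect_true(all(mind >= 6.4 - 1e-9))

  two <- make_ground_truth_path(rec, n_residues = 2, seed = 7)
  expect_equal(sqrt(sum((two$path[2, ] - two$path[1, ])^2)), 3.8,
               tolerance = 1e-9)

  # the truth satisfies connectivity exactly (one bead per residue)
  sys <- manual_system(list(LIG = list(p)))
  expect_equal(connectivity_score(sys), 0)
})

test_that("simulated crosslinks respect margins and reproduce byte-for-byte", {
  spec <- toy_spec()
  rec <- make_toy_receptor(spec, seed = 8)
  truth <- make_ground_truth_path(rec, seed = 9)
  sim <- simulate_crosslinks(truth, rec, spec, seed = 10)
  tt <- sim$truth_table
  is_true <- tt$label == "true"
  expect_true(all(tt$distance[is_true] <=
                    spec$margin * spec$thresholds[tt$linker[is_true]]))
  expect_true(all(tt$distance[!is_true] >
                    1.5 * spec$thresholds[tt$linker[!is_true]]))
  expect_true(all(sim$psms$q_value <= 0.01))
  expect_true(all(sim$psms$psm_count >= 2))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_psm_table(sim, f1)
  write_psm_table(simulate_crosslinks(truth, rec, spec, seed = 10), f2)
  expect_identical(readLines(f1), readLines(f2))

  # filter-violating rows are injectable and then removed by the filter
  noisy <- simulate_crosslinks(truth, rec, spec, seed = 10,
                               inject_bad_q = 3, inject_low_psm = 2)
  kept <- filter_psms(noisy$psms |> transform(source_row = seq_len(nrow(noisy$psms))) |>
                        setNames(c("protein1", "residue1", "protein2",
                                   "residue2", "linker", "q_value",
                                   "psm_count", "source_row")))
  expect_true(all(kept$q_min <= 0.01 & kept$n_psms >= 2))
})

test_that("the ground-truth configuration satisfies its own crosslinks", {
  spec <- toy_spec()
  rec <- make_toy_receptor(spec, seed = 12)
  truth <- make_ground_truth_path(rec, seed = 13)
  spec0 <- spec; spec0$n_false <- 0
  sim <- simulate_crosslinks(truth, rec, spec0, seed = 14)
  # system whose ligand beads sit exactly on the truth path
  mols <- list(LIG = list(truth$path))
  for (s in seq_len(spec$n_subunits))
    mols[[sprintf("SUB%d", s)]] <- list(rec$coords[rec$subunit == s, ])
  sys <- manual_system(mols, fixed = sprintf("SUB%d", seq_len(spec$n_subunits)),
                       rigid = sprintf("SUB%d", seq_len(spec$n_subunits)))
  csv <- tempfile(fileext = ".csv")
  write_psm_table(sim, csv)
  xl <- filter_psms(read_psm_table(csv))
  rep <- satisfaction_report(sys, xl, thresholds = spec$thresholds)
  expect_equal(attr(rep, "fraction"), 1)

  # decoys alone are all violated by the truth
  specd <- spec; specd$n_true <- 0; specd$n_false <- 5
  simd <- simulate_crosslinks(truth, rec, specd, seed = 15)
  write_psm_table(simd, csv)
  xld <- filter_psms(read_psm_table(csv))
  repd <- satisfaction_report(sys, xld, thresholds = spec$thresholds)
  expect_equal(attr(repd, "fraction"), 0)
})

test_that("path recovery counts truth points inside the density contour", {
  spec <- toy_spec(n_subunits = 1, subunit_dims = c(3, 3, 3), spacing = 4,
                   n_residues = 20, n_true = 4, n_false = 0)
  rec <- make_toy_receptor(spec, seed = 16)
  truth <- make_ground_truth_path(rec, seed = 17)
  sys <- manual_system(list(LIG = list(truth$path)))
  ens <- structure(list(models = list(truth$path), system = sys,
                        provenance = data.frame(model = 1, run = 1, seed = 1,
                                                snapshot = 1)),
                   class = "xlwalk_ensemble")
  dens <- localization_density(ens, selection = 1:20, voxel = 3)
  expect_equal(recovery_metrics(dens, truth), 1)
  # a decoy path far from the density recovers nothing
  decoy <- truth
  decoy$path <- truth$path + 200
  expect_equal(recovery_metrics(dens, decoy), 0)
  # agreement with a per-point brute-force lookup
  level <- contour_level(dens, 0.025)
  hand <- mean(vapply(seq_len(nrow(truth$path)), function(i) {
    idx <- round((truth$path[i, ] - dens$origin) / dens$voxel + 0.5)
    if (any(idx < 1) || any(idx > dens$dim)) return(0)
    dens$values[idx[1], idx[2], idx[3]]
  }, 0) >= level)
  expect_equal(recovery_metrics(dens, truth, 0.025), hand)
})
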