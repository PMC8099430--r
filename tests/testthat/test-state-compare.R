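test_that("Kabsch superposition recovers constructed transforms", {
  set.seed(2)
  a <- matrix(rnorm(45, 0, 10), 15, 3)
  fit0 <- superpose(a, a)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$transform$R, diag(3), tolerance = 1e-9)

  tf <- random_transform(6)
  b <- apply_transform(a, invert_transform(tf))
  fit <- superpose(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$transform$R, tf$R, tolerance = 1e-6)
  expect_equal(fit$transform$t, tf$t, tolerance = 1e-6)
  expect_lt(max(abs(apply_transform(b, fit$transform) - a)), 1e-6)

  expect_error(superpose(a, b[1:10, ]), "mismatch")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superposition agrees with the bio3d reference fit", {
  set.seed(4)
  a <- matrix(rnorm(60, 0, 12), 20, 3)
  b <- apply_transform(a, random_transform(8)) +
    matrix(rnorm(60, 0, 0.5), 20, 3)
  fit <- superpose(a, b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(a)), mobile = as.numeric(t(b))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("COM displacement isolates component motion after alignment", {
  set.seed(5)
  state_a <- matrix(rnorm(90, 0, 15), 30, 3)
  align <- 1:20
  comp <- 21:30
  # move the component by (3,4,0), then bury the change under a global
  # rigid transform of the whole state
  state_b <- state_a
  state_b[comp, ] <- state_b[comp, ] + rep(c(3, 4, 0), each = 10)
  tf <- random_transform(9)
  state_b <- apply_transform(state_b, tf)
  expect_equal(com_displacement(state_a, state_a, align, comp), 0,
               tolerance = 1e-9)
  expect_equal(com_displacement(state_a, state_b, align, comp), 5,
               tolerance = 1e-6)
  expect_error(com_displacement(state_a, state_b, align, integer(0)),
               "empty")
})

test_that("screw parameters decompose and reconstruct rigid transforms", {
  tf <- screw_transform(60, 21, axis = c(0, 0, 1))
  sp <- screw_parameters(tf)
  expect_equal(sp$twist, 60, tolerance = 1e-9)
  expect_equal(sp$rise, 21, tolerance = 1e-9)
  expect_equal(abs(sp$axis[3]), 1, tolerance = 1e-9)

  expect_error(screw_parameters(rigid_transform(diag(3), c(0, 0, 21))),
               "degenerate")

  set.seed(11)
  for (k in 1:15) {
    twist <- runif(1, 5, 175)
    rise <- runif(1, 0, 40)
    axis <- rnorm(3)
    point <- rnorm(3, 0, 30)
    tf <- screw_transform(twist, rise, axis, point)
    sp <- screw_parameters(tf)
    expect_equal(sp$twist, twist, tolerance = 1e-6)
    expect_equal(sp$rise, rise, tolerance = 1e-6)
    back <- screw_transform(sp$twist, sp$rise, sp$axis, sp$point)
    pts <- matrix(rnorm(30, 0, 50), 10, 3)
    expect_lt(max(abs(apply_transform(pts, back) - apply_transform(pts, tf))),
              1e-6)
  }
})

test_that("helical pitch matches the filament state arithmetic", {
  open_state <- helical_pitch(54.5, 21.2)
  expect_equal(open_state$pitch, 140.0, tolerance = 0.1)
  expect_equal(open_state$subunits_per_turn, 6.61, tolerance = 0.01)
  closed_state <- helical_pitch(55.1, 20.2)
  expect_equal(closed_state$pitch, 132.0, tolerance = 0.1)
  expect_equal(helical_pitch(360, 10)$pitch, 10)
  expect_error(helical_pitch(0, 10), "twist")
})

test_that("pitch is invariant under conjugation by a rigid transform", {
  tf <- screw_transform(54.5, 21.2, axis = c(0.3, -1, 0.5), point = c(5, 8, -2))
  g <- random_transform(13)
  conj <- compose_transforms(g, compose_transforms(tf, invert_transform(g)))
  sp <- screw_parameters(conj)
  expect_equal(helical_pitch(sp$twist, sp$rise)$pitch, 140.0, tolerance = 0.1)
})

test_that("Shrake-Rupley SASA matches closed forms", {
  one <- sasa(matrix(0, 1, 3), radii = 2)
  expect_equal(attr(one, "total"), 4 * pi * 3.4^2, tolerance = 0.01)
  # additivity at large separation
  two <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(2, 2))
  expect_equal(attr(two, "total"), 2 * 4 * pi * 3.4^2, tolerance = 0.01)
  # fully caged atom has zero accessible area
  cage <- rbind(c(0, 0, 0),
                as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3),
                                      z = c(-3, 0, 3)))[-14, ])
  s <- sasa(cage, radii = c(1.5, rep(3.2, 26)))
  expect_equal(s[1], 0)
  # rotation invariance within the sampling tolerance
  set.seed(15)
  pts <- matrix(rnorm(30, 0, 4), 10, 3)
  r <- runif(10, 1.4, 2)
  t1 <- attr(sasa(pts, r), "total")
  t2 <- attr(sasa(apply_transform(pts, random_transform(16)), r), "total")
  expect_lt(abs(t1 - t2) / t1, 0.01)
})

test_that("buried area follows the two-sphere occlusion oracle", {
  # independent oracle: Monte Carlo points on each expanded sphere
  bf_pair_sasa <- function(c1, c2, r1, r2, probe, n = 40000) {
    set.seed(17)
    one <- function(ca, ra, cb, rb) {
      p <- matrix(rnorm(3 * n), n, 3)
      p <- p / sqrt(rowSums(p^2)) * (ra + probe)
      p <- sweep(p, 2, ca, "+")
      acc <- sqrt(rowSums(sweep(p, 2, cb)^2)) >= rb + probe
      4 * pi * (ra + probe)^2 * mean(acc)
    }
    free <- 4 * pi * ((r1 + probe)^2 + (r2 + probe)^2)
    complexed <- one(c1, r1, c2, r2) + one(c2, r2, c1, r1)
    free - complexed
  }
  at <- data.frame(x = c(0, 4), y = 0, z = 0, radius = c(2, 2),
                   chain = c("A", "B"), resno = c(1L, 1L))
  rep <- buried_area(at, "A", "B")
  want <- bf_pair_sasa(c(0, 0, 0), c(4, 0, 0), 2, 2, 1.4)
  expect_equal(rep$buried, want, tolerance = 0.02 * want)
  expect_equal(rep$buried, rep$buried_a + rep$buried_b, tolerance = 1e-9)
  expect_equal(nrow(rep$residues_a), 1)

  # symmetry under swapping the chain sets
  swap <- buried_area(at, "B", "A")
  expect_equal(swap$buried, rep$buried, tolerance = 1e-12)
  expect_equal(swap$buried_a, rep$buried_b, tolerance = 1e-12)

  # distant chains bury nothing
  at2 <- at; at2$x[2] <- 100
  far <- buried_area(at2, "A", "B")
  expect_equal(far$buried, 0, tolerance = 1e-9)
  expect_equal(nrow(far$residues_a), 0)
  expect_error(buried_area(at, c("A", "B"), "B"), "disjoint")
})

test_that("lattice register displacement reports per-subunit offsets", {
  set.seed(19)
  ref <- cbind(40 * cos(2 * pi * (1:13) / 13), 40 * sin(2 * pi * (1:13) / 13),
               9.2 * (1:13) / 13)
  ring <- apply_transform(ref, random_transform(20))
  out <- mt_register_displacement(ring, ref, align_pairs = 1:13)
  expect_lt(out$max, 1e-6)

  ring2 <- ref
  ring2[7, ] <- ring2[7, ] + c(0, 0, 7)
  out2 <- mt_register_displacement(apply_transform(ring2, random_transform(21)),
                                   ref, align_pairs = c(1, 2, 3))
  expect_equal(out2$max, 7, tolerance = 1e-6)
  expect_equal(which.max(out2$displacement), 7L)
  # exhaustive check: reported displacements match direct recomputation
  tf <- out2$transform
  moved <- apply_transform(apply_transform(ring2, random_transform(21)), tf)
  expect_equal(out2$displacement, sqrt(rowSums((moved - ref)^2)),
               tolerance = 1e-9)
  expect_error(mt_register_displacement(ring, ref, align_pairs = 1),
               "at least 2")
  # two-pair alignment still resolves pure translations
  shifted <- ref + rep(c(5, -3, 2), each = 13)
  out3 <- mt_register_displacement(shifted, ref, align_pairs = c(1, 7))
  expect_lt(out3$max, 1e-6)
})

test_that("site context reports partner distances and interface membership", {
  at <- data.frame(
    x = c(0, 1, 3.5, 50), y = 0, z = 0,
    radius = 1.7, chain = c("A", "A", "B", "C"),
    resno = c(10L, 10L, 5L, 7L), stringsAsFactors = FALSE)
  ctx <- site_context(at, "A", 10, partner_chains = c("B", "C"))
  expect_equal(unname(ctx$distances["B"]), 2.5)
  expect_equal(unname(ctx$distances["C"]), 49)
  expect_true(ctx$within_interface)
  expect_false(site_context(at, "B", 5, "C")$within_interface)
  un <- site_context(at, "A", 999, "B")
  expect_true(un$unmapped)
  expect_true(is.na(un$distances[["B"]]))

  # brute-force agreement on a random 200-atom toy
  set.seed(23)
  toy <- data.frame(x = rnorm(200, 0, 20), y = rnorm(200, 0, 20),
                    z = rnorm(200, 0, 20), radius = 1.7,
                    chain = sample(c("A", "B", "C"), 200, TRUE),
                    resno = sample(1:30, 200, TRUE),
                    stringsAsFactors = FALSE)
  pick <- toy[toy$chain == "A", ][1, ]
  got <- site_context(toy, "A", pick$resno, c("B", "C"))
  want <- bf_site_context(toy, "A", pick$resno, c("B", "C"), 4.5)
  expect_equal(unname(got$distances), unname(want$distances),
               tolerance = 1e-9)
  expect_equal(got$within_interface, want$within)
})

test_that("chain range selections resolve Calpha coordinates", {
  f <- tempfile(fileext = ".pdb")
  n <- 30
  xyz <- matrix(round(rnorm(3 * n, 0, 10), 3), n, 3)
  x <- matrix(as.numeric(t(xyz)), nrow = 1)
  class(x) <- c("xyz", "matrix")
  bio3d::write.pdb(file = f, xyz = x, resno = c(1:15, 1:15),
                   resid = rep("ALA", n), eleno = 1:n,
                   elety = rep("CA", n), chain = rep(c("A", "B"), each = 15))
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  sel <- select_ca(pdb, "A:3-7+B:10-12")
  expect_equal(nrow(sel), 8)
  expect_equal(attr(sel, "chain"), rep(c("A", "B"), c(5, 3)))
  expect_error(select_ca(pdb, "Z:1-5"), "matches no")
})
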