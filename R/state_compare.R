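#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation that superposes the selected
#' points of `coords_b` onto the corresponding points of `coords_a`,
#' minimizing the RMSD.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices with paired rows.
#' @param selection optional integer row indices applied to both.
#' @return a list: `transform` (an [rigid_transform()] mapping B into the A
#'   frame) and `rmsd` (Angstrom, after application).
#' @export
superpose <- function(coords_a, coords_b, selection = NULL) {
  if (!is.null(selection)) {
    coords_a <- coords_a[selection, , drop = FALSE]
    coords_b <- coords_b[selection, , drop = FALSE]
  }
  if (nrow(coords_a) != nrow(coords_b))
    stop("selection cardinality mismatch between the two states")
  if (nrow(coords_a) < 3)
    stop("superposition needs at least 3 paired points")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  sv_a <- svd(A)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate (collinear) selection for superposition")
  H <- crossprod(B, A)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- ca - as.numeric(R %*% cb)
  tf <- rigid_transform(R, t_)
  rmsd <- sqrt(mean(rowSums((apply_transform(coords_b, tf) - coords_a)^2)))
  list(transform = tf, rmsd = rmsd)
}

#' Center-of-mass displacement between two conformational states
#'
#' Superposes state B onto state A over `align_selection`, then reports the
#' displacement of the (unweighted) center of mass of
#' `component_selection`.  This isolates the component's motion from any
#' global placement difference between the two models.
#'
#' @param state_a,state_b n x 3 coordinate matrices with paired rows
#'   (typically Calpha coordinates).
#' @param align_selection integer indices of the region held fixed by the
#'   alignment.
#' @param component_selection integer indices of the moving component.
#' @param weights optional per-point masses for a weighted COM (default:
#'   unweighted).
#' @return displacement in Angstrom.
#' @export
com_displacement <- function(state_a, state_b, align_selection,
                             component_selection, weights = NULL) {
  if (!length(component_selection)) stop("empty component selection")
  fit <- superpose(state_a, state_b, align_selection)
  b_aligned <- apply_transform(state_b, fit$transform)
  com <- function(x, idx) {
    xx <- x[idx, , drop = FALSE]
    if (is.null(weights)) colMeans(xx)
    else colSums(xx * weights[idx]) / sum(weights[idx])
  }
  vec_norm(com(b_aligned, component_selection) - com(state_a, component_selection))
}

#' Screw parameters of a rigid transform
#'
#' Decomposes a rigid transform into a rotation (twist) about a screw axis
#' plus a translation (rise) along it.  The twist is reported in
#' (0, 180], which fixes the axis direction; the rise is the signed
#' translation along that axis.  The axis point is the point on the axis
#' closest to the origin.
#'
#' @param tf an [rigid_transform()].
#' @param tol minimum rotation angle in degrees (default 1e-3); a
#'   near-identity rotation has no defined screw axis.
#' @return an object of class `xlwalk_screw`: `twist` (degrees, in
#'   (0, 180]), `rise` (Angstrom, signed), `axis` (unit vector), `point`.
#' @export
screw_parameters <- function(tf, tol = 1e-3) {
  R <- tf$R; t_ <- tf$t
  theta <- rotation_angle(R)
  if (theta < tol)
    stop("rotation angle ", format(theta), " deg is below tolerance: ",
         "degenerate screw (pure translation)")
  s <- sin(theta * pi / 180)
  if (abs(s) > 1e-6) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * s)
  } else {
    ## theta ~ 180 deg: axis from the symmetric part
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, k])
  }
  axis <- unit(axis)
  if (abs(s) <= 1e-6) {
    ## 180-degree rotations leave the axis sign free: fix it
    nz <- which(abs(axis) > 1e-9)[1]
    if (axis[nz] < 0) axis <- -axis
  }
  rise <- sum(t_ * axis)
  ## axis point: min-norm solution of (I - R) p = t_perp
  t_perp <- t_ - rise * axis
  A <- diag(3) - R
  sv <- svd(A)
  dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
  point <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, t_perp)))
  structure(list(twist = theta, rise = rise, axis = axis, point = point),
            class = "xlwalk_screw")
}

#' @export
print.xlwalk_screw <- function(x, ...) {
  cat(sprintf("screw: twist %.4f deg, rise %.4f A, axis (%s), point (%s)\n",
              x$twist, x$rise,
              paste(format(x$axis, digits = 4), collapse = ", "),
              paste(format(x$point, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Build a rigid transform from screw parameters
#'
#' Inverse of [screw_parameters()]: rotation of `twist` degrees about the
#' axis through `point`, plus a `rise` translation along the axis.
#'
#' @param twist rotation in degrees.
#' @param rise translation along the axis in Angstrom.
#' @param axis axis direction (normalized internally).
#' @param point a point on the axis.
#' @return an [rigid_transform()].
#' @export
screw_transform <- function(twist, rise, axis = c(0, 0, 1),
                            point = c(0, 0, 0)) {
  axis <- unit(axis)
  R <- rotation_matrix(axis, twist)
  t_ <- rise * axis + as.numeric((diag(3) - R) %*% point)
  rigid_transform(R, t_)
}

#' Helical pitch and subunits per turn
#'
#' @param twist inter-subunit twist in degrees (> 0).
#' @param rise inter-subunit rise in Angstrom.
#' @return a list: `pitch` (Angstrom per turn, `rise * 360 / twist`) and
#'   `subunits_per_turn` (`360 / twist`).
#' @export
helical_pitch <- function(twist, rise) {
  if (twist <= 0) stop("twist must be > 0")
  list(pitch = rise * 360 / twist, subunits_per_turn = 360 / twist)
}

## --- solvent-accessible surface area ------------------------------------

#' Van der Waals radii for common elements
#'
#' Bondi-style heavy-atom radii used for SASA calculations; unknown
#' elements fall back to carbon.
#'
#' @param elements character vector of element symbols.
#' @return numeric radii in Angstrom.
#' @export
vdw_radius <- function(elements) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
           FE = 1.80, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 1.80,
           "NA" = 2.27)
  r <- tab[toupper(trimws(elements))]
  r[is.na(r)] <- tab[["C"]]
  as.numeric(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` quasi-uniform points (golden-spiral) on the expanded
#' sphere of each atom (radius + probe) and counts the fraction not buried
#' inside any neighbor's expanded sphere.
#'
#' @param coords n x 3 heavy-atom coordinate matrix.
#' @param radii per-atom radii in Angstrom (> 0).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return per-atom accessible areas in square Angstrom, with attribute
#'   `total`.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0))
  pts <- sphere_points(n_points)
  re <- radii + probe
  areas <- numeric(n)
  ## neighbor candidates via a coarse pairwise cutoff
  maxr <- max(re)
  for (i in seq_len(n)) {
    d <- point_dists(coords, coords[i, ])
    nb <- which(d < re[i] + re & seq_len(n) != i)
    sp <- pts * re[i]
    sp <- sweep(sp, 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- point_dists(sp[acc, , drop = FALSE], coords[j, ])
      acc[acc] <- dj >= re[j]
    }
    areas[i] <- 4 * pi * re[i]^2 * sum(acc) / n_points
  }
  attr(areas, "total") <- sum(areas)
  areas
}

## heavy-atom table from a bio3d pdb object (or a ready-made data frame)
atom_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!inherits(x, "pdb")) stop("expected a bio3d 'pdb' object")
  at <- x$atom[x$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | trimws(elem) == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  keep <- toupper(trimws(elem)) != "H"
  at <- at[keep, , drop = FALSE]
  data.frame(x = at$x, y = at$y, z = at$z,
             radius = vdw_radius(elem[keep]),
             chain = at$chain, resno = at$resno,
             stringsAsFactors = FALSE)
}

#' SASA of a structure
#'
#' @param pdb a bio3d `pdb` object (hydrogens are ignored).
#' @param probe,n_points see [sasa()].
#' @return per-atom areas with attribute `total`.
#' @export
sasa_pdb <- function(pdb, probe = 1.4, n_points = 960) {
  at <- atom_table(pdb)
  sasa(cbind(at$x, at$y, at$z), at$radius, probe, n_points)
}

#' Buried interface area between two chain sets
#'
#' Computes `buried = SASA(A alone) + SASA(B alone) - SASA(A+B)` (the
#' both-sides convention) plus per-side burials and the interface residue
#' list (any residue with a heavy atom within `cutoff` of the partner set).
#'
#' @param structure a bio3d `pdb` object, or a data frame with columns
#'   `x, y, z, radius, chain, resno`.
#' @param chains_a,chains_b disjoint chain identifier sets.
#' @param probe,n_points see [sasa()].
#' @param cutoff interface residue distance cutoff in Angstrom (default
#'   4.5).
#' @return a list of class `xlwalk_interface`: `buried` (both-sides, A^2),
#'   `buried_a`, `buried_b` (per-side), `sasa_free`, `sasa_complexed`
#'   (named per set), `residues_a`, `residues_b` (interface residue data
#'   frames).
#' @export
buried_area <- function(structure, chains_a, chains_b, probe = 1.4,
                        n_points = 960, cutoff = 4.5) {
  if (length(intersect(chains_a, chains_b)))
    stop("chain sets must be disjoint")
  at <- atom_table(structure)
  ia <- which(at$chain %in% chains_a)
  ib <- which(at$chain %in% chains_b)
  if (!length(ia) || !length(ib))
    stop("one of the chain sets matches no atoms")
  xyz <- cbind(at$x, at$y, at$z)
  sa_a <- sasa(xyz[ia, , drop = FALSE], at$radius[ia], probe, n_points)
  sa_b <- sasa(xyz[ib, , drop = FALSE], at$radius[ib], probe, n_points)
  iab <- c(ia, ib)
  sa_ab <- sasa(xyz[iab, , drop = FALSE], at$radius[iab], probe, n_points)
  in_complex_a <- sum(sa_ab[seq_along(ia)])
  in_complex_b <- sum(sa_ab[length(ia) + seq_along(ib)])
  buried <- attr(sa_a, "total") + attr(sa_b, "total") - attr(sa_ab, "total")
  iface <- function(self, partner) {
    hits <- vapply(self, function(i)
      min(point_dists(xyz[partner, , drop = FALSE], xyz[i, ])) <= cutoff,
      TRUE)
    res <- unique(at[self[hits], c("chain", "resno")])
    res[order(res$chain, res$resno), , drop = FALSE]
  }
  structure(list(buried = buried,
                 buried_a = attr(sa_a, "total") - in_complex_a,
                 buried_b = attr(sa_b, "total") - in_complex_b,
                 sasa_free = c(A = attr(sa_a, "total"),
                               B = attr(sa_b, "total")),
                 sasa_complexed = c(A = in_complex_a, B = in_complex_b),
                 residues_a = iface(ia, ib), residues_b = iface(ib, ia)),
            class = "xlwalk_interface")
}

#' @export
print.xlwalk_interface <- function(x, ...) {
  cat(sprintf("buried interface area: %.1f A^2 (both sides; %.1f / %.1f per side)\n",
              x$buried, x$buried_a, x$buried_b))
  cat(sprintf("  interface residues: %d (A side), %d (B side)\n",
              nrow(x$residues_a), nrow(x$residues_b)))
  invisible(x)
}

#' Displacement of ring subunits from a reference lattice register
#'
#' Superposes the ring subunit positions onto the reference lattice using
#' only the designated alignment pairs (e.g., the subunits matched to
#' lattice-docked tubulins), then reports the per-subunit displacement from
#' its reference site.
#'
#' @param ring_positions k x 3 matrix of ring subunit positions.
#' @param reference_positions k x 3 matrix of ideal lattice positions,
#'   row-paired with `ring_positions`.
#' @param align_pairs integer indices (>= 2) of the rows used for the
#'   alignment.
#' @return a list: `displacement` (per subunit, Angstrom), `max`,
#'   `align_rmsd`.
#' @export
mt_register_displacement <- function(ring_positions, reference_positions,
                                     align_pairs) {
  if (nrow(ring_positions) != nrow(reference_positions))
    stop("ring and reference must have equal subunit counts")
  if (length(align_pairs) < 2)
    stop("at least 2 alignment pairs are required")
  if (length(align_pairs) >= 3) {
    fit <- superpose(reference_positions, ring_positions, align_pairs)
    tf <- fit$transform
  } else {
    ## two pairs: match centroids, minimal rotation aligning the pair axis
    a <- reference_positions[align_pairs, , drop = FALSE]
    b <- ring_positions[align_pairs, , drop = FALSE]
    va <- unit(a[2, ] - a[1, ]); vb <- unit(b[2, ] - b[1, ])
    cr <- c(vb[2] * va[3] - vb[3] * va[2],
            vb[3] * va[1] - vb[1] * va[3],
            vb[1] * va[2] - vb[2] * va[1])
    ang <- 180 / pi * atan2(vec_norm(cr), sum(va * vb))
    R <- if (vec_norm(cr) < 1e-12) diag(3) else rotation_matrix(cr, ang)
    t_ <- colMeans(a) - as.numeric(R %*% colMeans(b))
    tf <- rigid_transform(R, t_)
  }
  moved <- apply_transform(ring_positions, tf)
  disp <- sqrt(rowSums((moved - reference_positions)^2))
  list(displacement = disp, max = max(disp),
       align_rmsd = sqrt(mean(disp[align_pairs]^2)), transform = tf)
}

#' Interface context of a residue (e.g., a phosphorylation site)
#'
#' Minimum heavy-atom distance from a residue to each named partner chain,
#' and whether the residue sits within an interface cutoff of any of them.
#'
#' @param structure a bio3d `pdb` object or an atom data frame (see
#'   [buried_area()]).
#' @param chain,resno the residue to annotate.
#' @param partner_chains chains to measure against.
#' @param cutoff interface cutoff in Angstrom (default 4.5).
#' @return a list: `distances` (named per partner chain, `NA` when the
#'   partner chain is absent), `within_interface`, `unmapped` (`TRUE` when
#'   the residue itself is not resolved; no exception is thrown).
#' @export
site_context <- function(structure, chain, resno, partner_chains,
                         cutoff = 4.5) {
  at <- atom_table(structure)
  self <- which(at$chain == chain & at$resno == resno)
  if (!length(self)) {
    return(list(distances = stats::setNames(
      rep(NA_real_, length(partner_chains)), partner_chains),
      within_interface = NA, unmapped = TRUE))
  }
  xyz <- cbind(at$x, at$y, at$z)
  d <- vapply(partner_chains, function(ch) {
    idx <- which(at$chain == ch)
    if (!length(idx)) return(NA_real_)
    min(vapply(self, function(i)
      min(point_dists(xyz[idx, , drop = FALSE], xyz[i, ])), 0))
  }, 0)
  list(distances = d, within_interface = any(d <= cutoff, na.rm = TRUE),
       unmapped = FALSE)
}

#' Calpha coordinates for a chain/range selection
#'
#' Parses selections like `"A:52-276+B:178-342"` (chain, inclusive residue
#' range; `+` joins parts; a bare chain id selects the whole chain).
#'
#' @param pdb a bio3d `pdb` object.
#' @param spec selection string.
#' @return m x 3 Calpha coordinate matrix with `chain` and `resno`
#'   attributes.
#' @export
select_ca <- function(pdb, spec) {
  parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
  rows <- integer(0)
  for (pt in parts) {
    f <- strsplit(pt, ":", fixed = TRUE)[[1]]
    ch <- f[1]
    if (length(f) > 1) {
      rng <- as.integer(strsplit(f[2], "-", fixed = TRUE)[[1]])
      resno <- if (length(rng) == 2) rng[1]:rng[2] else rng[1]
      sel <- bio3d::atom.select(pdb, "calpha", chain = ch, resno = resno,
                                verbose = FALSE)
    } else {
      sel <- bio3d::atom.select(pdb, "calpha", chain = ch, verbose = FALSE)
    }
    rows <- c(rows, sel$atom)
  }
  if (!length(rows)) stop("selection '", spec, "' matches no Calpha atoms")
  at <- pdb$atom[rows, ]
  structure(cbind(at$x, at$y, at$z), chain = at$chain, resno = at$resno)
}
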